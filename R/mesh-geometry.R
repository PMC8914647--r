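#' Check watertightness of a triangle mesh
#'
#' A mesh is watertight (closed 2-manifold) when every undirected edge is
#' shared by exactly two faces; winding is consistent when each such edge
#' appears once in each direction. Both are required before computing a
#' signed volume.
#'
#' @param mesh an [anthro_mesh()].
#' @return a list with logical `watertight`, logical `consistent_winding`,
#'   and `open_edges` (count of edges not shared by exactly two faces).
#' @export
mesh_watertight <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key_dir <- paste(he[, 1], he[, 2])
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und_tab <- table(key_und)
  open_edges <- sum(und_tab != 2L)
  watertight <- open_edges == 0L
  # consistent winding: no directed edge repeated
  consistent <- watertight && !anyDuplicated(key_dir)
  list(watertight = watertight, consistent_winding = consistent,
       open_edges = open_edges)
}

#' Mesh volume in litres
#'
#' Enclosed volume by the divergence theorem: the sum of signed tetrahedra
#' spanned by each face and the origin, \eqn{V = |\sum_f v_1 \cdot (v_2
#' \times v_3) / 6|}, converted from cubic metres to litres. Translation
#' invariant for watertight meshes.
#'
#' @param mesh an [anthro_mesh()]; must be watertight and consistently wound.
#' @return volume in litres.
#' @export
mesh_volume <- function(mesh) {
  wt <- mesh_watertight(mesh)
  if (!wt$watertight)
    stop("mesh is not watertight: ", wt$open_edges,
         " edge(s) not shared by exactly two faces")
  if (!wt$consistent_winding)
    stop("mesh winding is inconsistent; cannot compute signed volume")
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  signed <- sum(rowSums(a * cross)) / 6
  abs(signed) * 1000
}

#' Mesh height in centimetres
#'
#' Stature measured as the extent along the up axis: the difference between
#' the topmost point (head) and the lowest point (heel).
#'
#' @param mesh an [anthro_mesh()].
#' @return height in cm.
#' @export
mesh_height <- function(mesh) {
  if (nrow(mesh$vertices) == 0L) stop("mesh has no vertices")
  ax <- axis_index(mesh$up_axis)
  diff(range(mesh$vertices[, ax])) * 100
}

#' Euclidean distance between two points, in millimetres
#'
#' @param p1,p2 numeric length-3 points in metres.
#' @return distance in mm.
#' @export
point_distance <- function(p1, p2) {
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) * 1000
}

## ---- plane slicing ---------------------------------------------------

# Intersect each triangle with the plane (point p0, unit normal n) and
# return a list of segments (2 x 3 matrices). Degenerate contact is handled
# explicitly: on-plane vertices join segments, on-plane edges are emitted by
# both adjacent faces and deduplicated later, faces entirely in the plane
# are skipped, single-point contact is dropped.
triangle_plane_segments <- function(mesh, p0, n, tol = 1e-12) {
  v <- mesh$vertices
  d <- as.vector((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% n)
  cls <- ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
  segs <- list()
  for (fi in seq_len(nrow(mesh$faces))) {
    idx <- mesh$faces[fi, ]
    s <- cls[idx]
    n_on <- sum(s == 0L)
    if (all(s >= 0L) && n_on < 2L) next
    if (all(s <= 0L) && n_on < 2L) next
    if (n_on == 3L) next  # coplanar face: boundary edges come from neighbours
    pts <- NULL
    if (n_on == 2L) {
      pts <- v[idx[s == 0L], , drop = FALSE]
    } else if (n_on == 1L) {
      # one vertex on the plane, others strictly opposite sides
      on_v <- v[idx[s == 0L], , drop = FALSE]
      oth <- idx[s != 0L]
      a <- v[oth[1], ]; b <- v[oth[2], ]
      t <- d[oth[1]] / (d[oth[1]] - d[oth[2]])
      pts <- rbind(on_v, a + t * (b - a))
    } else {
      # classic crossing: two edges cut
      cut <- list()
      edges <- rbind(c(1, 2), c(2, 3), c(3, 1))
      for (e in seq_len(3)) {
        i1 <- idx[edges[e, 1]]; i2 <- idx[edges[e, 2]]
        if (cls[i1] * cls[i2] < 0L) {
          t <- d[i1] / (d[i1] - d[i2])
          cut[[length(cut) + 1L]] <- v[i1, ] + t * (v[i2, ] - v[i1, ])
        }
      }
      if (length(cut) == 2L) pts <- rbind(cut[[1]], cut[[2]])
    }
    if (!is.null(pts) && sqrt(sum((pts[1, ] - pts[2, ])^2)) > tol)
      segs[[length(segs) + 1L]] <- pts
  }
  segs
}

# Chain segments into closed loops. Endpoints coincide within `tol` metres.
# Returns a list of point matrices (loops, first point not repeated).
chain_segments <- function(segs, tol = 1e-9) {
  if (length(segs) == 0L) return(list())
  pts <- do.call(rbind, segs)
  key <- paste(round(pts[, 1] / tol), round(pts[, 2] / tol),
               round(pts[, 3] / tol))
  uk <- unique(key)
  id <- match(key, uk)                       # point ids, 2 per segment
  ends <- matrix(id, ncol = 2, byrow = TRUE)
  # drop duplicate segments (on-plane edges emitted by both adjacent faces)
  ekey <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  keep <- !duplicated(ekey)
  ends <- ends[keep, , drop = FALSE]
  coords <- pts[!duplicated(key), , drop = FALSE]
  # adjacency: each point should touch exactly 2 segments in a closed slice
  adj <- vector("list", length(uk))
  for (si in seq_len(nrow(ends))) {
    adj[[ends[si, 1]]] <- c(adj[[ends[si, 1]]], si)
    adj[[ends[si, 2]]] <- c(adj[[ends[si, 2]]], si)
  }
  deg <- lengths(adj)
  if (any(deg != 2L))
    stop("open intersection chain: slice is not a set of closed loops (",
         sum(deg != 2L), " endpoint(s) with degree != 2); ",
         "is the mesh watertight?")
  used <- rep(FALSE, nrow(ends))
  loops <- list()
  for (start in seq_len(nrow(ends))) {
    if (used[start]) next
    loop_pts <- integer(0)
    cur_seg <- start
    cur_pt <- ends[start, 1]
    repeat {
      used[cur_seg] <- TRUE
      loop_pts <- c(loop_pts, cur_pt)
      nxt_pt <- setdiff(ends[cur_seg, ], cur_pt)
      if (length(nxt_pt) != 1L) nxt_pt <- ends[cur_seg, ends[cur_seg, ] != cur_pt][1]
      cand <- setdiff(adj[[nxt_pt]], cur_seg)
      cur_pt <- nxt_pt
      cur_seg <- cand[!used[cand]][1]
      if (is.na(cur_seg)) break
    }
    loops[[length(loops) + 1L]] <- coords[loop_pts, , drop = FALSE]
  }
  loops
}

loop_perimeter <- function(loop) {
  nxt <- rbind(loop[-1, , drop = FALSE], loop[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - loop)^2)))
}

#' Slice a mesh with a plane and return all closed cross-section loops
#'
#' @param mesh an [anthro_mesh()].
#' @param plane_point point on the plane (metres).
#' @param plane_normal plane normal (normalised internally).
#' @param tol chaining tolerance on endpoint coincidence, metres.
#' @return a list of class `"anthro_slice"`: `plane_point`, `plane_normal`,
#'   and `loops`, a list of point matrices (closed by convention: the first
#'   point is not repeated as the last).
#' @export
slice_mesh <- function(mesh, plane_point, plane_normal, tol = 1e-9) {
  n <- as.numeric(plane_normal)
  n <- n / sqrt(sum(n^2))
  segs <- triangle_plane_segments(mesh, as.numeric(plane_point), n)
  if (length(segs) == 0L) stop("plane does not intersect the mesh")
  loops <- chain_segments(segs, tol)
  structure(list(plane_point = as.numeric(plane_point), plane_normal = n,
                 loops = loops),
            class = "anthro_slice")
}

#' Cross-section circumference by plane slicing
#'
#' Intersects the mesh with the plane, chains the intersection segments
#' into closed loops, selects the loop nearest `anchor` (the measurement's
#' landmark), and returns its perimeter. When the plane cuts several body
#' parts (a waist plane also crossing the arms), the anchor rule picks the
#' intended part. Optionally the loop is replaced by its 2-D convex hull
#' in the slicing plane — a "tape measure" reading; the default sums the
#' raw segments.
#'
#' @inheritParams slice_mesh
#' @param anchor point (metres) identifying the intended loop; usually the
#'   landmark vertex the plane passes through.
#' @param convex if `TRUE`, return the convex-hull perimeter of the
#'   selected loop instead of the raw polygon perimeter.
#' @return circumference in mm.
#' @export
slice_circumference <- function(mesh, plane_point, plane_normal, anchor,
                                convex = FALSE, tol = 1e-9) {
  sl <- slice_mesh(mesh, plane_point, plane_normal, tol)
  anchor <- as.numeric(anchor)
  d2 <- vapply(sl$loops, function(lp) {
    min(rowSums((lp - matrix(anchor, nrow(lp), 3, byrow = TRUE))^2))
  }, numeric(1))
  loop <- sl$loops[[which.min(d2)]]
  if (convex) loop <- loop_convex_hull(loop, sl$plane_normal)
  loop_perimeter(loop) * 1000
}

# project loop points into the plane and take the 2-D convex hull
loop_convex_hull <- function(loop, n) {
  # build an orthonormal basis (u, w) of the plane
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  xy <- cbind(loop %*% u, loop %*% w)
  h <- grDevices::chull(xy)
  loop[h, , drop = FALSE]
}
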