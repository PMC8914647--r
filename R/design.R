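#' Design specification for the height-weight baseline
#'
#' The plain baseline regresses each measurement on an intercept, height
#' and weight. Augmented baselines append interaction terms: `I = 2` adds
#' BMI (\eqn{w/h^2}) and \eqn{w/h}; `I = 4` further adds \eqn{w^2} and
#' \eqn{h^2}. Base height is in cm and weight in kg; the interaction
#' terms use height in metres, so the BMI column is conventional
#' kg/m\eqn{^2}.
#'
#' @param n_interactions 0, 2 or 4.
#' @return a list of class `"design_spec"` with `n_interactions` and the
#'   ordered `terms`.
#' @export
design_spec <- function(n_interactions = 0L) {
  n_interactions <- as.integer(n_interactions)
  if (!n_interactions %in% c(0L, 2L, 4L))
    stop("n_interactions must be 0, 2 or 4")
  terms <- c("intercept", "h", "w")
  if (n_interactions >= 2L) terms <- c(terms, "bmi", "w_over_h")
  if (n_interactions == 4L) terms <- c(terms, "w_sq", "h_sq")
  structure(list(n_interactions = n_interactions, terms = terms),
            class = "design_spec")
}

#' Build the regression design matrix
#'
#' One row per subject, a leading column of ones for the intercept, then
#' height (cm), weight (kg) and any interaction terms of the design
#' specification (computed with height in metres).
#'
#' @param height_cm,weight_kg numeric vectors of equal length, positive.
#' @param spec a [design_spec()] or the `n_interactions` integer.
#' @return an N x (3 + I) matrix with named columns.
#' @export
build_design_matrix <- function(height_cm, weight_kg, spec = design_spec()) {
  if (!inherits(spec, "design_spec")) spec <- design_spec(spec)
  if (length(height_cm) != length(weight_kg))
    stop("height and weight must have equal length")
  if (any(height_cm <= 0)) stop("non-positive height")
  h_m <- height_cm / 100
  cols <- list(intercept = rep(1, length(height_cm)),
               h = height_cm, w = weight_kg,
               bmi = weight_kg / h_m^2, w_over_h = weight_kg / h_m,
               w_sq = weight_kg^2, h_sq = h_m^2)
  X <- do.call(cbind, cols[spec$terms])
  colnames(X) <- spec$terms
  X
}

#' Closed-form ordinary least squares
#'
#' Solves \eqn{\min_A \|Y - XA\|^2}, the normal-equations solution
#' \eqn{A = (X^T X)^{-1} X^T Y}, computed through a QR factorisation for
#' numerical stability. Rank deficiency is an error naming the collinear
#' columns rather than a silently dropped coefficient.
#'
#' @param X design matrix (N x k, N > k).
#' @param y response vector (length N) or N x m matrix.
#' @return coefficient vector (or k x m matrix), named by design columns.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y_was_vector <- is.null(dim(y))
  y <- as.matrix(y)
  if (nrow(X) != nrow(y)) stop("X and y row counts differ")
  if (nrow(X) <= ncol(X))
    stop("need more observations (", nrow(X), ") than coefficients (",
         ncol(X), ")")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrx, y)
  if (y_was_vector) {
    coefs <- drop(coefs)
    names(coefs) <- colnames(X)
  } else rownames(coefs) <- colnames(X)
  coefs
}
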