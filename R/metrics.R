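#' Mean absolute error
#'
#' \eqn{E_{MAE} = \frac{1}{N}\sum_i |y_{est}^{(i)} - y_{gt}^{(i)}|}, in
#' the units of the inputs (mm throughout this package).
#'
#' @param est,gt paired numeric vectors of equal, positive length.
#' @return the MAE.
#' @export
mae <- function(est, gt) {
  if (length(est) != length(gt)) stop("est and gt differ in length")
  if (length(est) == 0L) stop("empty input")
  mean(abs(est - gt))
}

#' Mean relative error
#'
#' \eqn{E_{MRE} = \frac{1}{N}\sum_i |y_{est}^{(i)} -
#' y_{gt}^{(i)}|/y_{gt}^{(i)}}, a dimensionless per-sample ratio
#' (multiply by 100 for percent).
#'
#' @inheritParams mae
#' @return the MRE as a dimensionless ratio.
#' @export
mre <- function(est, gt) {
  if (length(est) != length(gt)) stop("est and gt differ in length")
  if (length(est) == 0L) stop("empty input")
  if (any(gt == 0)) stop("zero ground-truth value in MRE")
  mean(abs(est - gt) / abs(gt))
}

#' Percentage of samples within the expert allowable error
#'
#' The fraction of subjects whose absolute error is strictly below the
#' expert inter-observer threshold for that measurement, as a
#' percentage. Ties at the threshold count as failures (strict `<`).
#'
#' @inheritParams mae
#' @param threshold expert allowable error, mm (> 0).
#' @return percentage in \[0, 100\].
#' @export
pct_within_expert <- function(est, gt, threshold) {
  if (length(est) != length(gt)) stop("est and gt differ in length")
  if (length(est) == 0L) stop("empty input")
  if (is.na(threshold) || is.null(threshold)) stop("missing expert threshold")
  if (threshold <= 0) stop("expert threshold must be positive")
  100 * mean(abs(est - gt) < threshold)
}

#' Expert allowable-error table
#'
#' Per-measurement inter-observer error bounds from expert manual
#' anthropometry, available for 8 of the 15 standard measurements; the
#' rest carry no published threshold and are `NA`.
#'
#' @return named numeric vector (mm) over codes A-O.
#' @export
expert_error_table <- function() {
  c(A = 5.0, B = 6.0, C = 15.0, D = 12.0, E = 12.0, F = NA, G = NA, H = NA,
    I = 6.0, J = NA, K = 4.0, L = NA, M = NA, N = NA, O = 8.0)
}

#' Unweighted mean of the available expert errors
#'
#' @param table a named vector as from [expert_error_table()]; `NA`
#'   entries are unavailable thresholds.
#' @return mean threshold in mm.
#' @export
expert_error_mean <- function(table = expert_error_table()) {
  avail <- table[!is.na(table)]
  if (length(avail) == 0L) stop("no available expert thresholds")
  mean(avail)
}

#' Evaluate predicted measurements against ground truth
#'
#' Computes MAE (mm), MRE (reported as %), and — where an expert
#' threshold exists — the %<Expert ratio, per measurement code, plus the
#' unweighted mean MAE over the evaluated codes.
#'
#' @param pred,truth data.frames with matching measurement columns (and
#'   rows in the same subject order).
#' @param codes measurement columns to evaluate; default: the
#'   measurement columns common to both.
#' @param expert named threshold vector; see [expert_error_table()].
#' @return a list of class `"eval_report"`: `per_measurement`
#'   (data.frame with `code`, `mae_mm`, `mre_pct`, `pct_within_expert`)
#'   and `mean_mae_mm`.
#' @export
evaluate_measurements <- function(pred, truth, codes = NULL,
                                  expert = expert_error_table()) {
  if (is.null(codes))
    codes <- intersect(intersect(names(pred), names(truth)),
                       c(LETTERS[1:15], "arm_span", "inseam_height",
                         "hip_width"))
  if (length(codes) == 0L) stop("no common measurement columns")
  if (nrow(pred) != nrow(truth)) stop("pred and truth row counts differ")
  per <- do.call(rbind, lapply(codes, function(cd) {
    e <- pred[[cd]]; g <- truth[[cd]]
    thr <- if (cd %in% names(expert)) expert[[cd]] else NA_real_
    data.frame(code = cd,
               mae_mm = mae(e, g),
               mre_pct = 100 * mre(e, g),
               pct_within_expert = if (is.na(thr)) NA_real_ else
                 pct_within_expert(e, g, thr),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_measurement = per, mean_mae_mm = mean(per$mae_mm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("Measurement evaluation (per code):\n")
  tab <- x$per_measurement
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("mean MAE: %.*g mm\n", digits, x$mean_mae_mm))
  invisible(x)
}

#' Derive the standard measurements from an ANSUR-style record
#'
#' Maps the attribute names of an ANSUR-style tabular export (values in
#' mm) onto the measurement codes: direct copies for the circumferences
#' and shoulder breadth, and composite expressions for the three derived
#' lengths — shoulder-to-crotch `C = sittingheight - (stature -
#' acromialheight)`, arm length `J = acromialheight - wristheight`, and
#' inside-leg length `K = crotchheight - lateralmalleolusheight`.
#' Attribute names are matched case-insensitively after stripping
#' non-alphanumeric characters, to tolerate export dialects. A missing
#' attribute marks only the codes that need it as `NA`.
#'
#' @param row a named list / one-row data.frame of ANSUR attributes, mm.
#' @return named numeric vector over codes A-O (mm), `NA` where inputs
#'   are missing.
#' @export
ansur_derive <- function(row) {
  vals <- unlist(row)
  norm <- function(s) gsub("[^a-z0-9]", "", tolower(s))
  names(vals) <- norm(names(vals))
  g <- function(attr) {
    key <- norm(attr)
    if (key %in% names(vals)) as.numeric(vals[[key]]) else NA_real_
  }
  direct <- c(A = "headcircumference", B = "neckcircumference",
              D = "chestcircumference", E = "waistcircumference",
              F = "buttockcircumference", G = "wristcircumference",
              H = "bicepcircumferenceflexed",
              I = "forearmcircumferenceflexed",
              L = "thighcircumference", M = "calfcircumference",
              N = "anklecircumference", O = "biacromialbreadth")
  out <- stats::setNames(rep(NA_real_, 15), LETTERS[1:15])
  for (cd in names(direct)) out[cd] <- g(direct[cd])
  out["C"] <- g("sittingheight") - (g("stature") - g("acromialheight"))
  out["J"] <- g("acromialheight") - g("wristheight")
  out["K"] <- g("crotchheight") - g("lateralmalleolusheight")
  out
}
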