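#' Per-measurement OLS diagnostics
#'
#' Coefficient p-values from the standard two-sided t-test on `N - k`
#' degrees of freedom (k counts the intercept), adjusted
#' \eqn{R^2 = 1 - (1 - R^2)(N - 1)/(N - k)}, and the MAE and RMSE of the
#' residuals in mm. With zero residual variance (an exact fit) the
#' p-values are undefined and reported as `NA`, never as 0.
#'
#' @param X design matrix used for the fit.
#' @param y response vector.
#' @param coefs fitted coefficient vector (from [fit_ols()]).
#' @return a list: `p_values`, `std_errors`, `t_values`,
#'   `adj_r_squared`, `r_squared`, `mae`, `rmse`, `sigma` (residual SD),
#'   `residuals`, `df`.
#' @export
ols_diagnostics <- function(X, y, coefs = fit_ols(X, y)) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  res <- as.vector(y - X %*% coefs)
  df <- n - k
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / df else NA_real_
  sigma2 <- rss / df
  # an exact fit leaves only rounding noise in rss; p-values are undefined
  exact_fit <- rss <= 1e-12 * max(tss, sum(y^2), 1)
  xtx_inv <- chol2inv(qr.R(qr(X)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  if (!exact_fit && sigma2 > 0) {
    tval <- as.vector(coefs) / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  } else {
    tval <- rep(NA_real_, k)
    pval <- rep(NA_real_, k)
  }
  names(se) <- names(tval) <- names(pval) <- colnames(X)
  list(p_values = pval, std_errors = se, t_values = tval,
       adj_r_squared = adj_r2, r_squared = r2,
       mae = mean(abs(res)), rmse = sqrt(mean(res^2)),
       sigma = sqrt(sigma2), residuals = res, df = df)
}

#' Check the residual assumptions of a linear fit
#'
#' Verifies the three residual-related assumptions of linear regression:
#' \itemize{
#'   \item zero mean — one-sample t-test of the residuals against 0;
#'   \item normality — Anderson-Darling test
#'     ([nortest::ad.test()]; valid at cohort sizes where the
#'     Shapiro-Wilk test is unavailable);
#'   \item homoscedasticity — a Breusch-Pagan-style Lagrange-multiplier
#'     statistic: regress squared residuals on the fitted values, then
#'     \eqn{LM = n R^2 \sim \chi^2_1} under constant variance.
#' }
#' Verdict flags use `alpha`: a check "passes" when its null is not
#' rejected. All-zero (degenerate) residuals are reported explicitly
#' rather than tested.
#'
#' @param residuals,fitted_values numeric vectors, length >= 20.
#' @param alpha significance level for the verdict flags.
#' @return a list of class `"residual_checks"` with `mean`, per-check
#'   statistic/p-value pairs, logical `*_ok` flags and `degenerate`.
#' @export
residual_checks <- function(residuals, fitted_values, alpha = 0.05) {
  if (length(residuals) < 20L) stop("need at least 20 residuals")
  if (length(residuals) != length(fitted_values))
    stop("residuals and fitted values differ in length")
  if (all(residuals == 0)) {
    return(structure(list(mean = 0, degenerate = TRUE,
                          zero_mean_ok = TRUE, normality_ok = NA,
                          homoscedastic_ok = NA, alpha = alpha),
                     class = "residual_checks"))
  }
  tt <- stats::t.test(residuals, mu = 0)
  ad <- nortest::ad.test(residuals)
  # Breusch-Pagan LM statistic with fitted values as the variance covariate
  n <- length(residuals)
  aux <- stats::lm.fit(cbind(1, fitted_values), residuals^2)
  e2 <- residuals^2
  r2_aux <- 1 - sum(aux$residuals^2) / sum((e2 - mean(e2))^2)
  bp_stat <- n * r2_aux
  bp_p <- stats::pchisq(bp_stat, df = 1, lower.tail = FALSE)
  structure(list(
    mean = mean(residuals), degenerate = FALSE,
    zero_mean_statistic = unname(tt$statistic), zero_mean_p = tt$p.value,
    normality_statistic = unname(ad$statistic), normality_p = ad$p.value,
    homoscedasticity_statistic = bp_stat, homoscedasticity_p = bp_p,
    zero_mean_ok = tt$p.value >= alpha,
    normality_ok = ad$p.value >= alpha,
    homoscedastic_ok = bp_p >= alpha,
    alpha = alpha), class = "residual_checks")
}

#' @export
print.residual_checks <- function(x, ...) {
  cat("Residual assumption checks (alpha =", x$alpha, ")\n")
  if (isTRUE(x$degenerate)) {
    cat("  residuals are identically zero (exact fit); tests undefined\n")
    return(invisible(x))
  }
  fmt <- function(lbl, p, ok)
    cat(sprintf("  %-18s p = %.4g  [%s]\n", lbl, p,
                if (ok) "pass" else "FAIL"))
  cat(sprintf("  residual mean: %.4g\n", x$mean))
  fmt("zero mean", x$zero_mean_p, x$zero_mean_ok)
  fmt("normality", x$normality_p, x$normality_ok)
  fmt("homoscedasticity", x$homoscedasticity_p, x$homoscedastic_ok)
  invisible(x)
}
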