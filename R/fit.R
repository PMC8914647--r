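#' Fit per-sex height-weight baselines to a measurement cohort
#'
#' The central model of the package: for every measurement column and
#' each sex separately, an ordinary least-squares regression of the
#' measurement (mm) on height (cm), weight (kg) and optional interaction
#' terms, solved in closed form. Returns a classed object with the usual
#' modelling methods (`print`, `summary`, `coef`, `predict`,
#' `residuals`, `fitted`, `plot`, `simulate`).
#'
#' @param data data.frame with columns `sex` (`"male"`/`"female"`),
#'   `height_cm`, `weight_kg`, and one numeric column per measurement
#'   code.
#' @param measurements character vector of measurement columns; default:
#'   every numeric column other than height/weight/volume.
#' @param interactions number of interaction terms (0, 2 or 4); see
#'   [design_spec()].
#' @param sexes which sexes to fit. A sex with fewer subjects than
#'   coefficients + 1 is skipped with a warning.
#' @return an object of class `"anthrofit"`: a list with `spec`, and per
#'   sex a list holding the coefficient matrix (terms x measurements),
#'   diagnostics (see [ols_diagnostics()]), residual matrix and the
#'   training data slice.
#' @examples
#' cohort <- make_population(population_spec(n = 200, seed = 7))
#' fit <- anthro_fit(cohort, interactions = 2)
#' fit
#' head(predict(fit, data.frame(sex = "male", height_cm = 178,
#'                              weight_kg = 76)))
#' @export
anthro_fit <- function(data, measurements = NULL, interactions = 0L,
                       sexes = c("male", "female")) {
  if (!"sex" %in% names(data)) stop("data must contain a 'sex' column")
  stopifnot(all(c("height_cm", "weight_kg") %in% names(data)))
  if (is.null(measurements)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    measurements <- setdiff(num, c("height_cm", "weight_kg", "volume_L"))
  }
  if (length(measurements) == 0L) stop("no measurement columns to fit")
  spec <- design_spec(interactions)
  per_sex <- list()
  for (sx in sexes) {
    d <- data[data$sex == sx, , drop = FALSE]
    if (nrow(d) < length(spec$terms) + 1L) {
      warning("sex '", sx, "' has too few subjects (", nrow(d),
              "); model skipped")
      next
    }
    X <- build_design_matrix(d$height_cm, d$weight_kg, spec)
    Y <- as.matrix(d[, measurements, drop = FALSE])
    coefs <- fit_ols(X, Y)
    fitted <- X %*% coefs
    resid <- Y - fitted
    diag_list <- lapply(measurements, function(m)
      ols_diagnostics(X, Y[, m], coefs[, m]))
    names(diag_list) <- measurements
    per_sex[[sx]] <- list(coefficients = coefs, diagnostics = diag_list,
                          residuals = resid, fitted = fitted,
                          n = nrow(d), data = d)
  }
  if (length(per_sex) == 0L) stop("no sex had enough subjects to fit")
  structure(list(spec = spec, measurements = measurements,
                 models = per_sex, call = match.call()),
            class = "anthrofit")
}

#' @export
print.anthrofit <- function(x, ...) {
  cat("Per-sex linear anthropometric baseline\n")
  cat(sprintf("  terms: %s (I = %d)\n", paste(x$spec$terms, collapse = ", "),
              x$spec$n_interactions))
  for (sx in names(x$models))
    cat(sprintf("  %s: n = %d, %d measurements\n", sx, x$models[[sx]]$n,
                length(x$measurements)))
  invisible(x)
}

#' @export
coef.anthrofit <- function(object, sex = NULL, ...) {
  if (is.null(sex)) lapply(object$models, `[[`, "coefficients")
  else object$models[[sex]]$coefficients
}

#' @export
residuals.anthrofit <- function(object, sex = NULL, ...) {
  if (is.null(sex)) lapply(object$models, `[[`, "residuals")
  else object$models[[sex]]$residuals
}

#' @export
fitted.anthrofit <- function(object, sex = NULL, ...) {
  if (is.null(sex)) lapply(object$models, `[[`, "fitted")
  else object$models[[sex]]$fitted
}

#' Predict measurements for new subjects
#'
#' Pure linear algebra: each subject's design row times the coefficient
#' matrix of that subject's sex model.
#'
#' @param object an [anthro_fit()] model.
#' @param newdata data.frame with `sex`, `height_cm`, `weight_kg`.
#' @param ... unused.
#' @return data.frame: `sex`, `height_cm`, `weight_kg`, one column per
#'   measurement (mm), rows in `newdata` order.
#' @export
predict.anthrofit <- function(object, newdata, ...) {
  stopifnot(all(c("sex", "height_cm", "weight_kg") %in% names(newdata)))
  out <- matrix(NA_real_, nrow(newdata), length(object$measurements),
                dimnames = list(NULL, object$measurements))
  for (sx in names(object$models)) {
    rows <- which(newdata$sex == sx)
    if (!length(rows)) next
    X <- build_design_matrix(newdata$height_cm[rows],
                             newdata$weight_kg[rows], object$spec)
    out[rows, ] <- X %*% object$models[[sx]]$coefficients
  }
  unknown <- !newdata$sex %in% names(object$models)
  if (any(unknown))
    warning(sum(unknown), " subject(s) with no fitted sex model; NA returned")
  cbind(newdata[, c("sex", "height_cm", "weight_kg")], as.data.frame(out))
}

#' Simulate measurement vectors from a fitted baseline
#'
#' Draws each measurement as its linear prediction plus Gaussian noise
#' with the model's residual standard deviation, the generative
#' counterpart of the fit.
#'
#' @param object an [anthro_fit()] model.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed.
#' @param newdata subjects to simulate for; defaults to the training data.
#' @param ... unused.
#' @return a list of `nsim` data.frames shaped like [predict.anthrofit()].
#' @export
simulate.anthrofit <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata))
    newdata <- do.call(rbind, lapply(object$models, function(m)
      m$data[, c("sex", "height_cm", "weight_kg")]))
  base <- predict(object, newdata)
  sds <- lapply(object$models, function(m)
    vapply(m$diagnostics, `[[`, numeric(1), "sigma"))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    sim <- base
    for (sx in names(object$models)) {
      rows <- which(newdata$sex == sx)
      for (m in object$measurements)
        sim[rows, m] <- sim[rows, m] +
          stats::rnorm(length(rows), 0, sds[[sx]][[m]])
    }
    out[[s]] <- sim
  }
  if (nsim == 1L) out[[1L]] else out
}

#' @export
summary.anthrofit <- function(object, ...) {
  tabs <- lapply(names(object$models), function(sx) {
    dl <- object$models[[sx]]$diagnostics
    pv <- t(vapply(dl, `[[`, numeric(length(object$spec$terms)), "p_values"))
    data.frame(sex = sx, measurement = names(dl),
               adj_r_squared = vapply(dl, `[[`, numeric(1), "adj_r_squared"),
               mae_mm = vapply(dl, `[[`, numeric(1), "mae"),
               rmse_mm = vapply(dl, `[[`, numeric(1), "rmse"),
               as.data.frame(`colnames<-`(pv, paste0("p_", object$spec$terms))),
               row.names = NULL)
  })
  structure(list(spec = object$spec, table = do.call(rbind, tabs)),
            class = "summary.anthrofit")
}

#' @export
print.summary.anthrofit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear baseline (I = %d): adjusted R^2, MAE/RMSE (mm), ",
              x$spec$n_interactions),
      "coefficient p-values\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(cl) signif(cl, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Residual diagnostic plot for a fitted baseline
#'
#' Residuals versus fitted values plus a normal Q-Q panel for one
#' measurement and sex, the visual check of the homoscedasticity and
#' normality assumptions.
#'
#' @param x an [anthro_fit()] model.
#' @param measurement measurement code to plot (default: the first).
#' @param sex which sex model (default: the first fitted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.anthrofit <- function(x, measurement = x$measurements[1],
                           sex = names(x$models)[1], ...) {
  m <- x$models[[sex]]
  r <- m$residuals[, measurement]
  f <- m$fitted[, measurement]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(f, r, xlab = "fitted (mm)", ylab = "residual (mm)",
                 main = paste(sex, measurement), ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r, main = "normal Q-Q")
  stats::qqline(r)
  invisible(x)
}

#' Serialise / load a fitted baseline as JSON
#'
#' Stores the design specification, per-sex coefficient matrices,
#' residual SDs and sample sizes — everything [predict.anthrofit()] and
#' [simulate.anthrofit()] need.
#'
#' @param object an [anthro_fit()] model.
#' @param path JSON file path.
#' @return `write_model()`: `path` invisibly; `read_model()`: an
#'   `"anthrofit"` object (without training data or diagnostics).
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "anthrofit"))
  pay <- list(
    n_interactions = object$spec$n_interactions,
    measurements = object$measurements,
    models = lapply(object$models, function(m) list(
      n = m$n,
      coefficients = as.data.frame(m$coefficients),
      sigma = vapply(m$diagnostics, `[[`, numeric(1), "sigma")))
  )
  jsonlite::write_json(pay, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  pay <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- design_spec(pay$n_interactions)
  models <- lapply(pay$models, function(m) {
    co <- as.matrix(m$coefficients)
    rownames(co) <- spec$terms
    list(coefficients = co, n = m$n,
         diagnostics = lapply(as.list(m$sigma), function(s) list(sigma = s)))
  })
  structure(list(spec = spec, measurements = pay$measurements,
                 models = models, call = quote(read_model())),
            class = "anthrofit")
}
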