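#' Fit and cross-validate a linear WBSA prediction model
#'
#' The core statistical model of the framework: for a fixed camera
#' orientation, the whole body surface area is predicted linearly from the
#' view body surface area, optionally extended with stature and other
#' anthropometric measurements,
#' `WBSA = c1 * VBSA + c2 * Stature + ... + c0`.
#' Coefficients are estimated by ordinary least squares (QR decomposition)
#' and prediction error is estimated by seeded k-fold cross validation:
#' RMSE (dm^2), MSPE (dm^4, pooled over all held-out observations) and MAPE
#' (percent).
#'
#' @param formula model formula, e.g. `wbsa ~ vbsa` or
#'   `wbsa ~ vbsa + stature_cm`.
#' @param data data frame with the model variables.
#' @param k number of cross-validation folds (`k >= 2`, `k <= n`); set
#'   `cv = FALSE` to skip cross validation.
#' @param seed RNG seed for the random fold assignment.
#' @param cv compute cross-validation metrics.
#' @param theta,phi optional camera angles (degrees) recorded with the fit.
#' @param group optional group label recorded with the fit.
#' @return An object of class `"wbsa_model"`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `fitted`, `simulate`, `plot`.
#' @examples
#' d <- data.frame(vbsa = runif(50, 40, 120))
#' d$wbsa <- 1.9 * d$vbsa + 5 + rnorm(50)
#' fit <- wbsa_model(wbsa ~ vbsa, d, k = 5, seed = 1)
#' coef(fit)
#' @export
wbsa_model <- function(formula, data, k = 10L, seed = 1L, cv = TRUE,
                       theta = NA_real_, phi = NA_real_, group = "all") {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data)
  n <- nrow(mf)
  p <- ncol(stats::model.matrix(formula, mf))
  if (n <= p) stop("need more observations than coefficients")
  if (any(!is.finite(as.matrix(mf)))) stop("non-finite values in model data")
  lmfit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(lmfit)))) {
    bad <- names(stats::coef(lmfit))[is.na(stats::coef(lmfit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cvm <- if (cv) cross_validate(data, formula, k = k, seed = seed) else NULL
  structure(list(call = match.call(), formula = formula, fit = lmfit,
                 coefficients = stats::coef(lmfit),
                 residual_se = summary(lmfit)$sigma,
                 cv = cvm, n = n, theta = theta, phi = phi, group = group),
            class = "wbsa_model")
}

#' k-fold cross validation of a linear model
#'
#' Observations are split into `k` near-equal folds by a seeded uniform
#' random permutation; each fold is predicted by the model fitted on the
#' other `k - 1`. Errors are pooled over all held-out observations:
#' `MSPE = mean(err^2)`, `RMSE = sqrt(MSPE)`,
#' `MAPE = 100 * mean(|err| / truth)`.
#'
#' @param data data frame.
#' @param formula model formula.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed RNG seed for the fold assignment.
#' @return List with `rmse`, `mspe`, `mape`, `k`, `seed`, `folds` (the fold
#'   index of each observation) and `predictions`.
#' @export
cross_validate <- function(data, formula, k = 10L, seed = 1L) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of observations")
  folds <- local_seed(seed, sample(rep_len(seq_len(k), n)))
  resp <- stats::model.response(stats::model.frame(formula, data))
  pred <- numeric(n)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- stats::lm(formula, data = data[!test, , drop = FALSE])
    pred[test] <- stats::predict(fit, newdata = data[test, , drop = FALSE])
  }
  err <- resp - pred
  list(rmse = sqrt(mean(err^2)), mspe = mean(err^2),
       mape = 100 * mean(abs(err) / abs(resp)), k = k, seed = seed,
       folds = folds, predictions = pred)
}

#' @export
print.wbsa_model <- function(x, ...) {
  cat("Linear WBSA prediction model\n")
  if (!is.na(x$theta)) {
    cat(sprintf("  view: theta %.0f deg, phi %.0f deg\n", x$theta, x$phi))
  }
  cat(sprintf("  group: %s, n = %d\n", x$group, x$n))
  cat("  coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  residual SE: %.4f dm^2\n", x$residual_se))
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV: RMSE %.4f dm^2, MSPE %.4f, MAPE %.3f%%\n",
                x$cv$k, x$cv$rmse, x$cv$mspe, x$cv$mape))
  }
  invisible(x)
}

#' @export
summary.wbsa_model <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(lm_summary = s, cv = object$cv, n = object$n,
              theta = object$theta, phi = object$phi, group = object$group)
  class(out) <- "summary.wbsa_model"
  out
}

#' @export
print.summary.wbsa_model <- function(x, ...) {
  print(x$lm_summary)
  if (!is.null(x$cv)) {
    cat(sprintf("%d-fold CV: RMSE %.4f dm^2, MSPE %.4f dm^4, MAPE %.3f%%\n",
                x$cv$k, x$cv$rmse, x$cv$mspe, x$cv$mape))
  }
  invisible(x)
}

#' @export
coef.wbsa_model <- function(object, ...) object$coefficients

#' @export
predict.wbsa_model <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.wbsa_model <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.wbsa_model <- function(object, ...) stats::fitted(object$fit)

#' @export
simulate.wbsa_model <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Diagnostic plots for a WBSA model
#'
#' Draws the validation plots used for linear-model checking: residual
#' normal QQ plot and the scale plot of residuals against fitted values
#' (homoscedasticity check).
#'
#' @param x a [wbsa_model()].
#' @param which subset of `1:2`.
#' @param ... passed to the base plotting functions.
#' @export
plot.wbsa_model <- function(x, which = 1:2, ...) {
  r <- stats::rstandard(x$fit)
  if (1 %in% which) {
    stats::qqnorm(r, main = "Residual QQ plot", ...)
    stats::qqline(r)
  }
  if (2 %in% which) {
    graphics::plot(stats::fitted(x$fit), r,
                   xlab = expression(paste("fitted WBSA (", dm^2, ")")),
                   ylab = "standardized residual",
                   main = "Scale plot", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Spearman correlation matrix
#'
#' Rank-based correlation between every pair of numeric columns, with
#' average ranks for ties. Constant columns have undefined rank correlation
#' and are flagged with `NA` and a warning rather than silently reported
#' as 0.
#'
#' @param data data frame or matrix of numeric variables (>= 3 rows).
#' @return A symmetric correlation matrix of class `"spearman_matrix"` with
#'   unit diagonal.
#' @export
spearman_matrix <- function(data) {
  x <- as.matrix(as.data.frame(data)[vapply(as.data.frame(data), is.numeric,
                                            TRUE)])
  if (nrow(x) < 3L) stop("need at least 3 rows")
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(constant)) {
    warning("constant columns have undefined rank correlation: ",
            paste(colnames(x)[constant], collapse = ", "))
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
    diag(rho) <- ifelse(constant, NA_real_, 1)
  }
  class(rho) <- c("spearman_matrix", class(rho))
  rho
}

#' @export
print.spearman_matrix <- function(x, digits = 4, ...) {
  cat("Spearman rank correlation matrix\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Fit WBSA models per population group
#'
#' Repeats the fit and cross validation independently on each partition of
#' the data (males/females, kids/adults, stature classes, ...). Groups with
#' fewer observations than `min_size` are skipped with a warning.
#'
#' @param data data frame.
#' @param formula model formula.
#' @param group grouping: a column name in `data` or a vector of labels.
#' @param k,seed cross-validation settings.
#' @param min_size minimum group size; defaults to the number of
#'   coefficients plus two.
#' @param theta,phi camera angles recorded with each fit.
#' @return Named list of [wbsa_model()] objects, one per retained group.
#' @export
fit_by_group <- function(data, formula, group, k = 10L, seed = 1L,
                         min_size = NULL, theta = NA_real_, phi = NA_real_) {
  data <- as.data.frame(data)
  g <- if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(data)) stop("grouping column not found: ", group)
    data[[group]]
  } else {
    group
  }
  if (length(g) != nrow(data)) stop("grouping length must match data")
  if (all(is.na(g)) || !length(g)) stop("empty grouping")
  p <- ncol(stats::model.matrix(formula, stats::model.frame(formula, data)))
  if (is.null(min_size)) min_size <- p + 2L
  out <- list()
  for (lev in unique(as.character(g))) {
    idx <- which(as.character(g) == lev)
    if (length(idx) < max(min_size, k)) {
      warning("group '", lev, "' skipped: only ", length(idx),
              " observations")
      next
    }
    out[[lev]] <- wbsa_model(formula, data[idx, , drop = FALSE], k = k,
                             seed = seed, theta = theta, phi = phi,
                             group = lev)
  }
  if (!length(out)) stop("no group met the minimum size")
  out
}

#' Residual diagnostics table
#'
#' Returns the table behind the QQ and scale plots — residuals, standardized
#' residuals, fitted values and theoretical normal quantiles — together
#' with a Breusch-Pagan variance-trend test (studentized) as the formal
#' homoscedasticity check.
#'
#' @param fit a [wbsa_model()].
#' @return List with `table` (data frame) and `bp` (the Breusch-Pagan test,
#'   `htest`).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "wbsa_model"))
  r <- stats::residuals(fit$fit)
  rs <- stats::rstandard(fit$fit)
  n <- length(r)
  theo <- stats::qnorm(stats::ppoints(n))[rank(rs, ties.method = "first")]
  tab <- data.frame(fitted = stats::fitted(fit$fit), residual = r,
                    standardized = rs, theoretical_quantile = theo)
  bp <- lmtest::bptest(fit$fit)
  list(table = tab, bp = bp)
}

#' Flatten fitted models to a results table
#'
#' One row per fit: angles, group, sample size, coefficients, residual SE,
#' t-value of the VBSA coefficient and cross-validation errors — the
#' machine-readable per-angle results table of a sweep.
#'
#' @param fits a [wbsa_model()], or a (possibly nested) list of them.
#' @param model label stored in the `model` column.
#' @return A data frame.
#' @export
angle_fit_table <- function(fits, model = "vbsa") {
  if (inherits(fits, "wbsa_model")) fits <- list(fits)
  fits <- unlist(list(fits), recursive = FALSE)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "wbsa_model"))
    cf <- f$coefficients
    s <- summary(f$fit)$coefficients
    tv <- if ("vbsa" %in% rownames(s)) s["vbsa", "t value"] else NA_real_
    row <- data.frame(theta = f$theta, phi = f$phi, group = f$group,
                      model = model, n = f$n,
                      c0 = unname(cf["(Intercept)"]),
                      se = f$residual_se, t_value = tv,
                      cv_rmse = if (!is.null(f$cv)) f$cv$rmse else NA_real_,
                      cv_mspe = if (!is.null(f$cv)) f$cv$mspe else NA_real_,
                      cv_mape = if (!is.null(f$cv)) f$cv$mape else NA_real_,
                      stringsAsFactors = FALSE)
    slopes <- cf[setdiff(names(cf), "(Intercept)")]
    names(slopes) <- paste0("c_", names(slopes))
    names(slopes)[names(slopes) == "c_vbsa"] <- "c1"
    cbind(row, as.data.frame(as.list(slopes)))
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA_real_
    r[all_cols]
  }))
  rownames(tab) <- NULL
  tab
}
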