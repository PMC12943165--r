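#' Create a named linear model specification
#'
#' A `model_spec` is the minimal portable form of a linear QSAR model:
#' an intercept plus one coefficient per descriptor name. It is what
#' [fit_mlr()] produces and what [predict_pic50()] consumes.
#'
#' @param name Model name.
#' @param intercept Intercept (b0).
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, intercept, coefficients) {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    abort("coefficients must have unique non-empty names",
          class = "qsardyn_domain")
  }
  if (!all(is.finite(c(intercept, coefficients)))) {
    abort("model coefficients must be finite", class = "qsardyn_domain")
  }
  structure(list(name = as.character(name),
                 intercept = as.numeric(intercept),
                 coefficients = setNames(as.numeric(coefficients),
                                         names(coefficients))),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- sprintf("%+.4f*%s", x$coefficients, names(x$coefficients))
  cat(sprintf("<model_spec '%s'>\n  pIC50 = %.4f %s\n",
              x$name, x$intercept, paste(terms, collapse = " ")))
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(x$name, ": ", x$intercept, " + ",
         paste(sprintf("%g*%s", x$coefficients, names(x$coefficients)),
               collapse = " + "))
}

#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of the activity on a chosen descriptor subset,
#' with an intercept. Descriptors enter unscaled, so coefficients are on
#' the raw descriptor scales (their magnitudes are therefore not
#' comparable across descriptors).
#'
#' @param data Descriptor tibble containing the activity column.
#' @param activity Name of the activity column.
#' @param descriptors Character vector of descriptor names to fit on;
#'   `NULL` uses every descriptor column.
#' @param name Name to give the fitted `model_spec`.
#' @return An object of class `mlr_fit`: list with `model` (a
#'   [model_spec()]), `fitted_values`, `residuals`, `n`, `p`, `leverages`,
#'   and the training design. Supports [tidy()], [glance()], [augment()],
#'   [predict()] and [autoplot()].
#' @examples
#' sim <- gen_qsar_dataset(preset_study57(seed = 1))
#' fit <- fit_mlr(sim$data, activity = "pIC50",
#'                descriptors = sim$truth$signal_names)
#' glance(fit)
#' @export
fit_mlr <- function(data, activity, descriptors = NULL, name = "mlr") {
  parts <- dt_parts(data, activity = activity, descriptors = descriptors,
                    require_activity = TRUE)
  X <- parts$X
  y <- parts$y
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) {
    abort(sprintf("under-determined fit: n = %d compounds for p = %d descriptors (need n > p + 1)",
                  n, p), class = "qsardyn_underdetermined")
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) {
    dropped <- colnames(X1)[qrx$pivot[(qrx$rank + 1L):ncol(X1)]]
    abort(paste0("singular design: column(s) collinear with the rest: ",
                 paste(dropped, collapse = ", ")),
          class = "qsardyn_singular")
  }
  coefs <- qr.coef(qrx, y)
  fitted <- as.vector(X1 %*% coefs)
  resid <- y - fitted
  h <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
  spec <- model_spec(name, coefs[1], coefs[-1])
  structure(list(model = spec,
                 fitted_values = fitted,
                 residuals = resid,
                 observed = y,
                 leverages = h,
                 n = n, p = p,
                 compound_ids = parts$ids,
                 activity = activity,
                 X = X),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("<mlr_fit> n = %d, p = %d descriptors\n", x$n, x$p))
  print(x$model)
  g <- glance(x)
  cat(sprintf("  R2 = %.4f, adj R2 = %.4f, RMSE = %.4f, MAE = %.4f\n",
              g$r2, g$adj_r2, g$rmse, g$mae))
  invisible(x)
}

#' Predict activity from a fitted model or model spec
#'
#' @param object An `mlr_fit` or `model_spec`.
#' @param newdata Descriptor tibble (or named list/vector) containing every
#'   descriptor the model uses. Extra columns are ignored.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.mlr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  predict_pic50(object$model, newdata, .warn_extra = FALSE)
}

#' @export
predict.model_spec <- function(object, newdata, ...) {
  predict_pic50(object, newdata, .warn_extra = FALSE)
}

#' Tidy an MLR fit into a coefficient table
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`.
#' @method tidy mlr_fit
#' @export
tidy.mlr_fit <- function(x, ...) {
  X1 <- cbind(`(Intercept)` = 1, x$X)
  rss <- sum(x$residuals^2)
  sigma2 <- rss / (x$n - x$p - 1L)
  se <- sqrt(diag(chol2inv(chol(crossprod(X1)))) * sigma2)
  est <- c(x$model$intercept, x$model$coefficients)
  tibble(term = colnames(X1), estimate = unname(est),
         std_error = unname(se), statistic = unname(est / se))
}

#' One-row summary of an MLR fit
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `p`, `r2`, `adj_r2`, `rmse`, `mae`.
#' @method glance mlr_fit
#' @export
glance.mlr_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n, p = x$p), fit_statistics(x))
}

#' Per-compound fit diagnostics
#'
#' @param x An `mlr_fit`.
#' @param ... Unused.
#' @return Tibble with `compound_id`, `observed`, `fitted`, `residual`,
#'   `leverage`.
#' @method augment mlr_fit
#' @export
augment.mlr_fit <- function(x, ...) {
  tibble(compound_id = x$compound_ids,
         observed = x$observed,
         fitted = x$fitted_values,
         residual = x$residuals,
         leverage = x$leverages)
}

#' Observed-versus-fitted plot for an MLR fit
#'
#' @param object An `mlr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mlr_fit
#' @export
autoplot.mlr_fit <- function(object, ...) {
  ggplot2::ggplot(augment(object),
                  ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fitted pIC50", y = "Observed pIC50",
                  title = object$model$name) +
    ggplot2::theme_minimal()
}

#' Multivariate correlation K index (QUIK rule)
#'
#' Todeschini's K index summarises the total correlation of a set of
#' columns from the eigenvalues of their correlation matrix:
#' K = sum_j |l_j / sum(l) - 1/p| / (2 (p - 1) / p). It is 0 for mutually
#' orthogonal columns (all eigenvalues equal) and 1 for complete
#' collinearity. The QUIK rule accepts a model only when the K index of
#' the descriptor block *with* the response exceeds that of the block
#' alone by at least a margin dK, rejecting models whose apparent fit is
#' driven by descriptor inter-correlation.
#'
#' @param x A numeric matrix or data frame with at least two non-constant
#'   columns.
#' @return K in `[0, 1]`; invariant under column scaling and permutation.
#' @examples
#' quik_k(matrix(rnorm(40), 20, 2))
#' @export
quik_k <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) abort("need at least two columns", class = "qsardyn_domain")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column has undefined correlation: ",
                 paste(colnames(x)[sds == 0], collapse = ", ")),
          class = "qsardyn_constant_column")
  }
  p <- ncol(x)
  lambda <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  sum(abs(lambda / sum(lambda) - 1 / p)) / (2 * (p - 1) / p)
}
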