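#' Leverage-based applicability domain
#'
#' Computes, for the training compounds of a fitted model, the hat-matrix
#' leverages h_i = x_i' (X'X)^-1 x_i (intercept column included), the
#' warning leverage h* = 3(p+1)/n, and standardized residuals
#' e_i / (RMSE * sqrt(1 - h_i)). Optional query compounds receive a
#' leverage and an in/out-of-domain flag; predictions for compounds with
#' h > h* are extrapolations beyond the descriptor space the model was
#' trained on. Together with the standardized residuals this is the data
#' behind a Williams plot ([autoplot()]).
#'
#' @param fit An [mlr_fit()][fit_mlr] object.
#' @param newdata Optional query descriptor tibble (e.g. the external set
#'   or designed compounds) containing the model's descriptors. If it also
#'   carries the activity column, query standardized residuals are
#'   computed too.
#' @param activity Optional activity column name in `newdata`.
#' @return Object of class `ad_report`: a tibble with one row per
#'   compound (`compound_id`, `set`, `leverage`, `std_residual`,
#'   `high_leverage`, `outlier`, `in_domain`) carrying attributes
#'   `h_star`, `n`, `p`. Standardized-residual outliers use the |z| > 3
#'   rule.
#' @examples
#' sim <- gen_qsar_dataset(preset_study57(seed = 1))
#' fit <- fit_mlr(sim$data, "pIC50", sim$truth$signal_names)
#' ad <- applicability_domain(fit)
#' attr(ad, "h_star")   # 3 * (p + 1) / n
#' @export
applicability_domain <- function(fit, newdata = NULL, activity = NULL) {
  stopifnot(inherits(fit, "mlr_fit"))
  n <- fit$n
  p <- fit$p
  h_star <- 3 * (p + 1) / n
  rmse <- sqrt(sum(fit$residuals^2) / n)
  h_tr <- unname(fit$leverages)
  z_tr <- unname(fit$residuals / (rmse * sqrt(1 - h_tr)))
  out <- tibble(compound_id = fit$compound_ids, set = "train",
                leverage = h_tr, std_residual = z_tr)
  if (!is.null(newdata)) {
    qp <- dt_parts(newdata, activity = activity,
                   descriptors = names(fit$model$coefficients))
    X1 <- cbind(1, fit$X)
    xtx_inv <- chol2inv(chol(crossprod(X1)))
    Q1 <- cbind(1, qp$X)
    h_q <- unname(rowSums((Q1 %*% xtx_inv) * Q1))
    z_q <- rep(NA_real_, length(h_q))
    if (!is.null(qp$y)) {
      yhat <- predict_pic50(fit$model, newdata, .warn_extra = FALSE)
      z_q <- (qp$y - yhat) / (rmse * sqrt(pmax(1 - h_q, .Machine$double.eps)))
    }
    out <- dplyr::bind_rows(out, tibble(compound_id = qp$ids, set = "query",
                                        leverage = h_q, std_residual = z_q))
  }
  out$high_leverage <- out$leverage > h_star
  out$outlier <- !is.na(out$std_residual) & abs(out$std_residual) > 3
  out$in_domain <- !out$high_leverage & !out$outlier
  structure(out, class = c("ad_report", class(out)),
            h_star = h_star, n = n, p = p)
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> h* = %.4f (n = %d, p = %d); %d/%d in domain\n",
              attr(x, "h_star"), attr(x, "n"), attr(x, "p"),
              sum(x$in_domain), nrow(x)))
  NextMethod()
}

#' Williams plot of an applicability-domain report
#'
#' Standardized residuals versus leverage, with the warning leverage h*
#' and the +/-3 residual bands drawn; points outside either boundary are
#' outside the applicability domain.
#'
#' @param object An `ad_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ad_report
#' @export
autoplot.ad_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leverage, y = .data$std_residual,
                                   colour = .data$set)) +
    ggplot2::geom_vline(xintercept = attr(object, "h_star"), linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 3) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "Leverage h", y = "Standardized residual",
                  title = "Williams plot",
                  subtitle = sprintf("h* = %.4f", attr(object, "h_star"))) +
    ggplot2::theme_minimal()
}

#' Write Williams-plot data as CSV
#'
#' @param report An `ad_report`.
#' @param path Output CSV path.
#' @return `report`, invisibly.
#' @export
write_ad_report <- function(report, path) {
  stopifnot(inherits(report, "ad_report"))
  readr::write_csv(as_tibble(report), path, progress = FALSE)
  invisible(report)
}
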