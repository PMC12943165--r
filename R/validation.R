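#' Training-set goodness-of-fit statistics
#'
#' Computes the determination coefficient R2 = 1 - RSS/TSS, its
#' degrees-of-freedom-adjusted form, and the training RMSE and MAE. RMSE
#' uses an n denominator (not n - p - 1), the common QSAR reporting
#' convention.
#'
#' @param fit An [mlr_fit()][fit_mlr] object.
#' @param observed Observed activities; defaults to those stored in `fit`.
#' @return Tibble with `r2`, `adj_r2`, `rmse`, `mae`.
#' @export
fit_statistics <- function(fit, observed = fit$observed) {
  stopifnot(inherits(fit, "mlr_fit"))
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) {
    abort("activity has zero variance: R2 undefined", class = "qsardyn_domain")
  }
  rss <- sum((observed - fit$fitted_values)^2)
  r2 <- 1 - rss / tss
  n <- fit$n
  p <- fit$p
  tibble(r2 = r2,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         rmse = sqrt(rss / n),
         mae = mean(abs(observed - fit$fitted_values)))
}

# PRESS via the hat-matrix shortcut: e_i / (1 - h_ii) are the LOO
# prediction errors of an OLS fit, without refitting.
press_shortcut <- function(fit) {
  d <- 1 - fit$leverages
  if (any(d <= .Machine$double.eps^0.5)) {
    abort("a compound has leverage ~1; LOO prediction undefined",
          class = "qsardyn_singular")
  }
  sum((fit$residuals / d)^2)
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS/TSS, where PRESS sums squared prediction errors for each
#' compound from a model refit without it. The default uses the exact
#' hat-matrix identity e_i/(1 - h_ii) for the deleted residuals;
#' `method = "refit"` performs the n explicit refits (used as a
#' cross-check, the two agree to machine precision).
#'
#' @inheritParams fit_mlr
#' @param method `"shortcut"` (hat-matrix identity) or `"refit"`.
#' @return Q2 (can be negative for models worse than the mean).
#' @export
q2_loo <- function(data, activity, descriptors = NULL,
                   method = c("shortcut", "refit")) {
  method <- match.arg(method)
  parts <- dt_parts(data, activity = activity, descriptors = descriptors,
                    require_activity = TRUE)
  y <- parts$y
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    abort("activity has zero variance: Q2 undefined", class = "qsardyn_domain")
  }
  n <- length(y)
  if (n <= ncol(parts$X) + 2L) {
    abort("too few compounds for leave-one-out validation",
          class = "qsardyn_underdetermined")
  }
  fit <- fit_mlr(data, activity, parts$descriptors)
  if (method == "shortcut") {
    press <- press_shortcut(fit)
  } else {
    press <- 0
    X1 <- cbind(1, parts$X)
    for (i in seq_len(n)) {
      qri <- qr(X1[-i, , drop = FALSE])
      if (qri$rank < ncol(X1)) {
        abort(sprintf("rank-deficient design when leaving out compound %d ('%s')",
                      i, parts$ids[i]), class = "qsardyn_singular")
      }
      beta <- qr.coef(qri, y[-i])
      press <- press + (y[i] - sum(X1[i, ] * beta))^2
    }
  }
  1 - press / tss
}

#' Leave-many-out cross-validated Q2
#'
#' Repeats a grouped cross-validation: compounds are randomly partitioned
#' into leave-out groups of `group_size`, each group is predicted from a
#' model refit on the rest, and Q2 = 1 - PRESS/TSS is computed for the
#' partition; the mean over `repeats` partitions is returned. With
#' `group_size = 1` a single repeat reproduces leave-one-out exactly.
#'
#' @inheritParams q2_loo
#' @param group_size Compounds left out per group (1 <= group_size < n/2);
#'   `NULL` uses ceiling(n/5) (roughly 5 folds).
#' @param repeats Number of random partitions to average over.
#' @param seed Integer seed for the partitioning.
#' @return Mean Q2 across repeats.
#' @export
q2_lmo <- function(data, activity, descriptors = NULL, group_size = NULL,
                   repeats = 50, seed = 1L) {
  parts <- dt_parts(data, activity = activity, descriptors = descriptors,
                    require_activity = TRUE)
  y <- parts$y
  n <- length(y)
  group_size <- group_size %||% ceiling(n / 5)
  if (!is_count(group_size) || group_size < 1 || group_size >= n / 2) {
    abort("group_size must satisfy 1 <= group_size < n/2",
          class = "qsardyn_domain")
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("activity has zero variance", class = "qsardyn_domain")
  X1 <- cbind(1, parts$X)
  q2s <- with_seed(seed, vapply(seq_len(repeats), function(r) {
    ord <- sample.int(n)
    groups <- split(ord, ceiling(seq_along(ord) / group_size))
    press <- 0
    for (g in groups) {
      qri <- qr(X1[-g, , drop = FALSE])
      if (qri$rank < ncol(X1)) {
        abort("rank-deficient design in a leave-many-out fold",
              class = "qsardyn_singular")
      }
      beta <- qr.coef(qri, y[-g])
      press <- press + sum((y[g] - X1[g, , drop = FALSE] %*% beta)^2)
    }
    1 - press / tss
  }, numeric(1)))
  mean(q2s)
}

#' Y-scrambling (response permutation) test
#'
#' Refits the model on the same descriptor subset after permuting the
#' activity vector, `n_permutations` times (identity permutation
#' excluded), and reports the mean scrambled R2 and mean scrambled
#' leave-one-out Q2. A real structure-activity relationship collapses
#' under scrambling; mean scrambled R2 well below the unscrambled value
#' (OECD practice: below 0.20) rules out chance correlation. When the
#' number of distinct non-identity permutations does not exceed
#' `n_permutations` (tiny n), all of them are enumerated exactly instead
#' of sampled.
#'
#' @inheritParams q2_loo
#' @param n_permutations Number of permutations (>= 10).
#' @param seed Integer seed.
#' @return Object of class `y_scramble`: list with `r2_yscr`, `q2_yscr`
#'   (means over permutations) and `permutations`, a tibble of
#'   per-permutation `r2` and `q2`. [tidy()] returns the per-permutation
#'   tibble; [glance()] the two means.
#' @export
y_scramble <- function(data, activity, descriptors = NULL,
                       n_permutations = 100, seed = 1L) {
  if (!is_count(n_permutations) || n_permutations < 10) {
    abort("n_permutations must be an integer >= 10", class = "qsardyn_domain")
  }
  parts <- dt_parts(data, activity = activity, descriptors = descriptors,
                    require_activity = TRUE)
  y <- parts$y
  n <- length(y)
  if (n <= ncol(parts$X) + 2L) {
    abort("too few compounds to refit scrambled models",
          class = "qsardyn_underdetermined")
  }
  X1 <- cbind(1, parts$X)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) {
    abort("singular design", class = "qsardyn_singular")
  }
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  h <- rowSums(Q^2)
  tss_den <- function(v) sum((v - mean(v))^2)
  perms <- enumerate_or_sample_perms(n, n_permutations, seed)
  stats <- purrr::map(perms, function(pi) {
    yp <- y[pi]
    fitted <- Q %*% crossprod(Q, yp)
    e <- yp - fitted
    rss <- sum(e^2)
    tss <- tss_den(yp)
    press <- sum((e / (1 - h))^2)
    tibble(r2 = 1 - rss / tss, q2 = 1 - press / tss)
  })
  per <- dplyr::bind_rows(stats)
  per$permutation <- seq_len(nrow(per))
  structure(list(r2_yscr = mean(per$r2),
                 q2_yscr = mean(per$q2),
                 permutations = per[c("permutation", "r2", "q2")],
                 n_permutations = nrow(per),
                 exhaustive = length(perms) < n_permutations ||
                   factorial(n) - 1 <= n_permutations,
                 seed = seed),
            class = "y_scramble")
}

# All non-identity permutations when few enough, otherwise seeded draws
# (identity redrawn away).
enumerate_or_sample_perms <- function(n, n_permutations, seed) {
  if (n <= 7 && factorial(n) - 1 <= n_permutations) {
    all_perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      purrr::flatten(lapply(seq_along(v), function(i) {
        lapply(all_perms(v[-i]), function(rest) c(v[i], rest))
      }))
    }
    ps <- all_perms(seq_len(n))
    return(ps[!vapply(ps, function(p) all(p == seq_len(n)), logical(1))])
  }
  with_seed(seed, {
    lapply(seq_len(n_permutations), function(i) {
      repeat {
        p <- sample.int(n)
        if (!all(p == seq_len(n))) return(p)
      }
    })
  })
}

#' @export
print.y_scramble <- function(x, ...) {
  cat(sprintf("<y_scramble> %d permutations%s\n", x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  mean scrambled R2 = %.4f\n  mean scrambled Q2 = %.4f\n",
              x$r2_yscr, x$q2_yscr))
  invisible(x)
}

#' @method tidy y_scramble
#' @export
tidy.y_scramble <- function(x, ...) x$permutations

#' @method glance y_scramble
#' @export
glance.y_scramble <- function(x, ...) {
  tibble(r2_yscr = x$r2_yscr, q2_yscr = x$q2_yscr,
         n_permutations = x$n_permutations)
}

#' External-set prediction metrics
#'
#' Computes the external determination coefficient in the Q2F1 convention,
#' R2ext = 1 - sum((y - yhat)^2) / sum((y - ybar_train)^2), where the
#' reference mean is the *training* activity mean; Lin's concordance
#' correlation coefficient CCC = 2 s_oy / (s_o^2 + s_y^2 + (obar - ybar)^2)
#' with n-denominator (co)variances; and external RMSE/MAE. The squared
#' Pearson correlation between observed and predicted is also reported,
#' since conventions differ across the QSAR literature.
#'
#' @param model A `model_spec` or `mlr_fit`.
#' @param data External-set descriptor tibble containing the activity
#'   column.
#' @param activity Name of the activity column.
#' @param train_activity_mean Mean activity of the training set (the Q2F1
#'   reference).
#' @return Tibble with `r2_ext`, `ccc_ext`, `rmse_ext`, `mae_ext`,
#'   `r2_pearson_ext`.
#' @export
external_metrics <- function(model, data, activity, train_activity_mean) {
  if (inherits(model, "mlr_fit")) model <- model$model
  stopifnot(inherits(model, "model_spec"))
  parts <- dt_parts(data, activity = activity, require_activity = TRUE)
  if (length(parts$y) == 0L) {
    abort("external set is empty", class = "qsardyn_empty")
  }
  yhat <- predict_pic50(model, data, .warn_extra = FALSE)
  y <- parts$y
  e <- y - yhat
  r2_ext <- 1 - sum(e^2) / sum((y - train_activity_mean)^2)
  m <- length(y)
  s_o <- mean((y - mean(y))^2)
  s_p <- mean((yhat - mean(yhat))^2)
  s_op <- mean((y - mean(y)) * (yhat - mean(yhat)))
  ccc <- 2 * s_op / (s_o + s_p + (mean(y) - mean(yhat))^2)
  pear <- if (s_o > 0 && s_p > 0) cor(y, yhat)^2 else NA_real_
  tibble(r2_ext = r2_ext, ccc_ext = ccc,
         rmse_ext = sqrt(mean(e^2)), mae_ext = mean(abs(e)),
         r2_pearson_ext = pear)
}

#' Roy's rm2 external-validation metrics
#'
#' Penalizes divergence between the ordinary squared correlation of
#' observed and predicted values (r2) and its through-origin counterpart
#' (r0^2): rm2 = r2 * (1 - sqrt(r2 - r0^2)), computed with observed
#' regressed on predicted; the primed variant swaps the axes. The average
#' of the two and the absolute difference between them are returned; a
#' small difference indicates axis-symmetric agreement. The difference
#' r2 - r0^2 is clamped at zero before the square root (it can go
#' negative by rounding when the through-origin line coincides with the
#' free fit). Computed on unscaled data.
#'
#' @param observed,predicted Numeric vectors of length >= 3, both
#'   non-constant.
#' @return Tibble with `r2m`, `r2m_prime`, `r2m_avg`, `delta_r2m`.
#' @export
rm2_metrics <- function(observed, predicted) {
  if (length(observed) < 3L || length(observed) != length(predicted)) {
    abort("need >= 3 paired points", class = "qsardyn_domain")
  }
  if (sd(observed) == 0 || sd(predicted) == 0) {
    abort("observed and predicted must both be non-constant",
          class = "qsardyn_domain")
  }
  r2 <- cor(observed, predicted)^2
  r0sq <- function(yy, xx) {
    k <- sum(yy * xx) / sum(xx^2)
    1 - sum((yy - k * xx)^2) / sum((yy - mean(yy))^2)
  }
  rm2_one <- function(yy, xx) {
    r2 * (1 - sqrt(pmax(r2 - r0sq(yy, xx), 0)))
  }
  rm2 <- rm2_one(observed, predicted)
  rm2p <- rm2_one(predicted, observed)
  tibble(r2m = rm2, r2m_prime = rm2p,
         r2m_avg = (rm2 + rm2p) / 2, delta_r2m = abs(rm2 - rm2p))
}

#' Full OECD validation battery for a fitted QSAR model
#'
#' Assembles, for one descriptor subset, the internal statistics (R2,
#' adjusted R2, Q2 leave-one-out, Q2 leave-many-out, training RMSE/MAE),
#' the Y-scrambling permutation null (mean scrambled R2 and Q2), and —
#' when an external partition is supplied — the external metrics (Q2F1,
#' CCC, RMSE, MAE, rm2 average and delta).
#'
#' @inheritParams q2_loo
#' @param split Optional tibble from [make_split()]; when given, the model
#'   is fit on the training partition and externally validated on the
#'   rest. When `NULL`, all compounds train and external fields are `NA`.
#' @param n_permutations Permutations for [y_scramble()].
#' @param lmo_group_size,lmo_repeats Settings for [q2_lmo()].
#' @param seed Integer seed driving scrambling and LMO partitioning.
#' @return Object of class `validation_report`. [glance()] returns the
#'   one-row metric tibble; [tidy()] a long (metric, value) table.
#' @examples
#' sim <- gen_qsar_dataset(preset_study57(seed = 1))
#' sp <- make_split(sim$data, 10, activity = "pIC50")
#' rep <- validate_model(sim$data, "pIC50", sim$truth$signal_names,
#'                       split = sp, n_permutations = 20, lmo_repeats = 5)
#' glance(rep)
#' @export
validate_model <- function(data, activity, descriptors, split = NULL,
                           n_permutations = 100, lmo_group_size = NULL,
                           lmo_repeats = 50, seed = 1L) {
  if (!is.null(split)) {
    ids <- dt_parts(data, activity = activity)$ids
    train_ids <- split$compound_id[split$partition == "train"]
    ext_ids <- split$compound_id[split$partition == "external"]
    train <- data[ids %in% train_ids, , drop = FALSE]
    ext <- data[ids %in% ext_ids, , drop = FALSE]
  } else {
    train <- data
    ext <- NULL
  }
  fit <- fit_mlr(train, activity, descriptors)
  internal <- fit_statistics(fit)
  q2l <- q2_loo(train, activity, descriptors)
  q2m <- q2_lmo(train, activity, descriptors, group_size = lmo_group_size,
                repeats = lmo_repeats, seed = seed)
  scr <- y_scramble(train, activity, descriptors,
                    n_permutations = n_permutations, seed = seed)
  ext_metrics <- tibble(r2_ext = NA_real_, ccc_ext = NA_real_,
                        rmse_ext = NA_real_, mae_ext = NA_real_,
                        r2_pearson_ext = NA_real_)
  rm2 <- tibble(r2m_avg = NA_real_, delta_r2m = NA_real_)
  if (!is.null(ext) && nrow(ext) > 0L) {
    ext_metrics <- external_metrics(fit$model, ext, activity,
                                    mean(fit$observed))
    yhat_ext <- predict_pic50(fit$model, ext, .warn_extra = FALSE)
    y_ext <- dt_parts(ext, activity = activity,
                      require_activity = TRUE)$y
    if (length(y_ext) >= 3L && sd(y_ext) > 0 && sd(yhat_ext) > 0) {
      rm2 <- rm2_metrics(y_ext, yhat_ext)[c("r2m_avg", "delta_r2m")]
    }
  }
  metrics <- dplyr::bind_cols(
    internal[c("r2", "adj_r2")],
    tibble(q2_loo = q2l, q2_lmo = q2m),
    tibble(rmse_train = internal$rmse, mae_train = internal$mae),
    tibble(r2_yscr = scr$r2_yscr, q2_yscr = scr$q2_yscr),
    ext_metrics[c("r2_ext", "ccc_ext", "rmse_ext", "mae_ext")],
    rm2
  )
  structure(list(metrics = metrics,
                 fit = fit,
                 scramble = scr,
                 settings = list(n_permutations = scr$n_permutations,
                                 lmo_group_size = lmo_group_size %||%
                                   ceiling(fit$n / 5),
                                 lmo_repeats = lmo_repeats,
                                 seed = seed,
                                 rmse_denominator = "n",
                                 r2_ext_convention = "Q2F1 (training-mean reference)")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) x$metrics

#' Long-format validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value`, and the OECD guideline
#'   `threshold` where one is conventional.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  thresholds <- c(r2 = "> 0.60", adj_r2 = "close to R2", q2_loo = "> 0.50",
                  q2_lmo = "> 0.60", rmse_train = "lower is better",
                  mae_train = "lower is better", r2_yscr = "< 0.20",
                  q2_yscr = "< 0.20", r2_ext = "> 0.60", ccc_ext = "> 0.85",
                  rmse_ext = "lower is better", mae_ext = "lower is better",
                  r2m_avg = "> 0.50", delta_r2m = "< 0.20")
  long <- tidyr::pivot_longer(x$metrics, dplyr::everything(),
                              names_to = "metric", values_to = "value")
  long$threshold <- unname(thresholds[long$metric])
  long
}

#' Serialize a validation report
#'
#' Writes the metric battery as JSON (with settings) or as a flat
#' two-column CSV of metric labels and values.
#'
#' @param report A `validation_report`.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(metrics = as.list(report$metrics),
                              settings = report$settings),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tidy(report), path, progress = FALSE)
  }
  invisible(report)
}
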