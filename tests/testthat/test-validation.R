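test_that("fit statistics match hand-computed anchors", {
  # perfect fit
  d <- tibble::tibble(compound_id = paste0("c", 1:8),
                      x = as.numeric(1:8), pIC50 = 2 + 3 * (1:8))
  fit <- fit_mlr(d, "pIC50")
  fs <- fit_statistics(fit)
  expect_equal(unlist(fs), c(r2 = 1, adj_r2 = 1, rmse = 0, mae = 0),
               tolerance = 1e-10)

  # 5-point worked example, RSS/TSS by hand
  y <- c(1, 2, 3, 5, 9)
  x <- c(1, 2, 3, 4, 5)
  d5 <- tibble::tibble(compound_id = paste0("c", 1:5), x = x, pIC50 = y)
  f5 <- fit_mlr(d5, "pIC50")
  beta <- ols_normal_equations(cbind(x), y)
  res <- y - (beta[1] + beta[2] * x)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  fs5 <- fit_statistics(f5)
  expect_equal(fs5$r2, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(fs5$adj_r2, 1 - (1 - fs5$r2) * 4 / 3, tolerance = 1e-12)
  expect_equal(fs5$rmse, sqrt(rss / 5), tolerance = 1e-12)
  expect_equal(fs5$mae, mean(abs(res)), tolerance = 1e-12)

  # null model: fitted = mean -> R2 = 0
  dn <- tibble::tibble(compound_id = paste0("c", 1:10),
                       x = rep(c(0, 1), 5), pIC50 = rep(c(2, 4, 6, 8, 10), 2))
  fn <- fit_mlr(dn, "pIC50")
  expect_equal(fit_statistics(fn)$r2, 0, tolerance = 1e-10)
})

test_that("Q2(LOO) shortcut equals explicit refits and respects bounds", {
  # noiseless linear data: every deleted refit is exact
  d <- tibble::tibble(compound_id = paste0("c", 1:20),
                      x = as.numeric(1:20), pIC50 = 0.5 + 1.5 * (1:20))
  expect_equal(q2_loo(d, "pIC50"), 1, tolerance = 1e-10)

  for (seed in 1:20) {
    pr <- random_problem(8 + seed %% 5, 2, seed = seed + 50)
    s <- q2_loo(pr$data, "pIC50")
    r <- q2_loo(pr$data, "pIC50", method = "refit")
    expect_equal(s, r, tolerance = 1e-10)
    oracle <- 1 - loo_press_refit(pr$X, pr$y) /
      sum((pr$y - mean(pr$y))^2)
    expect_equal(s, oracle, tolerance = 1e-10)
    # PRESS >= RSS, so Q2 <= R2 on the same data
    fit <- fit_mlr(pr$data, "pIC50")
    expect_lte(s, fit_statistics(fit)$r2 + 1e-12)
  }

  flat <- tibble::tibble(compound_id = paste0("c", 1:10),
                         x = rnorm(10), pIC50 = rep(1, 10))
  expect_error(q2_loo(flat, "pIC50"), class = "qsardyn_domain")
})

test_that("LMO degenerates to LOO and is seeded", {
  pr <- random_problem(14, 2, seed = 77)
  expect_equal(q2_lmo(pr$data, "pIC50", group_size = 1, repeats = 1),
               q2_loo(pr$data, "pIC50"), tolerance = 1e-12)

  d <- tibble::tibble(compound_id = paste0("c", 1:20),
                      x = as.numeric(1:20), pIC50 = 3 - 2 * (1:20))
  expect_equal(q2_lmo(d, "pIC50", group_size = 4, repeats = 3), 1,
               tolerance = 1e-10)

  a <- q2_lmo(pr$data, "pIC50", group_size = 3, repeats = 10, seed = 5)
  b <- q2_lmo(pr$data, "pIC50", group_size = 3, repeats = 10, seed = 5)
  expect_identical(a, b)
  expect_error(q2_lmo(pr$data, "pIC50", group_size = 7),
               class = "qsardyn_domain")
})

test_that("Y-scrambling enumerates tiny cases and collapses real signal", {
  # n = 4: 23 non-identity permutations, enumerated exactly
  withr::with_seed(1, {
    d4 <- tibble::tibble(compound_id = paste0("c", 1:4),
                         x = rnorm(4), pIC50 = rnorm(4))
  })
  scr4 <- y_scramble(d4, "pIC50", n_permutations = 100, seed = 1)
  expect_equal(scr4$n_permutations, 23)
  expect_true(scr4$exhaustive)

  sim <- gen_qsar_dataset(preset_study57(seed = 4))
  sp <- make_split(sim$data, 10, activity = "pIC50")
  train <- sim$data[sp$partition == "train", ]
  scr <- y_scramble(train, "pIC50", sim$truth$signal_names,
                    n_permutations = 100, seed = 4)
  expect_lt(scr$r2_yscr, 0.20)
  expect_lt(scr$q2_yscr, 0.20)
  fit <- fit_mlr(train, "pIC50", sim$truth$signal_names)
  expect_lt(scr$r2_yscr, fit_statistics(fit)$r2 - 0.3)
  expect_equal(nrow(tidy(scr)), 100)
  expect_identical(glance(scr)$r2_yscr, scr$r2_yscr)
})

test_that("Y-scrambling null calibration: E[R2] ~ k/(n-1) for noise response", {
  n <- 30; k <- 3
  withr::with_seed(8, {
    d <- dplyr::bind_cols(
      tibble::tibble(compound_id = paste0("c", seq_len(n))),
      tibble::as_tibble(matrix(rnorm(n * k), n, k,
                               dimnames = list(NULL, paste0("d", 1:k)))),
      tibble::tibble(pIC50 = rnorm(n)))
  })
  scr <- y_scramble(d, "pIC50", n_permutations = 500, seed = 9)
  # null R2 ~ Beta(k/2, (n-k-1)/2): mean k/(n-1), sd ~ 0.077; the mean of
  # 500 permutations should sit well within a few SE of the theory value
  expect_lt(abs(scr$r2_yscr - k / (n - 1)), 0.03)
  # a pure-noise response is itself a single draw from the same null
  # (single-draw sd ~ 0.077, so allow a 2-sigma band)
  fit <- fit_mlr(d, "pIC50")
  expect_lt(abs(scr$r2_yscr - fit_statistics(fit)$r2), 0.16)
})

test_that("external metrics hit their degenerate anchors", {
  m <- model_spec("m", 0, c(x = 1))
  d <- tibble::tibble(compound_id = paste0("c", 1:6),
                      x = c(1, 2, 3, 4, 5, 6.5),
                      pIC50 = c(1, 2, 3, 4, 5, 6.5))
  em <- external_metrics(m, d, "pIC50", train_activity_mean = 3)
  expect_equal(unlist(em[c("r2_ext", "ccc_ext", "rmse_ext", "mae_ext")]),
               c(r2_ext = 1, ccc_ext = 1, rmse_ext = 0, mae_ext = 0),
               tolerance = 1e-12)

  # constant prediction at the training mean -> r2_ext = 0
  m0 <- model_spec("null", 3, c(x = 0))
  em0 <- external_metrics(m0, d, "pIC50", train_activity_mean = 3)
  expect_equal(em0$r2_ext, 0, tolerance = 1e-12)

  # constant shift: Pearson r = 1 but CCC < 1
  mshift <- model_spec("shift", 1.5, c(x = 1))
  ems <- external_metrics(mshift, d, "pIC50", train_activity_mean = 3)
  expect_equal(ems$r2_pearson_ext, 1, tolerance = 1e-12)
  expect_lt(ems$ccc_ext, 1)
})

test_that("|CCC| never exceeds |Pearson r|", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      y <- rnorm(12)
      yhat <- 0.5 * y + rnorm(12, sd = 0.5) + 0.3
    })
    d <- tibble::tibble(compound_id = paste0("c", 1:12), x = yhat, pIC50 = y)
    em <- external_metrics(model_spec("id", 0, c(x = 1)), d, "pIC50", mean(y))
    expect_lte(abs(em$ccc_ext), abs(stats::cor(y, yhat)) + 1e-12)
  }
})

test_that("rm2 metrics follow Roy's formulas", {
  y <- c(1, 2, 3, 4)
  expect_equal(unlist(rm2_metrics(y, y)),
               c(r2m = 1, r2m_prime = 1, r2m_avg = 1, delta_r2m = 0),
               tolerance = 1e-12)

  # proportional prediction: the through-origin line is the free fit,
  # r0^2 = r^2, so rm2 = r2
  obs <- c(1, 2, 3, 5)
  pred <- 2 * obs
  rm <- rm2_metrics(obs, pred)
  r2 <- stats::cor(obs, pred)^2
  expect_equal(rm$r2m, r2, tolerance = 1e-10)

  # 4-point worked pair against independent arithmetic
  o <- c(5.1, 6.0, 6.9, 7.4)
  p <- c(5.4, 5.8, 7.2, 7.0)
  r2h <- stats::cor(o, p)^2
  k1 <- sum(o * p) / sum(p^2)
  r01 <- 1 - sum((o - k1 * p)^2) / sum((o - mean(o))^2)
  k2 <- sum(o * p) / sum(o^2)
  r02 <- 1 - sum((p - k2 * o)^2) / sum((p - mean(p))^2)
  rm2a <- r2h * (1 - sqrt(max(r2h - r01, 0)))
  rm2b <- r2h * (1 - sqrt(max(r2h - r02, 0)))
  got <- rm2_metrics(o, p)
  expect_equal(got$r2m, rm2a, tolerance = 1e-12)
  expect_equal(got$r2m_prime, rm2b, tolerance = 1e-12)
  expect_equal(got$r2m_avg, (rm2a + rm2b) / 2, tolerance = 1e-12)
  expect_equal(got$delta_r2m, abs(rm2a - rm2b), tolerance = 1e-12)

  expect_error(rm2_metrics(c(1, 1, 1), c(1, 2, 3)), class = "qsardyn_domain")
})

test_that("coefficients are recovered and interval coverage is nominal", {
  # noiseless: exact recovery
  spec0 <- qsar_sim_spec(n_compounds = 57, n_noise = 0, noise_sigma = 0,
                         seed = 21)
  sim0 <- gen_qsar_dataset(spec0)
  fit0 <- fit_mlr(sim0$data, "pIC50", sim0$truth$signal_names)
  expect_equal(fit0$model$coefficients,
               sim0$truth$true_model$coefficients, tolerance = 1e-8)
  expect_equal(fit0$model$intercept, sim0$truth$true_model$intercept,
               tolerance = 1e-8)

  # at the study noise level, +/- 2 SE intervals cover ~95% of truths
  truth <- qsar_sim_spec(seed = 1)$true_model
  covered <- 0L; total <- 0L
  for (rep in 1:200) {
    sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 47, n_noise = 0,
                                          target_r2 = 0.83, seed = 1000 + rep))
    fit <- fit_mlr(sim$data, "pIC50", sim$truth$signal_names)
    td <- tidy(fit)
    tr <- c(truth$intercept, truth$coefficients)
    hit <- abs(td$estimate - tr) <= 2 * td$std_error
    covered <- covered + sum(hit)
    total <- total + length(hit)
  }
  expect_gt(covered / total, 0.90)
  expect_lt(covered / total, 0.985)
})

test_that("the assembled validation report is complete and order-invariant", {
  sim <- gen_qsar_dataset(preset_study57(seed = 6))
  sp <- make_split(sim$data, 10, activity = "pIC50")
  rep <- validate_model(sim$data, "pIC50", sim$truth$signal_names,
                        split = sp, n_permutations = 20, lmo_repeats = 5,
                        seed = 2)
  g <- glance(rep)
  expect_named(g, c("r2", "adj_r2", "q2_loo", "q2_lmo", "rmse_train",
                    "mae_train", "r2_yscr", "q2_yscr", "r2_ext", "ccc_ext",
                    "rmse_ext", "mae_ext", "r2m_avg", "delta_r2m"))
  expect_true(all(is.finite(unlist(g))))
  expect_lte(g$q2_loo, g$r2)
  expect_lte(g$adj_r2, g$r2)

  # shuffling compounds does not change any metric
  perm <- withr::with_seed(3, sample.int(nrow(sim$data)))
  rep2 <- validate_model(sim$data[perm, ], "pIC50",
                         sim$truth$signal_names, split = sp,
                         n_permutations = 20, lmo_repeats = 5, seed = 2)
  fixed <- c("r2", "adj_r2", "q2_loo", "rmse_train", "mae_train",
             "r2_ext", "ccc_ext", "rmse_ext", "mae_ext", "r2m_avg",
             "delta_r2m")
  expect_equal(glance(rep2)[fixed], g[fixed], tolerance = 1e-10)

  td <- tidy(rep)
  expect_equal(nrow(td), 14)
  expect_true("threshold" %in% names(td))

  tj <- withr::local_tempfile(fileext = ".json")
  tc <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep, tj)
  write_validation_report(rep, tc)
  expect_equal(jsonlite::read_json(tj)$metrics$r2, g$r2, tolerance = 1e-12)
  expect_equal(nrow(readr::read_csv(tc, show_col_types = FALSE)), 14)
})
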