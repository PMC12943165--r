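test_that("descriptor tables round-trip through CSV to high precision", {
  tf <- withr::local_tempfile(fileext = ".csv")
  d <- tibble::tibble(compound_id = c("a", "b", "c"),
                      d1 = c(1.123456789012345, 2e-7, -3.5),
                      d2 = c(pi, exp(1), sqrt(2)))
  write_descriptor_table(d, tf)
  back <- read_descriptor_table(tf)
  expect_identical(names(back), names(d))
  expect_identical(back$compound_id, d$compound_id)
  expect_equal(as.matrix(back[-1]), as.matrix(d[-1]), tolerance = 1e-12)

  sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 20, n_noise = 8,
                                        seed = 4))
  write_descriptor_table(sim$data, tf)
  back <- read_descriptor_table(tf, activity_column = "pIC50")
  expect_equal(as.matrix(back[-1]), as.matrix(sim$data[-1]),
               tolerance = 1e-12)
})

test_that("malformed CSV inputs fail with informative parse errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,d1,d1", "a,1,2", "b,3,4"), tf)
  expect_error(read_descriptor_table(tf), "d1",
               class = "qsardyn_dup_name")

  writeLines(c("id,d1,d2", "a,1,x", "b,3,4"), tf)
  expect_error(read_descriptor_table(tf), class = "qsardyn_parse")

  writeLines(c("id,d1,d2", "a,1", "b,3,4"), tf)
  expect_error(read_descriptor_table(tf), class = "qsardyn_parse")

  writeLines(c("id,d1,d2", "a,1,2", "a,3,4"), tf)
  expect_error(read_descriptor_table(tf), class = "qsardyn_dup_id")

  writeLines(c("id,d1,d2", "a,1,2", "b,3,4"), tf)
  expect_error(read_descriptor_table(tf, activity_column = "missing"),
               class = "qsardyn_missing_column")
})

test_that("a 57-compound activity-bearing fixture reads as n = 57, p = 4", {
  tf <- withr::local_tempfile(fileext = ".csv")
  sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 57, n_noise = 0,
                                        seed = 2))
  write_descriptor_table(sim$data, tf)
  tab <- read_descriptor_table(tf, activity_column = "pIC50")
  expect_equal(nrow(tab), 57)
  expect_setequal(setdiff(names(tab), c("compound_id", "pIC50")),
                  sim$truth$signal_names)
  expect_length(setdiff(names(tab), c("compound_id", "pIC50")), 4)
})

test_that("IC50 converts to pIC50 on the molar negative-log scale", {
  expect_equal(ic50_to_pic50(1, "uM"), 6)
  expect_equal(ic50_to_pic50(10, "nM"), 8)
  expect_equal(ic50_to_pic50(0.05, "uM"), 7.3010, tolerance = 1e-4)
  expect_equal(ic50_to_pic50(1, "M"), 0)
  expect_equal(ic50_to_pic50(1, "mM"), 3)
  # strictly decreasing in concentration, consistent across units
  x <- sort(runif(20, 0.01, 100))
  expect_true(all(diff(ic50_to_pic50(x, "uM")) < 0))
  expect_equal(ic50_to_pic50(1, "uM"), ic50_to_pic50(1000, "nM"))
  expect_error(ic50_to_pic50(0, "uM"), class = "qsardyn_domain")
  expect_error(ic50_to_pic50(-1, "nM"), class = "qsardyn_domain")
  expect_warning(ic50_to_pic50(1), class = "qsardyn_unit_assumed")
})

test_that("splits partition the compounds exactly", {
  sim <- gen_qsar_dataset(preset_study57(seed = 1))
  sp <- make_split(sim$data, 10, activity = "pIC50")
  expect_equal(sum(sp$partition == "train"), 47)
  expect_equal(sum(sp$partition == "external"), 10)
  expect_setequal(sp$compound_id, sim$data$compound_id)

  # partition property across sizes and strategies
  for (ec in c(0, 1, 5, 19)) {
    for (strat in c("sorted_stride", "random")) {
      small <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 20, n_noise = 2,
                                              seed = 9))$data
      sp2 <- make_split(small, ec, strategy = strat, activity = "pIC50",
                        seed = 3)
      expect_equal(sum(sp2$partition == "external"), ec)
      expect_equal(nrow(sp2), 20)
      expect_false(anyDuplicated(sp2$compound_id) > 0)
    }
  }
})

test_that("split strategies are deterministic and guard their inputs", {
  sim <- gen_qsar_dataset(preset_study57(seed = 2))
  a <- make_split(sim$data, 10, strategy = "random", seed = 42)
  b <- make_split(sim$data, 10, strategy = "random", seed = 42)
  expect_identical(a, b)
  c <- make_split(sim$data, 10, strategy = "random", seed = 43)
  expect_false(identical(a, c))

  no_act <- dplyr::select(sim$data, -"pIC50")
  expect_error(make_split(no_act, 10), class = "qsardyn_domain")
  expect_error(make_split(sim$data, 57, activity = "pIC50"),
               class = "qsardyn_domain")
  expect_error(make_split(sim$data, -1, activity = "pIC50"),
               class = "qsardyn_domain")
})

test_that("split files round-trip", {
  sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 15, n_noise = 2,
                                        seed = 5))
  sp <- make_split(sim$data, 3, activity = "pIC50")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_split(sp, tf)
  expect_equal(as.data.frame(read_split(tf)), as.data.frame(sp))
})
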