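random_traj <- function(n_frames, n_sites, seed, thermal = 0.4) {
  gen_trajectory(traj_sim_spec(
    n_sites = n_sites, n_frames = n_frames,
    modes = list(traj_mode(seq_len(n_sites) / n_sites, amplitude = 1.3),
                 traj_mode(rep_len(c(1, -1), n_sites), amplitude = 0.6,
                           direction = c(0, 1, 1), noise = TRUE)),
    thermal_sigma = thermal, seed = seed))
}

test_that("multi-frame XYZ files round-trip and reject malformed frames", {
  tr <- random_traj(4, 3, seed = 1)
  tf <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, tf)
  back <- read_xyz_trajectory(tf)
  expect_identical(back$labels, tr$labels)
  expect_equal(back$coords, tr$coords, tolerance = 1e-8)

  # frame 2 with the wrong atom count
  lines <- c("3", "f1", "A 0 0 0", "B 1 0 0", "C 0 1 0",
             "2", "f2", "A 0 0 0", "B 1 0 0")
  writeLines(lines, tf)
  expect_error(read_xyz_trajectory(tf), "frame 2", class = "qsardyn_parse")

  writeLines(c("2", "f1", "A 0 0 0", "B 1 notanumber 0"), tf)
  expect_error(read_xyz_trajectory(tf), class = "qsardyn_parse")

  writeLines(character(0), tf)
  expect_error(read_xyz_trajectory(tf), class = "qsardyn_parse")
})

test_that("Kabsch superposition nulls rigid motions and is symmetric", {
  withr::with_seed(7, {
    ref <- matrix(rnorm(30), 10, 3)
  })
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)

  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- ref %*% R + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$coords, ref, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  withr::with_seed(8, {
    other <- ref + matrix(rnorm(30, sd = 0.5), 10, 3)
  })
  expect_equal(kabsch_superpose(other, ref)$rmsd,
               kabsch_superpose(ref, other)$rmsd, tolerance = 1e-10)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]),
               class = "qsardyn_domain")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "qsardyn_domain")
})

test_that("Kabsch RMSD matches a numeric-minimisation oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- matrix(rnorm(30), 10, 3)
      B <- matrix(rnorm(30), 10, 3)
    })
    ours <- kabsch_superpose(A, B)$rmsd
    oracle <- rmsd_minimize_oracle(A, B)
    expect_equal(ours, oracle, tolerance = 1e-4)
    expect_lte(ours, oracle + 1e-8)  # SVD optimum can never be beaten
  }
})

test_that("RMSD series anchors: self, static, and pure translation", {
  tr <- random_traj(20, 6, seed = 3)
  rs <- rmsd_series(tr, reference_frame = 1)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-10)
  expect_equal(nrow(rs), 20)

  static <- gen_trajectory(traj_sim_spec(n_sites = 4, n_frames = 6))
  expect_equal(rmsd_series(static)$rmsd, rep(0, 6), tolerance = 1e-12)

  # translate frame 2 by (3, 4, 0): unsuperposed RMSD is the 3-4-5 diagonal
  coords <- static$coords
  coords[2, , 1] <- coords[2, , 1] + 3
  coords[2, , 2] <- coords[2, , 2] + 4
  shifted <- trajectory(coords, static$labels)
  expect_equal(rmsd_series(shifted, superpose = FALSE)$rmsd[2], 5,
               tolerance = 1e-12)
  expect_equal(rmsd_series(shifted, superpose = TRUE)$rmsd[2], 0,
               tolerance = 1e-10)

  # superposed RMSD never exceeds unsuperposed, framewise
  tr2 <- random_traj(15, 8, seed = 9)
  expect_true(all(rmsd_series(tr2, superpose = TRUE)$rmsd <=
                    rmsd_series(tr2, superpose = FALSE)$rmsd + 1e-10))
  expect_error(rmsd_series(tr2, reference_frame = 99),
               class = "qsardyn_domain")
})

test_that("RMSF matches its closed forms", {
  # one site alternating +/- d about its mean: RMSF = d
  coords <- array(0, c(10, 4, 3))
  coords[, 2, 1] <- 4   # static offsets for the other sites
  coords[, 3, 2] <- 8
  coords[, 4, 1] <- -4
  d <- 1.7
  coords[, 1, 1] <- rep(c(d, -d), 5)
  tr <- trajectory(coords)
  out <- rmsf(tr, superpose = FALSE)
  expect_equal(out$rmsf[1], d, tolerance = 1e-12)
  expect_equal(out$rmsf[2:4], rep(0, 3), tolerance = 1e-12)

  # sinusoidal mode: RMS of a sine is amplitude / sqrt(2)
  amp <- 2.4
  sp <- traj_sim_spec(n_sites = 3, n_frames = 10000,
                      modes = list(traj_mode(c(1, 0, 0), amplitude = amp)))
  got <- rmsf(gen_trajectory(sp), superpose = FALSE)$rmsf[1]
  expect_equal(got, amp / sqrt(2), tolerance = 0.02)

  expect_error(rmsf(trajectory(array(0, c(1, 3, 3)))),
               class = "qsardyn_domain")
})

test_that("DCCM satisfies its matrix invariants and sampling bounds", {
  tr <- random_traj(400, 6, seed = 12)
  d <- dccm(tr)
  expect_equal(d$values, t(d$values), tolerance = 1e-10)
  expect_equal(diag(d$values), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(d$values >= -1 & d$values <= 1))

  # independent thermal motion: off-diagonals vanish like 1/sqrt(T)
  indep <- gen_trajectory(traj_sim_spec(n_sites = 4, n_frames = 10000,
                                        thermal_sigma = 1, seed = 40))
  ci <- dccm(indep, superpose = FALSE)$values
  expect_lt(max(abs(ci[upper.tri(ci)])), 0.05)

  # zero-fluctuation site is refused by name
  coords <- array(rnorm(60 * 3 * 3), c(60, 3, 3))
  coords[, 2, ] <- 5
  expect_error(dccm(trajectory(coords), superpose = FALSE), "site_002",
               class = "qsardyn_zero_fluctuation")
})

test_that("DCCM is invariant under rigid-body motion when superposing", {
  tr <- random_traj(150, 7, seed = 21)
  base <- dccm(tr, superpose = TRUE)$values

  th <- 0.83
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  coords <- tr$coords
  for (t in seq_len(dim(coords)[1])) {
    coords[t, , ] <- coords[t, , ] %*% R +
      matrix(c(11, -4, 2), dim(coords)[2], 3, byrow = TRUE)
  }
  moved <- dccm(trajectory(coords, tr$labels), superpose = TRUE)$values
  expect_equal(moved, base, tolerance = 1e-8)
})

test_that("trajectory statistics agree with the bio3d reference", {
  tr <- random_traj(250, 5, seed = 33)
  xyz <- t(apply(tr$coords, 1, function(fr) as.vector(t(fr))))

  ours <- dccm(tr, superpose = FALSE)$values
  ref <- unclass(bio3d::dccm.xyz(xyz))
  expect_equal(ours, ref, tolerance = 1e-10, ignore_attr = TRUE)

  a <- xyz[1, ]
  b <- xyz[7, ]
  expect_equal(kabsch_superpose(tr$coords[7, , ], tr$coords[1, , ])$rmsd,
               bio3d::rmsd(a, b, fit = TRUE), tolerance = 1e-3)
})

test_that("long-form and heatmap views of the DCCM are consistent", {
  tr <- random_traj(80, 4, seed = 2)
  d <- dccm(tr)
  td <- tidy(d)
  expect_equal(nrow(td), 16)
  expect_equal(td$correlation[td$site_i == td$site_j], rep(1, 4))
  expect_s3_class(autoplot(d), "ggplot")
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_dccm(d, t1)
  write_dccm_long(d, t2)
  expect_equal(nrow(readr::read_csv(t1, show_col_types = FALSE)), 4)
  expect_equal(nrow(readr::read_csv(t2, show_col_types = FALSE)), 16)
})
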