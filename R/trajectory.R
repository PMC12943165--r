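#' Construct a trajectory of point sites
#'
#' A trajectory is an `n_frames x n_sites x 3` array of Cartesian
#' coordinates (Angstrom) with one label per site. Sites are abstract
#' points — typically one per residue (C-alpha level) — so any per-site
#' time series qualifies; no chemistry is interpreted.
#'
#' @param coords Numeric array of dimension `c(n_frames, n_sites, 3)`.
#' @param labels Character vector of site labels (defaults to
#'   `site_001`, ...).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, labels = NULL) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be an n_frames x n_sites x 3 array",
          class = "qsardyn_domain")
  }
  if (dim(coords)[1] < 1L) {
    abort("trajectory needs at least one frame", class = "qsardyn_empty")
  }
  if (!all(is.finite(coords))) {
    abort("coordinates must be finite", class = "qsardyn_nonfinite")
  }
  n_sites <- dim(coords)[2]
  labels <- labels %||% sprintf("site_%03d", seq_len(n_sites))
  if (length(labels) != n_sites || anyDuplicated(labels)) {
    abort("labels must be unique and match the site count",
          class = "qsardyn_domain")
  }
  structure(list(labels = as.character(labels), coords = coords),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d sites\n", d[1], d[2]))
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

#' Read a multi-frame XYZ trajectory
#'
#' Parses the standard XYZ concatenation: for each frame an atom-count
#' line, a comment line, then one `label x y z` line per site. Every
#' frame must carry the same site count; labels are taken from the first
#' frame.
#'
#' @param path Path to a multi-frame XYZ file.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) == 0L) {
    abort("empty XYZ file", class = "qsardyn_parse")
  }
  pos <- 1L
  frames <- list()
  labels <- NULL
  frame_i <- 0L
  n_total <- length(lines)
  while (pos <= n_total) {
    frame_i <- frame_i + 1L
    n_atoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n_atoms) || n_atoms < 1L) {
      abort(sprintf("frame %d: invalid atom-count line '%s'",
                    frame_i, lines[pos]), class = "qsardyn_parse")
    }
    if (pos + 1L + n_atoms > n_total) {
      abort(sprintf("frame %d: truncated (expected %d atom lines)",
                    frame_i, n_atoms), class = "qsardyn_parse")
    }
    body <- lines[(pos + 2L):(pos + 1L + n_atoms)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad)) {
      abort(sprintf("frame %d: malformed atom line %d", frame_i, bad[1]),
            class = "qsardyn_parse")
    }
    lab <- vapply(toks, `[[`, character(1), 1L)
    xyz <- suppressWarnings(
      t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3))))
    if (any(!is.finite(xyz))) {
      abort(sprintf("frame %d: non-numeric coordinate", frame_i),
            class = "qsardyn_parse")
    }
    if (is.null(labels)) {
      labels <- lab
      if (anyDuplicated(labels)) {
        labels <- sprintf("%s_%03d", lab, seq_along(lab))
      }
    } else if (n_atoms != length(labels)) {
      abort(sprintf("frame %d: atom count %d differs from frame 1 (%d)",
                    frame_i, n_atoms, length(labels)),
            class = "qsardyn_parse")
    }
    frames[[frame_i]] <- xyz
    pos <- pos + 2L + n_atoms
  }
  coords <- aperm(simplify2array(frames), c(3, 1, 2))
  trajectory(coords, labels)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param comment Comment-line prefix (frame index appended).
#' @return `traj`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, comment = "frame") {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(d[1])) {
    writeLines(c(as.character(d[2]), paste(comment, t)), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", traj$labels,
                       traj$coords[t, , 1], traj$coords[t, , 2],
                       traj$coords[t, , 3]), con)
  }
  invisible(traj)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two paired point sets, via SVD of the covariance matrix with the
#' reflection-corrected determinant sign, after matching centroids.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`
#'   non-collinear points.
#' @return List with `coords` (mobile after superposition onto the
#'   reference), `rotation` (3x3 proper rotation, applied on the right to
#'   centered row vectors), `rmsd` (Angstrom, after superposition).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' th <- pi / 3
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' kabsch_superpose(ref %*% R + 5, ref)$rmsd  # ~0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L ||
      nrow(mobile) < 3L) {
    abort("mobile and reference must be matching n x 3 matrices with n >= 3",
          class = "qsardyn_domain")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    abort("degenerate (collinear) geometry: rotation not unique",
          class = "qsardyn_domain")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotated <- P %*% t(R)
  out <- sweep(rotated, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((rotated - Q)^2)))
  list(coords = out, rotation = R, rmsd = rmsd)
}

# Superpose every frame of a trajectory onto the mean structure, with
# `iterations` fixed-point refinements of the mean.
superpose_frames <- function(coords, iterations = 2L) {
  n_f <- dim(coords)[1]
  ref <- apply(coords, c(2, 3), mean)
  for (it in seq_len(iterations)) {
    for (t in seq_len(n_f)) {
      coords[t, , ] <- kabsch_superpose(coords[t, , , drop = TRUE], ref)$coords
    }
    ref <- apply(coords, c(2, 3), mean)
  }
  coords
}

#' Per-frame RMSD series against a reference frame
#'
#' Root-mean-square deviation of each frame from the chosen reference
#' frame, optionally after per-frame Kabsch superposition (the standard
#' way to remove global translation/rotation before judging internal
#' motion).
#'
#' @param traj A [trajectory()].
#' @param reference_frame Index of the reference frame (default 1).
#' @param superpose Superpose each frame onto the reference first
#'   (default `TRUE`).
#' @return Tibble with `frame` and `rmsd` (Angstrom). With superposition
#'   on, each value is less than or equal to its unsuperposed
#'   counterpart.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  if (!is_count(reference_frame) || reference_frame < 1 ||
      reference_frame > d[1]) {
    abort(sprintf("reference_frame must be in 1..%d", d[1]),
          class = "qsardyn_domain")
  }
  ref <- traj$coords[reference_frame, , , drop = TRUE]
  vals <- vapply(seq_len(d[1]), function(t) {
    fr <- traj$coords[t, , , drop = TRUE]
    if (superpose) {
      kabsch_superpose(fr, ref)$rmsd
    } else {
      sqrt(mean(rowSums((fr - ref)^2)))
    }
  }, numeric(1))
  tibble(frame = seq_len(d[1]), rmsd = vals)
}

#' Per-site root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |r_i(t) - <r_i>|^2), after optional
#' superposition of every frame onto the trajectory mean structure (two
#' fixed-point iterations, so the mean is consistent with the fitted
#' frames).
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param superpose Remove global motion first (default `TRUE`).
#' @return Tibble with `site` (label) and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  if (d[1] < 2L) {
    abort("RMSF needs at least two frames", class = "qsardyn_domain")
  }
  coords <- traj$coords
  if (superpose) coords <- superpose_frames(coords)
  mean_str <- apply(coords, c(2, 3), mean)
  dev2 <- vapply(seq_len(d[2]), function(i) {
    mean(rowSums((coords[, i, , drop = TRUE] -
                    matrix(mean_str[i, ], d[1], 3, byrow = TRUE))^2))
  }, numeric(1))
  tibble(site = traj$labels, rmsf = sqrt(dev2))
}

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of per-site displacement vectors:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr_i(t) = r_i(t) - <r_i>`, using the full 3-vector dot product (the
#' standard DCCM definition). +1 is fully concerted motion, -1 exact
#' anti-correlation. Frames are superposed onto the mean structure first
#' by default, which makes the matrix invariant to global rigid-body
#' motion of the trajectory.
#'
#' @param traj A [trajectory()] with at least two frames; every site must
#'   fluctuate.
#' @param superpose Remove global motion first (default `TRUE`).
#' @return Object of class `dccm_matrix`: list with `labels` and
#'   `values`, a symmetric site-by-site matrix with unit diagonal.
#'   [tidy()] gives the long form; [autoplot()] a heat map.
#' @export
dccm <- function(traj, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  if (d[1] < 2L) {
    abort("DCCM needs at least two frames", class = "qsardyn_domain")
  }
  coords <- traj$coords
  if (superpose) coords <- superpose_frames(coords)
  n_f <- d[1]
  n_s <- d[2]
  mean_str <- apply(coords, c(2, 3), mean)
  # covariance of displacement vectors via per-axis crossproducts
  C <- matrix(0, n_s, n_s)
  for (ax in 1:3) {
    dev <- coords[, , ax] - matrix(mean_str[, ax], n_f, n_s, byrow = TRUE)
    C <- C + crossprod(dev) / n_f
  }
  v <- diag(C)
  zero <- which(v <= 0 | v < 1e-24)
  if (length(zero)) {
    abort(paste0("site(s) with zero fluctuation: ",
                 paste(traj$labels[zero], collapse = ", ")),
          class = "qsardyn_zero_fluctuation")
  }
  C <- C / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1
  C[C < -1] <- -1
  dimnames(C) <- list(traj$labels, traj$labels)
  structure(list(labels = traj$labels, values = C), class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  n <- length(x$labels)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<dccm_matrix> %d x %d sites; off-diagonal range [%.3f, %.3f]\n",
              n, n, if (length(off)) min(off) else NA_real_,
              if (length(off)) max(off) else NA_real_))
  invisible(x)
}

#' Long-form DCCM
#'
#' @param x A `dccm_matrix`.
#' @param ... Unused.
#' @return Tibble with `site_i`, `site_j`, `correlation` (all pairs).
#' @method tidy dccm_matrix
#' @export
tidy.dccm_matrix <- function(x, ...) {
  tibble(site_i = rep(x$labels, times = length(x$labels)),
         site_j = rep(x$labels, each = length(x$labels)),
         correlation = as.vector(x$values))
}

#' DCCM heat map
#'
#' @param object A `dccm_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map on a blue-white-red scale over \[-1, 1\].
#' @method autoplot dccm_matrix
#' @export
autoplot.dccm_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_i, y = .data$site_j,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "C_ij") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write a DCCM as CSV
#'
#' `write_dccm()` writes the labelled square matrix;
#' `write_dccm_long()` the long (site_i, site_j, correlation) form.
#'
#' @param x A `dccm_matrix`.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_dccm <- function(x, path) {
  stopifnot(inherits(x, "dccm_matrix"))
  df <- as.data.frame(x$values)
  df <- cbind(site = x$labels, df)
  readr::write_csv(as_tibble(df), path, progress = FALSE)
  invisible(x)
}

#' @rdname write_dccm
#' @export
write_dccm_long <- function(x, path) {
  stopifnot(inherits(x, "dccm_matrix"))
  readr::write_csv(tidy(x), path, progress = FALSE)
  invisible(x)
}
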