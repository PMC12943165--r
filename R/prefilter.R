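#' Drop near-constant descriptors
#'
#' Removes every descriptor whose most common value is shared by strictly
#' more than `max_modal_fraction` of the compounds. Such columns carry
#' almost no variance and destabilise regression modelling. Value equality
#' is exact (bit-level): descriptor software emits exact repeats for
#' count-like and indicator descriptors, which is what this filter targets.
#'
#' @param data Descriptor tibble; id and activity columns are passed
#'   through untouched.
#' @param max_modal_fraction Modal-fraction cut-off in (0, 1); the default
#'   0.80 drops columns constant in more than 80% of rows. The comparison
#'   is strict, so a column at exactly the threshold is retained.
#' @param activity Optional activity column name to exempt from filtering
#'   (activity is never treated as a descriptor).
#' @return The filtered tibble with attribute `"dropped_constant"` listing
#'   the removed descriptor names.
#' @export
drop_near_constant <- function(data, max_modal_fraction = 0.80,
                               activity = NULL) {
  if (!is.numeric(max_modal_fraction) || max_modal_fraction <= 0 ||
      max_modal_fraction >= 1) {
    abort("max_modal_fraction must lie strictly between 0 and 1",
          class = "qsardyn_domain")
  }
  parts <- dt_parts(data, activity = activity)
  if (ncol(parts$X) == 0L) {
    abort("table has no descriptor columns", class = "qsardyn_empty")
  }
  n <- nrow(parts$X)
  modal <- vapply(seq_len(ncol(parts$X)), function(j) {
    max(tabulate(match(parts$X[, j], unique(parts$X[, j])))) / n
  }, numeric(1))
  dropped <- parts$descriptors[modal > max_modal_fraction]
  out <- data[, !(names(data) %in% dropped), drop = FALSE]
  out <- as_tibble(out)
  attr(out, "dropped_constant") <- dropped
  out
}

#' Drop pairwise-collinear descriptors
#'
#' Scans descriptors left to right and removes every column whose absolute
#' Pearson correlation with an already-retained column reaches
#' `r_threshold`. Anti-correlated duplicates are treated as redundant, so
#' the rule uses |r|. The scan keeps the earlier column of any offending
#' pair, which makes the result deterministic given the column order; when
#' `prefer_activity_correlated = TRUE` and an activity column is present,
#' the member of the pair more correlated with activity is kept instead.
#'
#' @param data Descriptor tibble with at least two rows. Constant columns
#'   are not allowed: run [drop_near_constant()] first.
#' @param r_threshold Absolute-correlation cut-off in (0, 1]; default 0.95.
#' @param activity Optional activity column name (exempt from filtering;
#'   used only by `prefer_activity_correlated`).
#' @param prefer_activity_correlated Tie-break by activity correlation
#'   instead of column order. Default `FALSE`.
#' @return The filtered tibble with attribute `"dropped_correlated"`: a
#'   tibble of (`dropped`, `kept`, `r`) recording, for each removed column,
#'   the retained column that triggered the removal and their correlation.
#' @export
drop_correlated <- function(data, r_threshold = 0.95, activity = NULL,
                            prefer_activity_correlated = FALSE) {
  if (!is.numeric(r_threshold) || r_threshold <= 0 || r_threshold > 1) {
    abort("r_threshold must lie in (0, 1]", class = "qsardyn_domain")
  }
  parts <- dt_parts(data, activity = activity)
  X <- parts$X
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) abort("need at least two rows", class = "qsardyn_domain")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("constant column '", parts$descriptors[sds == 0][1],
                 "' has undefined correlation; run drop_near_constant() first"),
          class = "qsardyn_constant_column")
  }
  # standardize so that crossprod(z_i, z_j) is the Pearson correlation
  Z <- scale(X) / sqrt(n - 1)
  y_cor <- if (prefer_activity_correlated && !is.null(parts$y)) {
    abs(as.vector(cor(X, parts$y)))
  } else {
    NULL
  }
  kept <- integer(0)
  K <- matrix(0, n, p)
  m <- 0L
  drops <- vector("list", p)
  for (j in seq_len(p)) {
    hit <- 0L
    if (m > 0L) {
      r <- crossprod(K[, seq_len(m), drop = FALSE], Z[, j])[, 1]
      over <- which(abs(r) >= r_threshold)
      if (length(over)) hit <- over[1]
    }
    if (hit > 0L) {
      keep_j <- !is.null(y_cor) && y_cor[j] > y_cor[kept[hit]]
      if (keep_j) {
        # swap: the later column wins the slot of its correlated partner
        drops[[j]] <- tibble(dropped = parts$descriptors[kept[hit]],
                             kept = parts$descriptors[j],
                             r = r[hit])
        K[, hit] <- Z[, j]
        kept[hit] <- j
      } else {
        drops[[j]] <- tibble(dropped = parts$descriptors[j],
                             kept = parts$descriptors[kept[hit]],
                             r = r[hit])
      }
    } else {
      m <- m + 1L
      K[, m] <- Z[, j]
      kept[m] <- j
    }
  }
  pairs <- dplyr::bind_rows(drops)
  if (nrow(pairs) == 0L) {
    pairs <- tibble(dropped = character(), kept = character(), r = numeric())
  }
  out <- as_tibble(data[, !(names(data) %in% pairs$dropped), drop = FALSE])
  attr(out, "dropped_correlated") <- pairs
  out
}

#' Two-stage descriptor pre-filter
#'
#' Applies [drop_near_constant()] then [drop_correlated()] and assembles a
#' report of every removal with its reason. Large machine-generated
#' descriptor pools routinely contain thousands of near-constant and
#' near-duplicate columns; this filter reduces such a pool to an
#' informative subset before subset search. The operation is idempotent:
#' filtering an already-filtered table removes nothing.
#'
#' @inheritParams drop_correlated
#' @param max_modal_fraction Passed to [drop_near_constant()].
#' @return The filtered tibble with attribute `"prefilter_report"`, an
#'   object of class `prefilter_report` (see [prefilter_report()]).
#' @examples
#' sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 30, n_noise = 5,
#'                                       n_constant = 2, n_collinear_pairs = 2,
#'                                       seed = 1))
#' filtered <- prefilter(sim$data, activity = "pIC50")
#' prefilter_report(filtered)
#' @export
prefilter <- function(data, max_modal_fraction = 0.80, r_threshold = 0.95,
                      activity = NULL, prefer_activity_correlated = FALSE) {
  original <- dt_parts(data, activity = activity)$descriptors
  s1 <- drop_near_constant(data, max_modal_fraction, activity = activity)
  s2 <- drop_correlated(s1, r_threshold, activity = activity,
                        prefer_activity_correlated = prefer_activity_correlated)
  report <- structure(list(
    dropped_constant = attr(s1, "dropped_constant"),
    dropped_correlated = attr(s2, "dropped_correlated"),
    retained = dt_parts(s2, activity = activity)$descriptors,
    original = original,
    max_modal_fraction = max_modal_fraction,
    r_threshold = r_threshold,
    correlation_rule = "absolute Pearson |r|, keep earlier column in table order",
    modal_rule = "strict > on modal fraction, exact value equality"
  ), class = "prefilter_report")
  attr(s2, "dropped_correlated") <- NULL
  attr(s2, "prefilter_report") <- report
  s2
}

#' Extract a pre-filter report
#'
#' @param x A tibble returned by [prefilter()], or a `prefilter_report`.
#' @return The `prefilter_report` object.
#' @export
prefilter_report <- function(x) {
  if (inherits(x, "prefilter_report")) return(x)
  rep <- attr(x, "prefilter_report")
  if (is.null(rep)) {
    abort("no prefilter report attached; was this tibble made by prefilter()?",
          class = "qsardyn_domain")
  }
  rep
}

#' @export
print.prefilter_report <- function(x, ...) {
  cat("<prefilter_report>\n")
  cat(sprintf("  original descriptors : %d\n", length(x$original)))
  cat(sprintf("  dropped near-constant: %d (modal fraction > %.2f)\n",
              length(x$dropped_constant), x$max_modal_fraction))
  cat(sprintf("  dropped collinear    : %d (|r| >= %.2f)\n",
              nrow(x$dropped_correlated), x$r_threshold))
  cat(sprintf("  retained             : %d\n", length(x$retained)))
  invisible(x)
}

#' Tidy a pre-filter report into one row per original descriptor
#'
#' @param x A `prefilter_report`.
#' @param ... Unused.
#' @return A tibble with columns `descriptor`, `status`
#'   (`retained`/`near_constant`/`collinear`), `partner`, `r`.
#' @method tidy prefilter_report
#' @export
tidy.prefilter_report <- function(x, ...) {
  out <- tibble(descriptor = x$original,
                status = "retained",
                partner = NA_character_, r = NA_real_)
  out$status[out$descriptor %in% x$dropped_constant] <- "near_constant"
  idx <- match(x$dropped_correlated$dropped, out$descriptor)
  out$status[idx] <- "collinear"
  out$partner[idx] <- x$dropped_correlated$kept
  out$r[idx] <- x$dropped_correlated$r
  out
}

#' Serialize a pre-filter report to JSON
#'
#' @param report A `prefilter_report`.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_prefilter_report <- function(report, path) {
  report <- prefilter_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
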