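#' Read a descriptor table from CSV
#'
#' Reads a compound-by-descriptor table: a CSV with a header row whose first
#' column holds compound identifiers and whose remaining columns are numeric
#' molecular descriptors, optionally including an activity column (e.g.
#' `pIC50`). The CSV dialect is fixed: comma-separated, `.` decimal, UTF-8,
#' header mandatory.
#'
#' @param path Path to a CSV file.
#' @param activity_column Name of the activity column, or `NULL` when the
#'   table carries descriptors only. The column must exist and be numeric.
#' @return A tibble with `compound_id` as its first column, descriptor
#'   columns in file order, and the activity column (if any) last. Column
#'   order among descriptors is preserved.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' d <- tibble::tibble(compound_id = c("a", "b"), d1 = c(1, 2), d2 = c(3, 4))
#' write_descriptor_table(d, tf)
#' read_descriptor_table(tf)
#' @export
read_descriptor_table <- function(path, activity_column = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qsardyn_io")
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (length(header) < 2L) {
    abort("CSV must have an id column and at least one descriptor column",
          class = "qsardyn_parse")
  }
  dup <- header[duplicated(header)]
  if (length(dup)) {
    abort(paste0("duplicate column header: '", dup[1], "'"),
          class = "qsardyn_dup_name")
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, name_repair = "minimal"
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    p <- probs[1, ]
    abort(sprintf("CSV parse error at row %d, column %d: expected %s, got '%s'",
                  p$row, p$col, p$expected, p$actual),
          class = "qsardyn_parse")
  }
  names(raw)[1] <- "compound_id"
  if (anyDuplicated(raw$compound_id)) {
    abort(paste0("duplicate compound id: '",
                 raw$compound_id[duplicated(raw$compound_id)][1], "'"),
          class = "qsardyn_dup_id")
  }
  bad <- names(raw)[-1][!vapply(raw[-1], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("non-numeric descriptor column: '", bad[1], "'"),
          class = "qsardyn_parse")
  }
  if (!is.null(activity_column)) {
    if (!activity_column %in% names(raw)) {
      abort(paste0("activity column '", activity_column, "' not found"),
            class = "qsardyn_missing_column")
    }
    raw <- dplyr::relocate(raw, dplyr::all_of(activity_column),
                           .after = dplyr::last_col())
  }
  raw
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; values survive a write/read
#' round-trip to better than 12 significant digits.
#'
#' @param data A descriptor tibble (first column compound ids).
#' @param path Output CSV path.
#' @return `data`, invisibly, so the call can sit mid-pipe.
#' @export
write_descriptor_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Convert IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in mol/L; higher values mean more potent
#' compounds. Converting activities onto this scale reduces skewness before
#' regression modelling.
#'
#' @param ic50 Positive IC50 value(s).
#' @param unit Concentration unit of `ic50`: one of `"M"`, `"mM"`, `"uM"`,
#'   `"nM"`. When the caller does not supply a unit, micromolar is assumed
#'   and a warning is emitted, since silently guessing units is a classic
#'   QSAR data-curation error.
#' @return pIC50 value(s), dimensionless.
#' @examples
#' ic50_to_pic50(1, "uM")    # 6
#' ic50_to_pic50(10, "nM")   # 8
#' @export
ic50_to_pic50 <- function(ic50, unit = c("uM", "M", "mM", "nM")) {
  if (missing(unit)) {
    warn("no IC50 unit supplied; assuming micromolar (uM)",
         class = "qsardyn_unit_assumed")
  }
  unit <- match.arg(unit)
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("IC50 values must be finite and strictly positive",
          class = "qsardyn_domain")
  }
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  -log10(ic50 * scale)
}

#' Partition compounds into training and external validation sets
#'
#' Splits a descriptor table into a training set and an external prediction
#' set. The default `sorted_stride` strategy sorts compounds by activity and
#' takes every ceiling(n / external_count)-th compound starting from the
#' least active, so the external set spans the activity range
#' deterministically; `random` draws the external set uniformly under a
#' seed.
#'
#' @param data Descriptor tibble.
#' @param external_count Number of compounds for the external set
#'   (`0 <= external_count < n`).
#' @param strategy `"sorted_stride"` (default, requires `activity`) or
#'   `"random"`.
#' @param activity Name of the activity column (needed by `sorted_stride`).
#' @param seed Integer seed for the `random` strategy.
#' @return A tibble with columns `compound_id` and `partition`
#'   (`"train"`/`"external"`), one row per compound; the two sets are
#'   disjoint and cover the table.
#' @examples
#' sim <- gen_qsar_dataset(preset_study57(seed = 1))
#' sp <- make_split(sim$data, external_count = 10, activity = "pIC50")
#' table(sp$partition)  # 47 train, 10 external
#' @export
make_split <- function(data, external_count,
                       strategy = c("sorted_stride", "random"),
                       activity = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  parts <- dt_parts(data, activity = activity)
  n <- length(parts$ids)
  if (!is_count(external_count) || external_count < 0 || external_count >= n) {
    abort(sprintf("external_count must satisfy 0 <= external_count < n (= %d)", n),
          class = "qsardyn_domain")
  }
  ext_idx <- integer(0)
  if (external_count > 0) {
    if (strategy == "sorted_stride") {
      if (is.null(parts$y)) {
        abort("sorted_stride needs an activity column", class = "qsardyn_domain")
      }
      ord <- order(parts$y)
      stride <- ceiling(n / external_count)
      idx <- seq(1L, n, by = stride)
      if (length(idx) != external_count) {
        # stride undershoots for some n/count combinations; fall back to
        # evenly spaced ranks across the sorted activities
        idx <- unique(round(seq(1, n, length.out = external_count)))
      }
      ext_idx <- ord[idx]
    } else {
      ext_idx <- with_seed(seed, sample.int(n, external_count))
    }
  }
  partition <- rep("train", n)
  partition[ext_idx] <- "external"
  tibble(compound_id = parts$ids, partition = partition)
}

#' Write or read a split assignment
#'
#' The split is stored as a two-column CSV (`compound_id`, `partition`).
#'
#' @param split Tibble from [make_split()].
#' @param path CSV path.
#' @return `split` (write) or the split tibble (read).
#' @export
write_split <- function(split, path) {
  stopifnot(all(c("compound_id", "partition") %in% names(split)))
  readr::write_csv(split[c("compound_id", "partition")], path, progress = FALSE)
  invisible(split)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  sp <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!all(sp$partition %in% c("train", "external"))) {
    abort("partition column must contain only 'train'/'external'",
          class = "qsardyn_parse")
  }
  sp
}
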