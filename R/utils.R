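# Internal helpers shared across modules.

# Split a descriptor tibble into ids / numeric descriptor matrix / activity.
# The id column is `compound_id` when present, otherwise the first
# non-numeric column, otherwise row numbers as character ids.
dt_parts <- function(data, activity = NULL, descriptors = NULL,
                     require_activity = FALSE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) {
    abort("descriptor table has no rows", class = "qsardyn_empty")
  }
  nms <- names(data)
  id_col <- if ("compound_id" %in% nms) {
    "compound_id"
  } else {
    cand <- nms[!vapply(data, is.numeric, logical(1))]
    if (length(cand)) cand[[1]] else NA_character_
  }
  ids <- if (is.na(id_col)) {
    as.character(seq_len(nrow(data)))
  } else {
    as.character(data[[id_col]])
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate compound id: ",
                 ids[duplicated(ids)][1]), class = "qsardyn_dup_id")
  }
  y <- NULL
  if (!is.null(activity)) {
    if (!activity %in% nms) {
      abort(paste0("activity column '", activity, "' not found"),
            class = "qsardyn_missing_column")
    }
    y <- as.numeric(data[[activity]])
  } else if (require_activity) {
    abort("an activity column is required here", class = "qsardyn_no_activity")
  }
  desc_cols <- setdiff(nms, c(id_col, activity))
  desc_cols <- desc_cols[vapply(data[desc_cols], is.numeric, logical(1))]
  if (!is.null(descriptors)) {
    missing <- setdiff(descriptors, desc_cols)
    if (length(missing)) {
      abort(paste0("descriptor(s) not found in table: ",
                   paste(missing, collapse = ", ")),
            class = "qsardyn_missing_column")
    }
    desc_cols <- descriptors
  }
  if (anyDuplicated(desc_cols)) {
    abort(paste0("duplicate descriptor name: ",
                 desc_cols[duplicated(desc_cols)][1]),
          class = "qsardyn_dup_name")
  }
  X <- as.matrix(data[desc_cols])
  if (length(X) && !all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at row %d, column '%s'",
                  bad[1], desc_cols[bad[2]]),
          class = "qsardyn_nonfinite")
  }
  rownames(X) <- ids
  list(ids = ids, X = X, y = y, id_col = id_col,
       activity = activity, descriptors = desc_cols)
}

# Evaluate `expr` under a locally seeded RNG without touching the caller's
# RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
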