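# Registry of the two published pIC50 equations for trimethoxyphenyl
# tubulin polymerization inhibitors. Coefficients are on raw descriptor
# scales and are stored verbatim; descriptor names (including "R3s++")
# are matched case-sensitively after whitespace trimming.
.published_registry <- list(
  model1 = list(
    intercept = -11.8572,
    coefficients = c(`R3s++` = 0.9217, map4_26 = 0.9359,
                     of0ug = 34.0115, ETA_shape_p = 6.4191)
  ),
  model2 = list(
    intercept = -12.1211,
    coefficients = c(Mor15i = 0.2414, map4_26 = 0.9746,
                     of0ug = 33.5921, ETA_shape_p = 6.8459)
  )
)

#' Published QSAR model registry
#'
#' Two published four-descriptor MLR equations predicting pIC50 for
#' tubulin polymerization inhibition of trimethoxyphenyl analogues.
#' Model 1 uses the steric-accessibility descriptor `R3s++`; Model 2
#' replaces it with the 3D-MoRSE electronic-density descriptor `Mor15i`;
#' both share `map4_26` (topological complexity), `of0ug` (molecular
#' polarizability, the dominant term) and `ETA_shape_p` (conformational
#' flexibility). Descriptor values must be supplied by the caller —
#' computing them from structures requires external descriptor software
#' and is out of scope.
#'
#' @param name `"model1"` or `"model2"`.
#' @return `published_model()` returns a [model_spec()];
#'   `published_models()` returns the full registry as a named list.
#' @examples
#' published_model("model1")$intercept        # -11.8572
#' predict_pic50(published_model("model2"),
#'               c(Mor15i = 0, map4_26 = 0, of0ug = 1, ETA_shape_p = 0))
#' @export
published_model <- function(name) {
  name <- trimws(name)
  if (!name %in% names(.published_registry)) {
    abort(paste0("unknown model '", name, "'; available: ",
                 paste(names(.published_registry), collapse = ", ")),
          class = "qsardyn_unknown_model")
  }
  entry <- .published_registry[[name]]
  model_spec(name, entry$intercept, entry$coefficients)
}

#' @rdname published_model
#' @export
published_models <- function() {
  setNames(lapply(names(.published_registry), published_model),
           names(.published_registry))
}

#' Predict pIC50 from a linear model specification
#'
#' Evaluates intercept + sum(coefficient * descriptor value) for each
#' compound. Every descriptor the model uses must be present; extra
#' entries are ignored with a warning.
#'
#' @param model A [model_spec()] (e.g. from [published_model()] or a fit).
#' @param descriptors A named numeric vector (one compound) or a data
#'   frame / tibble with one descriptor per column (one row per
#'   compound).
#' @param .warn_extra Warn about unused entries (default `TRUE`).
#' @return Numeric vector of predicted pIC50 values, one per compound.
#' @export
predict_pic50 <- function(model, descriptors, .warn_extra = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  need <- names(model$coefficients)
  if (is.data.frame(descriptors)) {
    have <- names(descriptors)
    missing <- setdiff(need, have)
    if (length(missing)) {
      abort(paste0("missing descriptor(s): ", paste(missing, collapse = ", ")),
            class = "qsardyn_missing_column")
    }
    numeric_extra <- setdiff(have[vapply(descriptors, is.numeric, logical(1))],
                             need)
    if (.warn_extra && length(numeric_extra)) {
      warn(paste0("ignoring ", length(numeric_extra),
                  " descriptor column(s) the model does not use"))
    }
    M <- as.matrix(descriptors[need])
    as.vector(model$intercept + M %*% model$coefficients)
  } else {
    v <- descriptors
    if (is.null(names(v))) {
      abort("descriptor vector must be named", class = "qsardyn_domain")
    }
    names(v) <- trimws(names(v))
    missing <- setdiff(need, names(v))
    if (length(missing)) {
      abort(paste0("missing descriptor(s): ", paste(missing, collapse = ", ")),
            class = "qsardyn_missing_column")
    }
    extra <- setdiff(names(v), need)
    if (.warn_extra && length(extra)) {
      warn(paste0("ignoring unused descriptor(s): ",
                  paste(extra, collapse = ", ")))
    }
    unname(model$intercept + sum(model$coefficients * v[need]))
  }
}

#' Serialize model specifications to and from JSON
#'
#' Coefficients round-trip byte-stably (written at full precision).
#'
#' @param model A [model_spec()].
#' @param path JSON path.
#' @return `write_model_spec()` returns `model` invisibly;
#'   `read_model_spec()` returns the `model_spec`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "model_spec"))
  jsonlite::write_json(list(name = model$name, intercept = model$intercept,
                            coefficients = as.list(model$coefficients)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- jsonlite::read_json(path)
  model_spec(obj$name, obj$intercept,
             setNames(vapply(obj$coefficients, as.numeric, numeric(1)),
                      names(obj$coefficients)))
}
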