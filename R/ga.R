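#' Genetic-algorithm configuration
#'
#' Hyperparameters for [ga_select()]. The chromosome is a fixed-size
#' subset of `subset_size` descriptors; crossover draws a child of that
#' size uniformly from the union of two parents, and mutation swaps one
#' member for a random non-member.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param subset_size Number of descriptors per model (k >= 1).
#' @param crossover_rate,mutation_rate Per-child probabilities in (0, 1).
#' @param quik_delta Minimum margin dK by which the K index of the
#'   descriptor block including the response must exceed that of the
#'   block alone (QUIK acceptance rule); subsets failing it get fitness
#'   -Inf.
#' @param elitism Number of best individuals copied unchanged into the
#'   next generation (guarantees a non-decreasing best fitness).
#' @param seed Integer seed; the whole search is reproducible from it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      subset_size = 4, crossover_rate = 0.8,
                      mutation_rate = 0.1, quik_delta = 0.05,
                      elitism = 2, seed = 1L) {
  stopifnot(is_count(population_size), population_size >= 2,
            is_count(generations), generations >= 1,
            is_count(subset_size), subset_size >= 1,
            crossover_rate > 0, crossover_rate < 1,
            mutation_rate > 0, mutation_rate < 1,
            quik_delta >= 0,
            is_count(elitism), elitism >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 subset_size = as.integer(subset_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 quik_delta = quik_delta,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf(paste0("<ga_config> k = %d, population %d x %d generations, ",
                     "crossover %.2f, mutation %.2f, dK >= %.3f, elitism %d, seed %d\n"),
              x$subset_size, x$population_size, x$generations,
              x$crossover_rate, x$mutation_rate, x$quik_delta, x$elitism,
              x$seed))
  invisible(x)
}

# Fitness of one subset: leave-one-out Q2, gated by the QUIK rule.
# Returns -Inf for rejected or numerically degenerate subsets.
ga_fitness <- function(idx, X, y, tss, quik_delta) {
  Xi <- X[, idx, drop = FALSE]
  ok <- tryCatch({
    if (length(idx) >= 2) {
      k_x <- quik_k(Xi)
      k_xy <- quik_k(cbind(Xi, y))
      (k_xy - k_x) >= quik_delta
    } else {
      kxy <- quik_k(cbind(Xi, y))
      kxy >= quik_delta
    }
  }, error = function(e) FALSE)
  if (!ok) return(-Inf)
  X1 <- cbind(1, Xi)
  qrx <- qr(X1)
  if (qrx$rank < ncol(X1)) return(-Inf)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  e <- y - Q %*% crossprod(Q, y)
  d <- 1 - rowSums(Q^2)
  if (any(d <= .Machine$double.eps^0.5)) return(-Inf)
  1 - sum((e / d)^2) / tss
}

#' Genetic-algorithm descriptor subset selection
#'
#' Searches fixed-size descriptor subsets for the model maximising
#' leave-one-out Q2 under the QUIK acceptance rule: a subset is admissible
#' only when the multivariate correlation (K index, [quik_k()]) of the
#' descriptor block *with* the activity exceeds that of the block alone
#' by at least `quik_delta`, which rejects models whose apparent
#' predictivity rides on descriptor inter-correlation. Selection is by
#' 2-tournament; elitism makes the best fitness non-decreasing across
#' generations.
#'
#' @inheritParams fit_mlr
#' @param config A [ga_config()].
#' @return Object of class `ga_result`: list with `descriptors` (selected
#'   names), `fit` (the [fit_mlr()] refit on them; `NULL` when every
#'   subset was rejected), `fitness` (best Q2), `trace` (tibble of
#'   per-generation best and mean finite fitness), `all_rejected`,
#'   `config`. [autoplot()] draws the fitness trace.
#' @examples
#' sim <- gen_qsar_dataset(qsar_sim_spec(n_compounds = 40, n_noise = 10,
#'                                       seed = 3))
#' res <- ga_select(sim$data, "pIC50",
#'                  ga_config(population_size = 30, generations = 20, seed = 3))
#' res$descriptors
#' @export
ga_select <- function(data, activity, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  parts <- dt_parts(data, activity = activity, require_activity = TRUE)
  X <- parts$X
  y <- parts$y
  n <- nrow(X)
  p <- ncol(X)
  k <- config$subset_size
  if (k > p) {
    abort(sprintf("subset_size %d exceeds the %d available descriptors", k, p),
          class = "qsardyn_domain")
  }
  if (n <= k + 1L) {
    abort("too few compounds for the requested subset size",
          class = "qsardyn_underdetermined")
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("activity has zero variance", class = "qsardyn_domain")

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- ga_fitness(idx, X, y, tss, config$quik_delta)
    cache[[key]] <- f
    f
  }

  if (k == p) {
    # single-subset search space
    idx <- seq_len(p)
    f <- fitness_of(idx)
    return(ga_finish(idx, f, tibble(generation = 1L, best = f, mean = f),
                     parts, data, activity, config))
  }

  search <- with_seed(config$seed, {
    pop <- replicate(config$population_size, sort(sample.int(p, k)),
                     simplify = FALSE)
    trace <- vector("list", config$generations)
    fits <- vapply(pop, fitness_of, numeric(1))
    for (gen in seq_len(config$generations)) {
      ord <- order(fits, decreasing = TRUE)
      pop <- pop[ord]
      fits <- fits[ord]
      finite <- fits[is.finite(fits)]
      trace[[gen]] <- tibble(generation = gen, best = fits[1],
                             mean = if (length(finite)) mean(finite) else NA_real_)
      elite <- head(pop, config$elitism)
      children <- vector("list", config$population_size - length(elite))
      for (i in seq_along(children)) {
        pick <- function() {
          c1 <- sample.int(length(pop), 2)
          pop[[c1[which.max(fits[c1])]]]
        }
        p1 <- pick()
        p2 <- pick()
        child <- if (runif(1) < config$crossover_rate) {
          pool <- union(p1, p2)
          sort(sample(pool, k))
        } else {
          p1
        }
        if (runif(1) < config$mutation_rate) {
          out_pos <- sample.int(k, 1)
          replacement <- sample(setdiff(seq_len(p), child), 1)
          child <- sort(c(child[-out_pos], replacement))
        }
        children[[i]] <- child
      }
      pop <- c(elite, children)
      fits <- vapply(pop, fitness_of, numeric(1))
    }
    best_i <- which.max(fits)
    list(best = pop[[best_i]], fitness = fits[best_i],
         trace = dplyr::bind_rows(trace))
  })
  ga_finish(search$best, search$fitness, search$trace, parts, data,
            activity, config)
}

ga_finish <- function(idx, fitness, trace, parts, data, activity, config) {
  all_rejected <- !is.finite(fitness)
  descriptors <- parts$descriptors[idx]
  fit <- if (all_rejected) NULL else fit_mlr(data, activity, descriptors,
                                             name = "ga_mlr")
  if (all_rejected) {
    inform(paste0("every subset visited was rejected by the QUIK rule ",
                  "(dK >= ", config$quik_delta, "); no model returned"))
  }
  structure(list(descriptors = if (all_rejected) character(0) else descriptors,
                 fit = fit, fitness = fitness, trace = trace,
                 all_rejected = all_rejected, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  if (x$all_rejected) {
    cat("<ga_result> all subsets rejected by the QUIK rule\n")
    return(invisible(x))
  }
  cat(sprintf("<ga_result> best Q2(LOO) = %.4f with descriptors: %s\n",
              x$fitness, paste(x$descriptors, collapse = ", ")))
  invisible(x)
}

#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) {
  if (x$all_rejected) {
    return(tibble(term = character(), estimate = numeric(),
                  std_error = numeric(), statistic = numeric()))
  }
  tidy(x$fit)
}

#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble(fitness = x$fitness, n_descriptors = length(x$descriptors),
         generations = nrow(x$trace), all_rejected = x$all_rejected)
}

#' Fitness-trace plot for a GA search
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per generation.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("best", "mean"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Generation", y = "Q2 (LOO) fitness") +
    ggplot2::theme_minimal()
}

#' Write a GA fitness trace as CSV
#'
#' @param result A `ga_result`.
#' @param path Output CSV path.
#' @return `result`, invisibly.
#' @export
write_ga_trace <- function(result, path) {
  stopifnot(inherits(result, "ga_result"))
  readr::write_csv(result$trace, path, progress = FALSE)
  invisible(result)
}
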