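#' Friedman lack-of-fit score
#'
#' `LOF = LSE / (1 - (c + d*p)/m)^2`, the size-penalized least-squares error
#' used as the genetic-search fitness.  `LSE` is taken as the mean squared
#' error (RSS/m) so the score is scale-consistent with the default smoothing
#' parameter `d = 1`; `c` counts basis functions, `p` counts descriptors and
#' `m` is the number of training observations.  Smaller is better; for
#' equal-size models LOF ordering equals LSE ordering.
#'
#' @param lse Least-squares error (non-negative).
#' @param c Number of basis functions in the model.
#' @param d Smoothing parameter (default 1); larger values favour smaller
#'   equations.
#' @param p Number of distinct descriptors in the model.
#' @param m Number of training observations; must exceed `c + d*p`.
#' @return The LOF value.
#' @export
lof <- function(lse, c, d = 1, p, m) {
  if (lse < 0) stop_("lse must be non-negative")
  pen <- 1 - (c + d * p) / m
  if (pen <= 0) stop_("model too large for sample: c + d*p = %g >= m = %g",
                      c + d * p, m)
  lse / pen^2
}

#' Configuration for the genetic function approximation search
#'
#' The genetic engine evolves sets of basis terms; each individual is fitted
#' by [ols_fit()] and scored by [lof()].  Population size and operator rates
#' are not dictated by the underlying method, so conventional desk-scale
#' defaults are used: population 100, single-point crossover on sorted term
#' lists, add/remove/knot-perturb mutation at probability 0.1 each, elitism
#' of one.  "Iterations" counts genetic operations (child creations), not
#' generations.
#'
#' @param iterations Number of genetic operations (default 5000).
#' @param population Population size (>= 2; default 100).
#' @param d LOF smoothing parameter (default 1).
#' @param transforms Allowed basis transforms; default linear plus both
#'   truncated-power-spline directions (the "linear and spline options").
#' @param p_crossover Probability an offspring comes from crossover.
#' @param p_mutate Per-operator mutation probability.
#' @param min_terms,max_terms Bounds on equation length ("no fixed length"
#'   means the term count floats freely in this range; default 1..6).
#' @param seed Integer RNG seed.
#' @return A list of class `gfa_config`.
#' @export
gfa_config <- function(iterations = 5000L, population = 100L, d = 1,
                       transforms = c("linear", "spline_below", "spline_above"),
                       p_crossover = 0.5, p_mutate = 0.1,
                       min_terms = 1L, max_terms = 6L, seed = 1L) {
  transforms <- match.arg(transforms, several.ok = TRUE,
                          choices = c("linear", "spline_below",
                                      "spline_above", "square"))
  if (population < 2L) stop_("population must be >= 2")
  if (p_crossover < 0 || p_crossover > 1 || p_mutate < 0 || p_mutate > 1) {
    stop_("probabilities must be in [0, 1]")
  }
  if (min_terms < 1L || max_terms < min_terms) stop_("bad term-count bounds")
  structure(list(iterations = as.integer(iterations),
                 population = as.integer(population), d = d,
                 transforms = transforms, p_crossover = p_crossover,
                 p_mutate = p_mutate, min_terms = as.integer(min_terms),
                 max_terms = as.integer(max_terms), seed = as.integer(seed)),
            class = "gfa_config")
}

# ---- genetic engine internals (shared by gfa_search and gpls_search) ----

# Random term on a random descriptor; spline knots are drawn from observed
# interior values of that descriptor so at least one sample lies on each
# side of the knot whenever possible.
random_term <- function(m, transforms) {
  d <- sample(colnames(m), 1L)
  tr <- sample(transforms, 1L)
  if (tr %in% c("spline_below", "spline_above")) {
    vals <- sort(unique(m[, d]))
    if (length(vals) < 3L) tr <- "linear"
    else return(model_term(d, tr, knot = sample(vals[-c(1L, length(vals))], 1L)))
  }
  model_term(d, tr)
}

random_individual <- function(m, cfg) {
  size <- sample(seq.int(cfg$min_terms, cfg$max_terms), 1L)
  terms <- replicate(size, random_term(m, cfg$transforms), simplify = FALSE)
  dedup_terms(terms)
}

dedup_terms <- function(terms) {
  sig <- vapply(terms, function(t) term_signature(list(t)), character(1L))
  terms[!duplicated(sig)]
}

# Single-point crossover on term lists sorted by signature.
crossover_terms <- function(a, b, cfg) {
  key <- function(ts) order(vapply(ts, function(t) term_signature(list(t)),
                                   character(1L)))
  a <- a[key(a)]; b <- b[key(b)]
  ca <- sample.int(length(a) + 1L, 1L) - 1L
  cb <- sample.int(length(b) + 1L, 1L) - 1L
  child <- dedup_terms(c(a[seq_len(ca)], b[seq_len(length(b) - cb) + cb]))
  clamp_terms(child, cfg)
}

clamp_terms <- function(terms, cfg) {
  if (length(terms) > cfg$max_terms) {
    terms <- terms[sample.int(length(terms), cfg$max_terms)]
  }
  terms
}

mutate_terms <- function(terms, m, cfg) {
  if (stats::runif(1L) < cfg$p_mutate && length(terms) < cfg$max_terms) {
    terms <- dedup_terms(c(terms, list(random_term(m, cfg$transforms))))
  }
  if (stats::runif(1L) < cfg$p_mutate && length(terms) > cfg$min_terms) {
    terms <- terms[-sample.int(length(terms), 1L)]
  }
  if (stats::runif(1L) < cfg$p_mutate) {
    has_knot <- which(vapply(terms, function(t) !is.null(t$knot), logical(1L)))
    if (length(has_knot)) {
      i <- if (length(has_knot) == 1L) has_knot else sample(has_knot, 1L)
      vals <- sort(unique(m[, terms[[i]]$descriptor]))
      if (length(vals) >= 3L) {
        inner <- vals[-c(1L, length(vals))]
        if (stats::runif(1L) < 0.5) {
          # local step: move the knot to a nearby observed value
          cur <- which.min(abs(inner - terms[[i]]$knot))
          j <- cur + sample(c(-2L, -1L, 1L, 2L), 1L)
          j <- min(max(j, 1L), length(inner))
          terms[[i]]$knot <- inner[j]
        } else {
          terms[[i]]$knot <- sample(inner, 1L)
        }
      }
    }
  }
  terms
}

# Steady-state GA: `iterations` child creations, child replaces the current
# worst individual when it improves on it; the best is never replaced.
run_ga <- function(m, cfg, score_fn) {
  if (cfg$min_terms > ncol(m)) {
    stop_("infeasible config: min_terms = %d > %d descriptors",
          cfg$min_terms, ncol(m))
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(terms) {
    sig <- term_signature(terms)
    hit <- cache[[sig]]
    if (!is.null(hit)) return(hit)
    res <- score_fn(terms)
    cache[[sig]] <- res
    res
  }
  pop <- replicate(cfg$population, random_individual(m, cfg), simplify = FALSE)
  scored <- lapply(pop, evaluate)
  lofs <- vapply(scored, `[[`, numeric(1L), "lof")
  trajectory <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    if (stats::runif(1L) < cfg$p_crossover && cfg$population >= 2L) {
      pick <- function() {
        duel <- sample.int(cfg$population, 2L)
        duel[which.min(lofs[duel])]
      }
      child <- crossover_terms(pop[[pick()]], pop[[pick()]], cfg)
    } else {
      child <- pop[[sample.int(cfg$population, 1L)]]
    }
    child <- mutate_terms(child, m, cfg)
    if (length(child) < cfg$min_terms) child <- random_individual(m, cfg)
    sc <- evaluate(child)
    worst <- which.max(lofs)
    if (sc$lof < lofs[worst]) {
      pop[[worst]] <- child
      scored[[worst]] <- sc
      lofs[worst] <- sc$lof
    }
    trajectory[it] <- min(lofs)
  }
  ord <- order(lofs)
  list(population = pop[ord], scored = scored[ord], lof = lofs[ord],
       trajectory = trajectory)
}

#' Genetic function approximation
#'
#' Evolves a population of linear/spline equations over the descriptor pool,
#' each individual fitted by ordinary least squares and scored by the
#' lack-of-fit ([lof()]) with `LSE = RSS/m`, `c` = number of basis terms and
#' `p` = number of distinct descriptors.  Deterministic for a fixed seed.
#'
#' @param table Descriptor data (variance-filter first).
#' @param activity Observed activity.
#' @param config A [gfa_config()].
#' @return A list of class `gfa_result`: `models` (population of
#'   `spline_model`s sorted by ascending LOF), `lof` (their scores), `best`
#'   (lowest-LOF model), `trajectory` (best LOF after each genetic
#'   operation; non-increasing), `config`.
#' @export
gfa_search <- function(table, activity, config = gfa_config()) {
  m <- as_descriptor_matrix(table)
  y <- as_activity_vector(activity, table)
  if (ncol(m) < 2L) stop_("need at least 2 descriptors")
  if (nrow(m) <= config$max_terms + 1L) {
    stop_("too few observations (n=%d) for max_terms=%d",
          nrow(m), config$max_terms)
  }
  score_fn <- function(terms) {
    fit <- try(ols_fit(terms, m, y), silent = TRUE)
    if (inherits(fit, "try-error")) return(list(lof = Inf, model = NULL))
    p_desc <- length(unique(vapply(fit$terms, `[[`, character(1L),
                                   "descriptor")))
    val <- lof(fit$stats$RSS / nrow(m), c = length(fit$terms), d = config$d,
               p = p_desc, m = nrow(m))
    # numerically tied LOF values (e.g. several exact fits) resolve toward
    # the smaller equation; far below any meaningful LOF difference
    list(lof = val + 1e-12 * length(fit$terms), model = fit)
  }
  res <- with_seed(config$seed, run_ga(m, config, score_fn))
  # memetic refinement of the champion: deterministic backward pruning and
  # exhaustive knot polishing until no move lowers the (tie-broken) LOF.
  # This collapses plateaus of numerically tied fits (e.g. two adjacent-knot
  # splines emulating one) onto the minimal equation and locks knots onto
  # their best observed values.
  ref <- refine_terms(res$population[[1L]], res$lof[1L], m, config, score_fn)
  models <- lapply(res$scored, `[[`, "model")
  models[[1L]] <- ref$model
  lofs <- res$lof
  lofs[1L] <- ref$lof
  structure(list(models = models, lof = lofs, best = models[[1L]],
                 trajectory = res$trajectory, config = config),
            class = "gfa_result")
}

refine_terms <- function(terms, lof0, m, cfg, score_fn, polish_knots = TRUE) {
  # coordinate-descent knot polish: exhaustive over observed interior values,
  # one spline term at a time, strict improvements only
  polish <- function(state) {
    repeat {
      moved <- FALSE
      for (j in seq_along(state$terms)) {
        if (is.null(state$terms[[j]]$knot)) next
        vals <- sort(unique(m[, state$terms[[j]]$descriptor]))
        if (length(vals) < 3L) next
        for (v in vals[-c(1L, length(vals))]) {
          cand <- state$terms
          cand[[j]]$knot <- v
          sc <- score_fn(cand)
          if (sc$lof < state$lof) {
            state <- list(terms = cand, lof = sc$lof, model = sc$model)
            moved <- TRUE
          }
        }
      }
      if (!moved) return(state)
    }
  }
  best <- list(terms = terms, lof = lof0, model = NULL)
  if (polish_knots) best <- polish(best)
  repeat {
    improved <- FALSE
    # backward pruning; each pruned candidate gets its own knot polish, so
    # plateaus of tied exact fits (e.g. two splines emulating one) collapse
    if (length(best$terms) > cfg$min_terms) {
      for (j in seq_along(best$terms)) {
        sc <- score_fn(best$terms[-j])
        cand <- list(terms = best$terms[-j], lof = sc$lof, model = sc$model)
        if (polish_knots) cand <- polish(cand)
        if (cand$lof < best$lof) {
          best <- cand
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  if (is.null(best$model)) best$model <- score_fn(best$terms)$model
  best
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("<gfa_result: population %d, best LOF %.6g>\n",
              length(x$models), x$lof[1L]))
  print(x$best)
  invisible(x)
}
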