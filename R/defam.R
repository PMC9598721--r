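#' Differential-evolution hyperparameters for FAM optimization
#'
#' @param F Scale factor for the classic mutation strategies (default 1.0).
#' @param F1,F2 Scale factors of the neighborhood-to-best mutation
#'   `V = x_r3 + F1 (x_best - x_r3) + F2 (x_r1 - x_r2)`; both default to `F`.
#' @param CR Crossover rate in `[0, 1]` (default 0.7).
#' @param generations Number of DE generations.
#' @param neigh_frac Fraction of top-ranked members eligible as mutation
#'   neighbors, in `[0.3, 0.6]`.
#' @param catmin,catmax Category-count bounds of the fitness; a good `catmin`
#'   equals the number of classes, and feasibility requires
#'   `n_classes <= catmin <= catmax`.
#' @param crossover_dialect `"canonical"` (`rand <= CR` takes the mutant,
#'   default) or `"printed"` (`rand > CR`), the inverted inequality retained
#'   behind a flag.
#' @param penalty Finite fitness assigned to infeasible members (category
#'   count outside `[catmin, catmax)` or zero accuracy).
#' @param fitness_form Numerator form of the guarded fitness:
#'   `"balanced"` (default) adds the accuracy-deficit term
#'   `catmin * (100 - pcc)` to the absolute numerator, which removes the
#'   spurious zero set `pcc * Na = 100 * catmin` (reachable at low accuracy)
#'   while leaving the optimum at `Na = catmin, pcc = 100`; `"guarded"` is
#'   the bare absolute numerator `|100 catmin - pcc Na|`.
#' @param stagnation Stop early after this many generations without best-
#'   fitness improvement (with a warning); `Inf` disables.
#' @param seed Integer seed for all DE randomness.
#' @return An object of class `de_params`.
#' @export
de_params <- function(F = 1.0, F1 = F, F2 = F, CR = 0.7, generations = 30,
                      neigh_frac = 0.5, catmin = 2, catmax = 20,
                      crossover_dialect = c("canonical", "printed"),
                      penalty = 1e6, stagnation = Inf, seed = 1,
                      fitness_form = c("balanced", "guarded")) {
  crossover_dialect <- match.arg(crossover_dialect)
  fitness_form <- match.arg(fitness_form)
  if (CR < 0 || CR > 1) stop("`CR` must lie in [0, 1]", call. = FALSE)
  if (neigh_frac < 0.3 || neigh_frac > 0.6) {
    stop("`neigh_frac` must lie in [0.3, 0.6]", call. = FALSE)
  }
  if (catmin > catmax) stop("`catmin` must not exceed `catmax`", call. = FALSE)
  structure(list(F = F, F1 = F1, F2 = F2, CR = CR,
                 generations = as.integer(generations),
                 neigh_frac = neigh_frac, catmin = as.integer(catmin),
                 catmax = as.integer(catmax),
                 crossover_dialect = crossover_dialect,
                 penalty = penalty, stagnation = stagnation,
                 seed = as.integer(seed), fitness_form = fitness_form),
            class = "de_params")
}

#' Encode a FAM network as a fixed-length real vector
#'
#' Fixed-capacity slot layout so every population member has the same
#' dimension `D = catmax * (2d + 2)`: each of the `catmax` slots holds `2d`
#' weight components, one label gene (index into the class alphabet) and one
#' validity gene (slot active iff `>= 0.5`). Unused slots are zeroed.
#'
#' @param network A [fam_network] with at most `catmax` categories.
#' @param catmax Slot capacity.
#' @param classes Class alphabet; defaults to the network's sorted labels.
#' @return Numeric vector of class `fam_encoding` with attributes `d`,
#'   `catmax`, `classes`, `alpha`.
#' @export
fam_encode <- function(network, catmax, classes = sort(unique(network$labels))) {
  stopifnot(inherits(network, "fam_network"))
  Na <- nrow(network$W)
  if (Na > catmax) {
    stop("network has ", Na, " categories but capacity is ", catmax, call. = FALSE)
  }
  d <- network$d
  slot <- 2L * d + 2L
  v <- numeric(catmax * slot)
  for (j in seq_len(Na)) {
    base <- (j - 1L) * slot
    v[base + seq_len(2L * d)] <- network$W[j, ]
    v[base + 2L * d + 1L] <- match(network$labels[j], classes)
    v[base + 2L * d + 2L] <- 1
  }
  structure(v, d = d, catmax = as.integer(catmax), classes = classes,
            alpha = network$alpha, class = "fam_encoding")
}

#' Decode an encoded vector back into a FAM network
#'
#' Slots with validity gene `>= 0.5` become categories; weight genes are
#' clipped to `[0, 1]` and label genes rounded to the nearest valid class
#' index.
#'
#' @param enc A `fam_encoding` (attributes may ride on a plain numeric vector
#'   after DE arithmetic; they are preserved by [de_child()]).
#' @return A [fam_network]; zero active slots give a 0-category network.
#' @export
fam_decode <- function(enc) {
  d <- attr(enc, "d"); catmax <- attr(enc, "catmax")
  classes <- attr(enc, "classes"); alpha <- attr(enc, "alpha")
  stopifnot(!is.null(d), !is.null(catmax))
  slot <- 2L * d + 2L
  W <- matrix(numeric(0), 0, 2L * d)
  labels <- character(0)
  for (j in seq_len(catmax)) {
    base <- (j - 1L) * slot
    if (enc[base + slot] >= 0.5) {
      W <- rbind(W, pmin(pmax(enc[base + seq_len(2L * d)], 0), 1))
      li <- min(max(round(enc[base + 2L * d + 1L]), 1L), length(classes))
      labels <- c(labels, classes[li])
    }
  }
  fam_network(W, labels, alpha = alpha)
}

# Carry encoding attributes from a parent onto a raw numeric child vector.
de_child <- function(v, parent) {
  structure(as.numeric(v), d = attr(parent, "d"), catmax = attr(parent, "catmax"),
            classes = attr(parent, "classes"), alpha = attr(parent, "alpha"),
            class = "fam_encoding")
}

#' Classic DE mutation strategies
#'
#' The four textbook strategies, applied to a list of encoded members:
#' `rand/1`, `best/1`, `rand-to-best/1` and `rand/2`. Donor indices are drawn
#' uniformly, distinct from each other and from `i`.
#'
#' @param pop List of equal-length numeric vectors.
#' @param i Target index.
#' @param fitness Numeric fitness values (smaller is better); needed by the
#'   `best` strategies.
#' @param strategy One of `"rand/1"`, `"best/1"`, `"rand-to-best/1"`, `"rand/2"`.
#' @param params A [de_params()] (supplies `F`).
#' @return The mutant vector.
#' @export
de_mutate_classic <- function(pop, i, fitness, strategy = c("rand/1", "best/1",
                              "rand-to-best/1", "rand/2"), params = de_params()) {
  strategy <- match.arg(strategy)
  N <- length(pop)
  need <- switch(strategy, "rand/1" = 3, "best/1" = 2, "rand-to-best/1" = 2, "rand/2" = 5)
  if (N - 1L < need) stop("population too small for ", strategy, call. = FALSE)
  r <- sample(setdiff(seq_len(N), i), need)
  Fs <- params$F
  best <- pop[[which.min(fitness)]]
  v <- switch(strategy,
    "rand/1"         = pop[[r[1]]] + Fs * (pop[[r[2]]] - pop[[r[3]]]),
    "best/1"         = best + Fs * (pop[[r[1]]] - pop[[r[2]]]),
    "rand-to-best/1" = pop[[i]] + Fs * (best - pop[[i]]) + Fs * (pop[[r[1]]] - pop[[r[2]]]),
    "rand/2"         = pop[[r[1]]] + Fs * (pop[[r[2]]] - pop[[r[3]]]) +
                       Fs * (pop[[r[4]]] - pop[[r[5]]])
  )
  de_child(v, pop[[i]])
}

#' Neighborhood-to-best DE mutation
#'
#' The modified strategy driving the FAM evolution:
#' `V = x_r3 + F1 (x_best - x_r3) + F2 (x_r1 - x_r2)`, where `x_best` is the
#' global best member and `r1, r2, r3` are distinct indices drawn uniformly
#' from the top `neigh_frac` fraction of the fitness ranking (at least 3
#' members). Restricting donors to high-fitness neighbors speeds convergence
#' while the pull toward `x_best` keeps the search directed.
#'
#' @param pop List of encoded members.
#' @param fitness Numeric fitness values (smaller is better).
#' @param params A [de_params()].
#' @return The mutant vector.
#' @export
de_mutate_neigh_to_best <- function(pop, fitness, params = de_params()) {
  N <- length(pop)
  pool_size <- max(3L, ceiling(params$neigh_frac * N))
  if (N < 3L) stop("neighborhood mutation needs a pool of at least 3 members",
                   call. = FALSE)
  pool_size <- min(pool_size, N)
  ranking <- order(fitness, seq_len(N))
  pool <- ranking[seq_len(pool_size)]
  r <- sample(pool, 3L)
  best <- pop[[ranking[1L]]]
  v <- pop[[r[3]]] + params$F1 * (best - pop[[r[3]]]) +
    params$F2 * (pop[[r[1]]] - pop[[r[2]]])
  de_child(v, pop[[1L]])
}

#' Binomial crossover
#'
#' Builds the trial vector from target `x` and mutant `v`. In the canonical
#' dialect component `j` comes from the mutant when `rand_j <= CR` or
#' `j == jrand` (one component is always inherited from the mutant); the
#' `"printed"` dialect inverts the inequality to `rand_j > CR`.
#'
#' @param x Target vector.
#' @param v Mutant vector (same length).
#' @param CR Crossover rate in `[0, 1]`.
#' @param dialect `"canonical"` or `"printed"`.
#' @return The trial vector.
#' @export
de_crossover <- function(x, v, CR, dialect = c("canonical", "printed")) {
  dialect <- match.arg(dialect)
  if (CR < 0 || CR > 1) stop("`CR` must lie in [0, 1]", call. = FALSE)
  D <- length(x)
  stopifnot(length(v) == D)
  jrand <- sample.int(D, 1L)
  rnd <- stats::runif(D)
  from_v <- if (dialect == "canonical") rnd <= CR else rnd > CR
  from_v[jrand] <- TRUE
  u <- ifelse(from_v, v, x)
  de_child(u, x)
}

#' Guarded fitness of an encoded FAM network
#'
#' Decodes the member, measures accuracy `pcc` (percent correct) and active
#' category count `Na` on the evaluation set, and scores
#' `numerator / ((catmax - Na) pcc^2)` when `catmin <= Na < catmax` and
#' `pcc > 0`, minimized. The default (`"balanced"`) numerator is
#' `|100 catmin - pcc Na| + catmin (100 - pcc)`; its only zero — the
#' optimum — is the smallest feasible network at full accuracy
#' (`Na = catmin`, `pcc = 100`). The bare `"guarded"` numerator
#' `|100 catmin - pcc Na|` also vanishes along the whole hyperbola
#' `pcc Na = 100 catmin`, which contains low-accuracy networks the
#' evolution would otherwise happily converge to; the accuracy-deficit term
#' removes that spurious optimum set. Members outside the feasible band (or
#' with zero accuracy) get the finite `params$penalty` plus their distance
#' to feasibility, so the search is still pulled toward the band.
#'
#' @param enc A `fam_encoding`.
#' @param x_eval,labels_eval Evaluation features and labels.
#' @param params A [de_params()] (supplies `catmin`, `catmax`, `penalty`,
#'   `fitness_form`).
#' @return A list `(pcc, Na, value)` of class `fitness_record`.
#' @export
defam_fitness <- function(enc, x_eval, labels_eval, params) {
  net <- fam_decode(enc)
  Na <- n_categories(net)
  pcc <- if (Na == 0L) 0 else fam_evaluate(net, x_eval, labels_eval)
  feasible <- Na >= params$catmin && Na < params$catmax && pcc > 0
  value <- if (feasible) {
    num <- abs(100 * params$catmin - pcc * Na)
    if (identical(params$fitness_form, "balanced")) {
      num <- num + params$catmin * (100 - pcc)
    }
    num / ((params$catmax - Na) * pcc^2)
  } else {
    params$penalty + max(0, params$catmin - Na) + max(0, Na - params$catmax + 1) +
      (100 - pcc) / 100
  }
  structure(list(pcc = pcc, Na = Na, value = value), class = "fitness_record")
}

#' Raw printed form of the fitness (unguarded)
#'
#' The unguarded ratio `(100 catmin - pcc Na) / ((catmax - Na) pcc^2)` as
#' printed, retained for inspection; it is signed and diverges as `Na`
#' approaches `catmax`. Not used by the optimizer.
#'
#' @inheritParams defam_fitness
#' @param pcc,Na Accuracy and category count.
#' @param catmin,catmax Category bounds.
#' @return Numeric value (possibly infinite).
#' @export
defam_fitness_raw <- function(pcc, Na, catmin, catmax) {
  (100 * catmin - pcc * Na) / ((catmax - Na) * pcc^2)
}

#' Pairwise DE selection
#'
#' Keeps the member with the smaller guarded fitness value; ties keep the
#' target.
#'
#' @param x,u Target and trial vectors.
#' @param fit_x,fit_u Their `fitness_record`s.
#' @return List `(member, fitness, replaced)`.
#' @export
de_select <- function(x, u, fit_x, fit_u) {
  if (fit_u$value < fit_x$value) {
    list(member = u, fitness = fit_u, replaced = TRUE)
  } else {
    list(member = x, fitness = fit_x, replaced = FALSE)
  }
}

#' Evolve a population of trained FAM networks
#'
#' Encodes the initial networks (fixed capacity `catmax`), then iterates
#' generations of fitness ranking, neighborhood-to-best mutation, binomial
#' crossover and pairwise selection. Selection is elitist per member, so the
#' best guarded fitness never increases across generations. Returns the
#' decoded best network, its fitness record and a per-generation trace.
#'
#' @param networks List of at least 6 trained [fam_network]s (e.g. from
#'   [fam_population()]); all must share feature dimension and class set.
#' @param x_eval,labels_eval Evaluation set scored by the fitness.
#' @param params A [de_params()]; `params$seed` fixes all DE randomness.
#' @return An object of class `defam_fit`: list with `best_network`,
#'   `best_fitness`, `trace` (tibble: generation, best_value, best_pcc,
#'   best_na), `population`, `params`.
#' @export
defam_evolve <- function(networks, x_eval, labels_eval, params = de_params()) {
  if (length(networks) < 6L) {
    stop("need at least 6 initial networks to seed the population", call. = FALSE)
  }
  classes <- sort(unique(unlist(lapply(networks, function(n) n$labels))))
  if (max(vapply(networks, n_categories, 1L)) > params$catmax) {
    stop("an initial network exceeds catmax categories; raise catmax or ",
         "lower population vigilance", call. = FALSE)
  }
  set.seed(params$seed)
  pop <- lapply(networks, fam_encode, catmax = params$catmax, classes = classes)
  fits <- lapply(pop, defam_fitness, x_eval = x_eval,
                 labels_eval = labels_eval, params = params)
  values <- vapply(fits, `[[`, numeric(1), "value")

  trace_row <- function(g) {
    b <- which.min(values)
    tibble::tibble(generation = g, best_value = values[b],
                   best_pcc = fits[[b]]$pcc, best_na = fits[[b]]$Na)
  }
  trace <- trace_row(0L)
  stale <- 0L

  for (g in seq_len(params$generations)) {
    improved <- FALSE
    for (i in seq_along(pop)) {
      v <- de_mutate_neigh_to_best(pop, values, params)
      u <- de_crossover(pop[[i]], v, params$CR, params$crossover_dialect)
      fit_u <- defam_fitness(u, x_eval, labels_eval, params)
      sel <- de_select(pop[[i]], u, fits[[i]], fit_u)
      if (sel$replaced) {
        if (fit_u$value < min(values)) improved <- TRUE
        pop[[i]] <- sel$member
        fits[[i]] <- sel$fitness
        values[i] <- sel$fitness$value
      }
    }
    trace <- dplyr::bind_rows(trace, trace_row(g))
    stale <- if (improved) 0L else stale + 1L
    if (stale >= params$stagnation) {
      warning("DE stagnated for ", stale, " generations; returning best so far",
              call. = FALSE)
      break
    }
  }

  b <- which.min(values)
  structure(list(best_network = fam_decode(pop[[b]]), best_fitness = fits[[b]],
                 trace = trace, population = pop, params = params),
            class = "defam_fit")
}

#' @export
print.defam_fit <- function(x, ...) {
  cat(sprintf(
    "<defam_fit> %d generations | best fitness %.4g (pcc %.1f%%, %d categories)\n",
    max(x$trace$generation), x$best_fitness$value, x$best_fitness$pcc,
    x$best_fitness$Na))
  invisible(x)
}
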