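#' Fuzzy ARTMAP hyperparameters
#'
#' @param rho Baseline vigilance in `[0, 1]`. The default 1.0 is capped
#'   internally to `1 - 1e-9` so the match test `|AI ^ W| / |AI| >= rho`
#'   never hinges on float equality.
#' @param alpha Choice parameter, `> 0`; small values reduce recoding.
#' @param beta Learning rate in `[0, 1]`; 1 is fast learning.
#' @param epsilon Match-tracking increment added to the winner's match ratio
#'   when its label disagrees with the pattern's.
#' @param epochs Number of passes over the training set.
#' @param update Weight update rule: `"convex"` (the standard fuzzy-ART
#'   update `beta * (AI ^ W) + (1 - beta) * W`, default) or `"printed"`
#'   (the additive form `W + beta * (AI ^ W)`, kept for auditability; it
#'   grows weights beyond `[0, 1]` and is clipped back).
#' @param delta Unbound tuning constant carried in configs for completeness;
#'   not used by the training dynamics.
#' @return An object of class `fam_params`.
#' @export
fam_params <- function(rho = 1.0, alpha = 0.001, beta = 0.8, epsilon = 0.001,
                       epochs = 5, update = c("convex", "printed"), delta = 0.2) {
  update <- match.arg(update)
  stopifnot(rho >= 0, rho <= 1, alpha > 0, beta >= 0, beta <= 1,
            epsilon > 0, epochs >= 1)
  structure(list(rho = rho, alpha = alpha, beta = beta, epsilon = epsilon,
                 epochs = as.integer(epochs), update = update, delta = delta),
            class = "fam_params")
}

#' Complement-code a unit-interval vector
#'
#' Maps `a` to `(a, 1 - a)`, doubling the dimension and fixing the L1 norm at
#' `d`, which keeps the vigilance denominator constant across inputs.
#'
#' @param a Numeric vector with every component in `[0, 1]`.
#' @return Numeric vector of length `2 * length(a)`.
#' @examples
#' complement_code(c(0.2, 0.7))  # 0.2 0.7 0.8 0.3
#' @export
complement_code <- function(a) {
  bad <- which(a < 0 | a > 1)
  if (length(bad)) {
    stop("feature components outside [0, 1] at index ", bad[1],
         "; rescale before coding", call. = FALSE)
  }
  c(a, 1 - a)
}

# Componentwise fuzzy AND (min) of a coded input against each category row.
fuzzy_and_norms <- function(W, AI) {
  # rowSums(pmin(W, AI)) with AI recycled across rows
  AImat <- matrix(AI, nrow = nrow(W), ncol = length(AI), byrow = TRUE)
  rowSums(pmin(W, AImat))
}

#' Category choice values
#'
#' `T_j = |AI ^ W_j|_1 / (alpha + |W_j|_1)` for every stored category; the
#' winner of the competition is `argmax T_j` (ties to the lowest index).
#'
#' @param network A [fam_network].
#' @param AI Complement-coded input of length `2d`.
#' @return Numeric vector of choice values, one per category.
#' @export
choice_values <- function(network, AI) {
  stopifnot(inherits(network, "fam_network"))
  if (length(AI) != 2L * network$d) {
    stop("coded input has length ", length(AI), ", expected ", 2L * network$d,
         call. = FALSE)
  }
  fuzzy_and_norms(network$W, AI) / (network$alpha + rowSums(network$W))
}

#' Vigilance test
#'
#' `TRUE` iff `|AI ^ W|_1 / |AI|_1 >= rho`.
#'
#' @param AI Complement-coded input.
#' @param W One category weight vector.
#' @param rho Vigilance in `[0, 1]`.
#' @return Logical.
#' @export
vigilance_pass <- function(AI, W, rho) {
  nAI <- sum(AI)
  if (nAI == 0) stop("zero-norm coded input: vigilance undefined", call. = FALSE)
  sum(pmin(AI, W)) / nAI >= rho
}

cap_rho <- function(rho) min(rho, 1 - 1e-9)

#' Train a Fuzzy ARTMAP classifier
#'
#' Incremental supervised training: each feature vector is complement-coded;
#' the first pattern of a label seeds a new category with `W = AI`; later
#' patterns compete through the choice function, must pass the vigilance
#' test, and either update the winning category (label agrees) or trigger
#' match tracking (vigilance is raised just above the winner's match ratio
#' and the search resumes; the raise lasts for the current pattern only).
#' A pattern that exhausts all categories commits a new one.
#'
#' @param x Numeric matrix, rows = patterns, columns = features in `[0, 1]`.
#' @param labels Vector of class labels, one per row of `x`.
#' @param params A [fam_params()].
#' @param order_seed Optional integer; when given, the presentation order is
#'   a seeded shuffle (the same order every epoch). `NULL` keeps row order.
#' @return An object of class `fam_network` with elements `W` (categories x
#'   `2d` weight matrix), `labels` (category class map), `d`, `alpha`,
#'   `params`, `order_seed`.
#' @export
fam_train <- function(x, labels, params = fam_params(), order_seed = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (length(labels) != nrow(x)) stop("one label per pattern required", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("features must be scaled to [0, 1]", call. = FALSE)
  labels <- as.character(labels)
  d <- ncol(x)
  rho_base <- cap_rho(params$rho)

  order_idx <- seq_len(nrow(x))
  if (!is.null(order_seed)) {
    # shuffle without disturbing the caller's RNG stream
    old <- .Random.seed_exists()
    set.seed(order_seed)
    order_idx <- sample.int(nrow(x))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }

  W <- matrix(numeric(0), nrow = 0, ncol = 2L * d)
  cat_labels <- character(0)
  seen_labels <- character(0)

  for (epoch in seq_len(params$epochs)) {
    for (i in order_idx) {
      AI <- complement_code(x[i, ])
      l <- labels[i]
      if (!(l %in% seen_labels)) {
        W <- rbind(W, AI)
        cat_labels <- c(cat_labels, l)
        seen_labels <- c(seen_labels, l)
        next
      }
      rho <- rho_base
      Tj <- fuzzy_and_norms(W, AI) / (params$alpha + rowSums(W))
      # stable ranking: descending T, ties to lower index
      rank_order <- order(-Tj, seq_along(Tj))
      committed <- FALSE
      for (J in rank_order) {
        match_ratio <- sum(pmin(AI, W[J, ])) / sum(AI)
        if (match_ratio < rho) next
        if (cat_labels[J] == l) {
          W[J, ] <- fam_update(W[J, ], AI, params)
          committed <- TRUE
          break
        }
        # match tracking: raise vigilance just above this winner's match
        rho <- cap_rho(match_ratio + params$epsilon)
      }
      if (!committed) {
        W <- rbind(W, AI)
        cat_labels <- c(cat_labels, l)
      }
    }
  }
  rownames(W) <- NULL
  structure(list(W = W, labels = cat_labels, d = d, alpha = params$alpha,
                 params = params, order_seed = order_seed),
            class = "fam_network")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

fam_update <- function(W_old, AI, params) {
  if (params$update == "convex") {
    params$beta * pmin(AI, W_old) + (1 - params$beta) * W_old
  } else {
    pmin(W_old + params$beta * pmin(AI, W_old), 1)
  }
}

#' Build a FAM network from explicit weights
#'
#' Mostly for tests and for decoding evolved encodings.
#'
#' @param W Categories x `2d` weight matrix, entries in `[0, 1]`.
#' @param labels One class label per category.
#' @param alpha Choice parameter.
#' @return A `fam_network`.
#' @export
fam_network <- function(W, labels, alpha = 0.001) {
  stopifnot(is.matrix(W), nrow(W) == length(labels), ncol(W) %% 2 == 0)
  structure(list(W = W, labels = as.character(labels), d = ncol(W) %/% 2L,
                 alpha = alpha, params = NULL, order_seed = NULL),
            class = "fam_network")
}

#' @export
print.fam_network <- function(x, ...) {
  cat(sprintf("<fam_network> %d categories, %d features, %d classes\n",
              nrow(x$W), x$d, length(unique(x$labels))))
  invisible(x)
}

#' Predict class labels with a trained FAM network
#'
#' Each pattern is complement-coded and assigned the label of the category
#' with the largest choice value; no vigilance test is applied at prediction,
#' and ties go to the lowest category index.
#'
#' @param network A `fam_network`.
#' @param x Feature matrix (rows = patterns) or single feature vector,
#'   components in `[0, 1]`.
#' @return Character vector of predicted labels.
#' @export
fam_predict <- function(network, x) {
  stopifnot(inherits(network, "fam_network"))
  if (nrow(network$W) == 0L) stop("untrained network", call. = FALSE)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  vapply(seq_len(nrow(x)), function(i) {
    Tj <- choice_values(network, complement_code(x[i, ]))
    network$labels[which.max(Tj)]
  }, character(1))
}

#' Classification accuracy of a FAM network
#'
#' @param network A `fam_network`.
#' @param x Feature matrix.
#' @param labels True labels.
#' @return Percentage of correct classifications in `[0, 100]`.
#' @export
fam_evaluate <- function(network, x, labels) {
  if (length(labels) == 0L) stop("empty evaluation set", call. = FALSE)
  pred <- fam_predict(network, x)
  100 * mean(pred == as.character(labels))
}

#' Number of stored categories
#'
#' @param network A `fam_network`.
#' @return Integer category count.
#' @export
n_categories <- function(network) {
  stopifnot(inherits(network, "fam_network"))
  nrow(network$W)
}

#' Serialize / restore a FAM network as JSON
#'
#' @param network A `fam_network`.
#' @param path File path; `fam_to_json` writes, `fam_from_json` reads.
#' @return `fam_to_json`: `path` invisibly; `fam_from_json`: a `fam_network`.
#' @export
fam_to_json <- function(network, path) {
  stopifnot(inherits(network, "fam_network"))
  obj <- list(d = network$d, alpha = network$alpha,
              labels = network$labels,
              weights = apply(network$W, 1, identity, simplify = FALSE),
              order_seed = network$order_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fam_to_json
#' @export
fam_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- obj$weights
  if (is.list(W)) W <- do.call(rbind, W)
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  fam_network(W, obj$labels, alpha = obj$alpha)
}

#' Train a diverse population of FAM networks
#'
#' Produces the seed population for [defam_evolve()]: `n` networks trained on
#' the same data with shuffled presentation orders and vigilance jittered
#' uniformly over `rho_range`, the two levers that drive category
#' proliferation and hence population diversity.
#'
#' @param x Feature matrix in `[0, 1]`.
#' @param labels Training labels.
#' @param n Population size (>= 6 for the evolution step).
#' @param params Base [fam_params()]; `rho` is replaced per member.
#' @param rho_range Vigilance jitter interval.
#' @param seed Integer seed controlling orders and jitter.
#' @return A list of `fam_network`s.
#' @export
fam_population <- function(x, labels, n = 10, params = fam_params(),
                           rho_range = c(0.5, 0.9), seed = 1) {
  set.seed(seed)
  rhos <- stats::runif(n, rho_range[1], rho_range[2])
  order_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  lapply(seq_len(n), function(k) {
    pk <- params
    pk$rho <- rhos[k]
    fam_train(x, labels, pk, order_seed = order_seeds[k])
  })
}
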