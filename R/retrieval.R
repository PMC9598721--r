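#' Index a labeled image set for retrieval
#'
#' Builds the retrieval database: one descriptor histogram per image plus its
#' max-normalized form used for distances. Accepts either a histogram table
#' from [compute_histograms()] or an image table (then histograms are
#' computed here).
#'
#' @param images Data frame with `id`, `label` and either a `hist` or a
#'   `pixels` list-column.
#' @param spec,variant,threshold Passed to [compute_histograms()] when
#'   histograms are absent.
#' @return An `image_db`: tibble with `id`, `label`, `hist`, `feature`
#'   list-columns.
#' @export
index_images <- function(images, spec = nbhd_spec(),
                         variant = c("avn", "classic"), threshold = 1) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(images), all(c("id", "label") %in% names(images)))
  if (!"hist" %in% names(images)) {
    images <- compute_histograms(images, spec, variant, threshold)
  }
  if (any(table(images$label) < 1L)) stop("every class needs >= 1 image", call. = FALSE)
  lens <- lengths(images$hist)
  if (length(unique(lens)) != 1L) {
    stop("all histograms must have identical length", call. = FALSE)
  }
  db <- tibble::as_tibble(images[, c("id", "label", "hist")])
  db$feature <- normalize_histogram(db$hist)
  class(db) <- c("image_db", class(db))
  db
}

# Histogram distances on max-normalized features.
hist_distance <- function(a, b, distance = c("l1", "chisq")) {
  distance <- match.arg(distance)
  if (distance == "l1") {
    sum(abs(a - b))
  } else {
    num <- (a - b)^2
    den <- a + b
    sum(ifelse(den > 0, num / den, 0))
  }
}

#' Retrieve the k nearest database images for a query
#'
#' Without a classifier, all entries are ranked by ascending distance between
#' normalized histograms. With a FAM classifier the query's class is
#' predicted first and same-class entries are ranked ahead of the rest (each
#' block ordered by distance) — classify, then search. Ties break by database
#' order.
#'
#' @param db An [index_images()] database.
#' @param query A query histogram (counts vector), an image matrix, or a
#'   one-row tibble with a `hist` entry.
#' @param k Number of images to retrieve, `1 <= k <= nrow(db)`.
#' @param classifier Optional [fam_network] trained on normalized histograms.
#' @param distance `"l1"` (default) or `"chisq"`.
#' @param spec,variant Used only when `query` is a raw image.
#' @return Tibble `rank, id, label, distance` (plus `predicted_label` when a
#'   classifier is used), distances non-decreasing within each block.
#' @export
retrieve_images <- function(db, query, k, classifier = NULL,
                            distance = c("l1", "chisq"),
                            spec = nbhd_spec(), variant = "avn") {
  distance <- match.arg(distance)
  if (k < 1 || k > nrow(db)) stop("`k` must lie in [1, nrow(db)]", call. = FALSE)
  if (is.matrix(query)) query <- lbp_histogram(query, spec, variant)
  if (is.data.frame(query)) query <- query$hist[[1]]
  qf <- normalize_histogram(query)
  d <- vapply(db$feature, hist_distance, numeric(1), b = qf, distance = distance)
  if (is.null(classifier)) {
    ord <- order(d, seq_along(d))
    out <- tibble::tibble(rank = seq_len(k), id = db$id[ord][seq_len(k)],
                          label = db$label[ord][seq_len(k)],
                          distance = d[ord][seq_len(k)])
  } else {
    pred <- fam_predict(classifier, qf)
    same <- db$label == pred
    ord <- order(!same, d, seq_along(d))
    out <- tibble::tibble(rank = seq_len(k), id = db$id[ord][seq_len(k)],
                          label = db$label[ord][seq_len(k)],
                          distance = d[ord][seq_len(k)],
                          predicted_label = pred)
  }
  out
}

#' Precision and recall of one retrieval result
#'
#' `precision = |relevant ∩ retrieved| / n_retrieved`,
#' `recall = |relevant ∩ retrieved| / n_relevant_in_db`, relevance meaning
#' same class as the query.
#'
#' @param result A [retrieve_images()] tibble.
#' @param query_label The query's true class.
#' @param db The database the result came from.
#' @return Named list `(precision, recall, n_retrieved, n_relevant)`.
#' @export
precision_recall <- function(result, query_label, db) {
  if (!all(result$id %in% db$id)) stop("result ids not all present in db", call. = FALSE)
  n_rel <- sum(db$label == query_label)
  if (n_rel == 0L) stop("query class absent from database: recall undefined", call. = FALSE)
  hit <- sum(result$label == query_label)
  list(precision = hit / nrow(result), recall = hit / n_rel,
       n_retrieved = nrow(result), n_relevant = n_rel)
}

#' Score retrieval over a set of queries (ARP / ARR)
#'
#' Runs every query through [retrieve_images()] twice — at depth
#' `k_precision` (default 10) for precision, and at
#' `max(n_relevant, k_recall_min)` for recall — and averages: ARP is the mean
#' precision, ARR the mean recall.
#'
#' @param db An [index_images()] database.
#' @param queries Tibble with `label` and a `hist` list-column (e.g. a held-
#'   out [compute_histograms()] table), or `NULL` to use every database entry
#'   as its own query.
#' @param k_precision Retrieval depth for precision (ARP), default 10.
#' @param k_recall_min Minimum depth for recall (ARR), default 10; actual
#'   depth per query is `max(n_relevant, k_recall_min)` capped at `nrow(db)`.
#' @param classifier,distance Passed to [retrieve_images()].
#' @return An object of class `retrieval_metrics`: tibble of per-query
#'   precision/recall with attributes `ARP` and `ARR`.
#' @export
score_retrieval <- function(db, queries = NULL, k_precision = 10,
                            k_recall_min = 10, classifier = NULL,
                            distance = "l1") {
  if (is.null(queries)) queries <- db
  kp <- min(k_precision, nrow(db))
  rows <- purrr::map(seq_len(nrow(queries)), function(q) {
    h <- queries$hist[[q]]
    lab <- queries$label[q]
    n_rel <- sum(db$label == lab)
    res_p <- retrieve_images(db, h, kp, classifier, distance)
    kr <- min(max(n_rel, k_recall_min), nrow(db))
    res_r <- retrieve_images(db, h, kr, classifier, distance)
    tibble::tibble(
      query = if ("id" %in% names(queries)) queries$id[q] else as.character(q),
      label = lab,
      precision = precision_recall(res_p, lab, db)$precision,
      recall = precision_recall(res_r, lab, db)$recall)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ARP") <- mean(out$precision)
  attr(out, "ARR") <- mean(out$recall)
  class(out) <- c("retrieval_metrics", class(out))
  out
}

#' Aggregate retrieval metrics
#'
#' @param metrics A [score_retrieval()] result.
#' @return One-row tibble with `n_queries`, `ARP`, `ARR`.
#' @export
retrieval_summary <- function(metrics) {
  tibble::tibble(n_queries = nrow(metrics),
                 ARP = attr(metrics, "ARP"),
                 ARR = attr(metrics, "ARR"))
}

#' @export
print.retrieval_metrics <- function(x, ...) {
  cat(sprintf("<retrieval_metrics> %d queries | ARP = %.4f | ARR = %.4f\n",
              nrow(x), attr(x, "ARP"), attr(x, "ARR")))
  NextMethod()
}
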