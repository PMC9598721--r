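#' @importFrom generics tidy glance
NULL

#' Tidy a FAM network into a category table
#'
#' One row per stored category: its class label, hyperbox size (L1 norm of
#' the complement-coded weights; `d` for a point category, larger boxes have
#' smaller norms) and the weight matrix row index.
#'
#' @param x A [fam_network].
#' @param ... Unused.
#' @return Tibble with `category`, `label`, `weight_norm`.
#' @method tidy fam_network
#' @export
tidy.fam_network <- function(x, ...) {
  tibble::tibble(category = seq_len(nrow(x$W)),
                 label = x$labels,
                 weight_norm = rowSums(x$W))
}

#' One-row summary of a FAM network
#'
#' @param x A [fam_network].
#' @param ... Unused.
#' @return Tibble with `n_categories`, `n_classes`, `d`, `alpha`.
#' @method glance fam_network
#' @export
glance.fam_network <- function(x, ...) {
  tibble::tibble(n_categories = nrow(x$W),
                 n_classes = length(unique(x$labels)),
                 d = x$d, alpha = x$alpha)
}

#' Tidy a DEFAM fit into its fitness trace
#'
#' @param x A [defam_evolve()] result.
#' @param ... Unused.
#' @return Tibble `generation`, `best_value`, `best_pcc`, `best_na`.
#' @method tidy defam_fit
#' @export
tidy.defam_fit <- function(x, ...) x$trace

#' One-row summary of a DEFAM fit
#'
#' @param x A [defam_evolve()] result.
#' @param ... Unused.
#' @return Tibble with final `best_value`, `best_pcc`, `best_na`,
#'   `generations`, `catmin`, `catmax`.
#' @method glance defam_fit
#' @export
glance.defam_fit <- function(x, ...) {
  tibble::tibble(best_value = x$best_fitness$value,
                 best_pcc = x$best_fitness$pcc,
                 best_na = x$best_fitness$Na,
                 generations = max(x$trace$generation),
                 catmin = x$params$catmin, catmax = x$params$catmax)
}

#' Plot a DEFAM fitness trace
#'
#' Best guarded fitness per generation (log scale when the range warrants
#' it); elitist selection makes the curve non-increasing.
#'
#' @param object A `defam_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot defam_fit
#' @export
autoplot.defam_fit <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$best_value)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "best guarded fitness",
                  title = "DEFAM evolution trace") +
    ggplot2::theme_minimal()
  if (min(tr$best_value) > 0 && max(tr$best_value) / min(tr$best_value) > 50) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' Plot per-query retrieval precision and recall
#'
#' @param object A [score_retrieval()] result.
#' @param ... Unused.
#' @return A ggplot of per-class precision/recall distributions.
#' @method autoplot retrieval_metrics
#' @export
autoplot.retrieval_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "query class", y = NULL,
                  title = sprintf("ARP = %.3f, ARR = %.3f",
                                  attr(object, "ARP"), attr(object, "ARR"))) +
    ggplot2::theme_minimal()
}

#' Plot a descriptor histogram
#'
#' @param hist A counts vector from [lbp_histogram()].
#' @return A ggplot bar chart of code frequencies.
#' @export
plot_histogram <- function(hist) {
  df <- tibble::tibble(code = as.integer(names(hist)), count = as.numeric(hist))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "descriptor code", y = "count") +
    ggplot2::theme_minimal()
}
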