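default_config <- function() {
  list(
    descriptor = list(p = 8, R = 3, theta = 45, variant = "avn", threshold = 1),
    fam = list(rho = 1.0, alpha = 0.001, beta = 0.8, epsilon = 0.001,
               epochs = 5, delta = 0.2),
    de = list(F = 1.0, F1 = 1.0, F2 = 1.0, CR = 0.7, generations = 20,
              neigh_frac = 0.5, catmin = NA, catmax = 20, n_population = 8,
              rho_min = 0.5, rho_max = 0.9),
    retrieval = list(distance = "l1", k_precision = 10, k_recall_min = 10),
    synthetic = list(n_classes = 3, images_per_class = 10, size = 64,
                     family = "grating", snr_db = Inf),
    split = list(train = 0.4, test = 0.3, validation = 0.3),
    seed = 1,
    out_dir = "avnlbp_run"
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (descriptor `p = 8, R = 3, theta = 45`;
#' FAM `rho = 1.0, beta = 0.8, alpha = 0.001`; DE `F = 1.0, CR = 0.7`),
#' overlays a YAML file and then named overrides, and validates every
#' invariant (angular closure `p * theta = 360`, `catmin <= catmax`, split
#' fractions summing to 1, parameter ranges). Unknown keys are an error —
#' misspelled settings never default silently.
#'
#' @param yaml_file Optional YAML file of overrides.
#' @param ... Named overrides as nested lists, e.g.
#'   `descriptor = list(p = 4)`.
#' @return A validated `run_config` (nested list).
#' @export
run_config <- function(yaml_file = NULL, ...) {
  cfg <- default_config()
  overlay <- function(base, over, path = "") {
    for (key in names(over)) {
      full <- paste0(path, key)
      if (!key %in% names(base)) {
        stop("unknown config key: ", full, call. = FALSE)
      }
      if (is.list(base[[key]]) && is.list(over[[key]])) {
        base[[key]] <- overlay(base[[key]], over[[key]], paste0(full, "$"))
      } else {
        base[[key]] <- over[[key]]
      }
    }
    base
  }
  if (!is.null(yaml_file)) cfg <- overlay(cfg, yaml::read_yaml(yaml_file))
  dots <- list(...)
  if (length(dots)) cfg <- overlay(cfg, dots)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  d <- cfg$descriptor
  if (abs(d$p * d$theta - 360) > 1e-8) {
    stop("descriptor invariant violated: p * theta must equal 360", call. = FALSE)
  }
  if (!d$variant %in% c("avn", "classic")) stop("unknown descriptor variant", call. = FALSE)
  f <- cfg$fam
  stopifnot(f$rho >= 0, f$rho <= 1, f$alpha > 0, f$beta >= 0, f$beta <= 1,
            f$epochs >= 1)
  de <- cfg$de
  if (!is.na(de$catmin) && de$catmin > de$catmax) {
    stop("config invariant violated: catmin must not exceed catmax", call. = FALSE)
  }
  if (de$CR < 0 || de$CR > 1) stop("CR must lie in [0, 1]", call. = FALSE)
  s <- cfg$split
  if (abs(s$train + s$test + s$validation - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

# Derive independent per-stage seeds from the master seed (all below 2^31).
stage_seeds <- function(master) {
  stages <- c("generate", "split", "noise", "population", "evolve", "retrieve")
  s <- (as.numeric(master) * 2654435761) %% 2147483647
  out <- as.integer((s + 97 * seq_along(stages)) %% 2147483647)
  stats::setNames(pmax(out, 1L), stages)
}

#' Run the full synthetic-to-metrics pipeline
#'
#' Executes generate -> split -> extract -> train a diverse FAM population ->
#' evolve with DE -> retrieve -> score, writing every artifact under
#' `config$out_dir`: `histograms.csv`, `initial_networks/` and
#' `best_network.json`, `trace.csv`, `metrics.csv`, and `config.json`
#' (the resolved configuration with its seed). One master seed derives
#' per-stage seeds so each stage is independently reproducible.
#'
#' @param config A [run_config()].
#' @param images Optional pre-built image tibble (`id`, `label`, `pixels`);
#'   when `NULL`, textures are generated from `config$synthetic`.
#' @return A list with `db`, `split`, `networks`, `defam`, `metrics`,
#'   `summary`, `paths`.
#' @export
run_pipeline <- function(config = run_config(), images = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # generate
  images <- stage("generate", {
    if (is.null(images)) {
      sp <- config$synthetic
      generate_textures(texture_spec(
        n_classes = sp$n_classes, images_per_class = sp$images_per_class,
        size = sp$size, family = sp$family, snr_db = sp$snr_db),
        seed = seeds[["generate"]])
    } else images
  })

  # split + extract
  split_tbl <- stage("split", split_dataset(
    images, c(train = config$split$train, test = config$split$test,
              validation = config$split$validation), seed = seeds[["split"]]))
  spec <- nbhd_spec(p = config$descriptor$p, R = config$descriptor$R)
  hists <- stage("extract", compute_histograms(
    split_tbl, spec, config$descriptor$variant, config$descriptor$threshold))
  hist_out <- cbind(hists[, c("id", "label", "split")],
                    do.call(rbind, hists$hist))
  utils::write.csv(hist_out, file.path(config$out_dir, "histograms.csv"),
                   row.names = FALSE)

  train_tbl <- hists[hists$split == "train", ]
  valid_tbl <- hists[hists$split == "validation", ]
  test_tbl <- hists[hists$split == "test", ]

  # train FAM population
  fp <- fam_params(rho = config$fam$rho, alpha = config$fam$alpha,
                   beta = config$fam$beta, epsilon = config$fam$epsilon,
                   epochs = config$fam$epochs, delta = config$fam$delta)
  nets <- stage("train", fam_population(
    feature_matrix(train_tbl), train_tbl$label, n = config$de$n_population,
    params = fp, rho_range = c(config$de$rho_min, config$de$rho_max),
    seed = seeds[["population"]]))

  # evolve
  catmin <- config$de$catmin
  if (is.na(catmin)) catmin <- length(unique(images$label))
  dp <- de_params(F = config$de$F, F1 = config$de$F1, F2 = config$de$F2,
                  CR = config$de$CR, generations = config$de$generations,
                  neigh_frac = config$de$neigh_frac, catmin = catmin,
                  catmax = config$de$catmax, seed = seeds[["evolve"]])
  fit <- stage("evolve", defam_evolve(
    nets, feature_matrix(valid_tbl), valid_tbl$label, dp))
  utils::write.csv(fit$trace, file.path(config$out_dir, "trace.csv"),
                   row.names = FALSE)
  fam_to_json(fit$best_network, file.path(config$out_dir, "best_network.json"))

  # retrieve + score: database = train images, queries = test images
  db <- stage("index", index_images(train_tbl, spec,
                                    config$descriptor$variant,
                                    config$descriptor$threshold))
  metrics <- stage("score", score_retrieval(
    db, test_tbl, k_precision = config$retrieval$k_precision,
    k_recall_min = config$retrieval$k_recall_min,
    classifier = fit$best_network, distance = config$retrieval$distance))
  utils::write.csv(as.data.frame(metrics),
                   file.path(config$out_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(db = db, split = split_tbl, networks = nets, defam = fit,
       metrics = metrics, summary = retrieval_summary(metrics),
       paths = file.path(config$out_dir,
                         c("histograms.csv", "trace.csv", "best_network.json",
                           "metrics.csv", "config.json")))
}
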