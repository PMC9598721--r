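#' Specify a synthetic texture database
#'
#' Defines a multi-class texture collection with class-distinct spatial
#' statistics, the stand-in for labeled grayscale image archives used to
#' exercise the full descriptor–classifier–retrieval pipeline. Two texture
#' families are available: sinusoidal gratings (class parameters: orientation
#' in degrees, spatial frequency in cycles/pixel) and Gaussian random fields
#' (class parameter: correlation length in pixels). Per-image phase /
#' realization randomness makes images within a class distinct; class
#' parameters must be pairwise distinct.
#'
#' @param n_classes Number of classes.
#' @param images_per_class Images per class.
#' @param size Image side length in pixels (square images).
#' @param family `"grating"`, `"grf"`, or `"mixed"` (odd classes gratings,
#'   even classes random fields).
#' @param orientations,frequencies Per-class grating parameters (degrees,
#'   cycles/pixel); defaults spread orientations evenly over `[0, 180)` and
#'   fix frequency at 0.125 (an 8-pixel period, matched to the default
#'   7-pixel descriptor window).
#' @param corr_lengths Per-class GRF correlation lengths in pixels.
#' @param snr_db Optional additive Gaussian noise level (dB); `Inf` = clean.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(n_classes = 3, images_per_class = 10, size = 64,
                         family = c("grating", "grf", "mixed"),
                         orientations = seq(0, 180, length.out = n_classes + 1)[-(n_classes + 1)],
                         frequencies = rep(0.125, n_classes),
                         corr_lengths = seq(1, 4, length.out = n_classes),
                         snr_db = Inf) {
  family <- match.arg(family)
  stopifnot(n_classes >= 1, images_per_class >= 1, size >= 16)
  key <- switch(family,
    grating = paste(orientations, frequencies),
    grf = as.character(corr_lengths),
    mixed = paste(orientations, frequencies, corr_lengths))
  if (anyDuplicated(key[seq_len(n_classes)])) {
    stop("class texture parameters must be pairwise distinct", call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 images_per_class = as.integer(images_per_class),
                 size = as.integer(size), family = family,
                 orientations = orientations, frequencies = frequencies,
                 corr_lengths = corr_lengths, snr_db = snr_db),
            class = "texture_spec")
}

# One sinusoidal grating image with random phase and small orientation jitter.
grating_image <- function(size, orientation, frequency) {
  phase <- stats::runif(1, 0, 2 * pi)
  ang <- (orientation + stats::rnorm(1, 0, 1.5)) * pi / 180
  xy <- seq_len(size)
  gx <- outer(rep(1, size), xy)   # column index
  gy <- outer(xy, rep(1, size))   # row index
  wave <- sin(2 * pi * frequency * (gx * cos(ang) + gy * sin(ang)) + phase)
  round(127.5 + 100 * wave)
}

# One Gaussian random field: white noise smoothed by a separable Gaussian
# kernel of the class's correlation length, standardized to mean 127, sd 40.
grf_image <- function(size, corr_length) {
  pad <- ceiling(3 * corr_length)
  n <- size + 2 * pad
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(seq(-pad, pad), sd = corr_length)
  k <- k / sum(k)
  sm <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm <- sm[(pad + 1):(pad + size), (pad + 1):(pad + size)]
  sm <- (sm - mean(sm)) / stats::sd(sm)
  pmin(pmax(round(127 + 40 * sm), 0), 255)
}

#' Generate a synthetic texture database
#'
#' Draws `images_per_class` images per class from the families configured in
#' the [texture_spec()], optionally corrupts them with Gaussian noise at the
#' spec's `snr_db`, and returns a tidy image table. Identical `(spec, seed)`
#' give identical datasets.
#'
#' @param spec A [texture_spec()].
#' @param seed Integer seed.
#' @return Tibble with `id`, `label` and a `pixels` list-column of intensity
#'   matrices.
#' @export
generate_textures <- function(spec = texture_spec(), seed = 1) {
  stopifnot(inherits(spec, "texture_spec"))
  set.seed(seed)
  rows <- list()
  for (cl in seq_len(spec$n_classes)) {
    use_grating <- switch(spec$family,
      grating = TRUE, grf = FALSE, mixed = cl %% 2L == 1L)
    for (im in seq_len(spec$images_per_class)) {
      img <- if (use_grating) {
        grating_image(spec$size, spec$orientations[cl], spec$frequencies[cl])
      } else {
        grf_image(spec$size, spec$corr_lengths[cl])
      }
      img <- pmin(pmax(img, 0), 255)
      if (is.finite(spec$snr_db)) img <- add_gaussian_noise(img, spec$snr_db)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("class_%d/img_%02d", cl, im),
        label = paste0("class_", cl),
        pixels = list(img))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a texture table as a PNG tree with manifest
#'
#' Lays images out as `class_<i>/img_<j>.png` under `dir` and writes
#' `manifest.csv` (`id`, `label`, `path`).
#'
#' @param images Tibble from [generate_textures()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_texture_tree <- function(images, dir) {
  paths <- file.path(dir, paste0(images$id, ".png"))
  for (i in seq_len(nrow(images))) {
    dir.create(dirname(paths[i]), recursive = TRUE, showWarnings = FALSE)
    write_gray_image(images$pixels[[i]], paths[i])
  }
  manifest <- tibble::tibble(id = images$id, label = images$label, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a PNG tree written by [write_texture_tree()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return Tibble with `id`, `label`, `pixels`.
#' @export
read_texture_tree <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  tibble::tibble(id = manifest$id, label = manifest$label,
                 pixels = lapply(manifest$path, read_gray_image))
}

# Largest-remainder apportionment of n into parts proportional to fractions;
# earlier parts win remainder ties (train first).
apportion <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    pri <- order(-(exact - base), seq_along(fractions))
    base[pri[seq_len(rem)]] <- base[pri[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified train/test/validation split
#'
#' Splits each class with a seeded shuffle into the requested fractions
#' (default 40/30/30). Per-class sizes follow the largest-remainder rule with
#' ties resolved in split order (train first), so each size is within one
#' image of the exact fraction.
#'
#' @param images Image or histogram tibble with `id` and `label`.
#' @param fractions Named or unnamed length-3 vector summing to 1
#'   (train, test, validation).
#' @param seed Integer seed for the per-class shuffles.
#' @return The input tibble with an added `split` factor column.
#' @export
split_dataset <- function(images, fractions = c(train = 0.4, test = 0.3,
                                                validation = 0.3), seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  split_names <- names(fractions)
  if (is.null(split_names)) split_names <- c("train", "test", "validation")
  set.seed(seed)
  out <- tibble::as_tibble(images)
  out$split <- NA_character_
  for (cl in unique(out$label)) {
    idx <- which(out$label == cl)
    if (length(idx) < 3L && all(fractions > 0)) {
      stop("class '", cl, "' has fewer than 3 images; cannot split", call. = FALSE)
    }
    sizes <- apportion(length(idx), fractions)
    shuffled <- sample(idx)
    assign_to <- rep(split_names, times = sizes)
    out$split[shuffled] <- assign_to
  }
  out$split <- factor(out$split, levels = split_names)
  out
}
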