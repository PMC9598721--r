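#' Neighborhood specification for LBP-family descriptors
#'
#' Bundles the three geometric parameters shared by the classic LBP operator
#' and the sector-averaged AvN-LBP variant: `p` neighbors/sectors, window
#' radius `R` (pixels), and the angular sector width `theta = 360 / p`
#' (degrees). Defaults are the values used throughout the package: `p = 8`,
#' `R = 3`, `theta = 45`.
#'
#' @param p Number of neighbors (classic LBP) or angular sectors (AvN-LBP).
#' @param R Window radius in pixels.
#' @return An object of class `nbhd_spec`.
#' @examples
#' nbhd_spec()          # p = 8, R = 3, theta = 45
#' nbhd_spec(p = 4, R = 1)
#' @export
nbhd_spec <- function(p = 8, R = 3) {
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p)) {
    stop("`p` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(R) || length(R) != 1L || R < 1 || R != round(R)) {
    stop("`R` must be an integer >= 1", call. = FALSE)
  }
  structure(list(p = as.integer(p), R = as.integer(R), theta = 360 / p),
            class = "nbhd_spec")
}

#' @export
print.nbhd_spec <- function(x, ...) {
  cat(sprintf("<nbhd_spec> p = %d, R = %d, theta = %g degrees\n", x$p, x$R, x$theta))
  invisible(x)
}

# Angle (degrees, [0, 360)) of an offset, measured counter-clockwise from the
# +x axis. Row offsets grow downward, so dy = -di.
offset_angle <- function(di, dj) {
  ang <- atan2(-di, dj) * 180 / pi
  (ang + 360) %% 360
}

#' Partition the square window ring into angular sectors
#'
#' Every offset `(di, dj)` with `0 < max(|di|, |dj|) <= R` of the
#' `(2R+1) x (2R+1)` window is assigned to the half-open angular bin
#' `[n * theta, (n + 1) * theta)`, with angles measured counter-clockwise from
#' the +x axis. For `R = 3, p = 8` each of the 8 sectors receives exactly 6
#' offsets. Sector membership uses the full square window, not a Euclidean
#' disc: it is the rule that makes the per-sector counts equal.
#'
#' @param spec A [nbhd_spec()].
#' @return A list of `p` two-column integer matrices (`di`, `dj`), element
#'   `n + 1` holding sector `n`'s offsets.
#' @export
sector_partition <- function(spec = nbhd_spec()) {
  stopifnot(inherits(spec, "nbhd_spec"))
  R <- spec$R
  grid <- expand.grid(di = -R:R, dj = -R:R)
  grid <- grid[!(grid$di == 0 & grid$dj == 0), ]
  ang <- offset_angle(grid$di, grid$dj)
  # guard float fuzz at exact bin boundaries (multiples of theta)
  sec <- floor((ang + 1e-9) / spec$theta) %% spec$p
  lapply(0:(spec$p - 1L), function(n) {
    m <- as.matrix(grid[sec == n, c("di", "dj"), drop = FALSE])
    dimnames(m) <- list(NULL, c("di", "dj"))
    m
  })
}

# Bilinear sample of image at (possibly fractional) positions.
bilinear_sample <- function(image, rows, cols) {
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  r1 <- pmin(r0 + 1, nrow(image)); c1 <- pmin(c0 + 1, ncol(image))
  i00 <- image[cbind(r0, c0)]; i01 <- image[cbind(r0, c1)]
  i10 <- image[cbind(r1, c0)]; i11 <- image[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

# Circle sampling offsets for classic LBP: neighbor n at angle n * theta,
# counter-clockwise from +x, radius R. Tiny fp residue is rounded away so
# axis-aligned neighbors land on integer pixels.
circle_offsets <- function(spec) {
  ang <- (0:(spec$p - 1L)) * spec$theta * pi / 180
  data.frame(dr = round(-spec$R * sin(ang), 9), dc = round(spec$R * cos(ang), 9))
}

#' Classic LBP code from explicit neighbor values
#'
#' The thresholding-and-accumulation step shared by all classic-LBP entry
#' points: bit `n` is set when `neighbors[n + 1] - center >= threshold`, and
#' the code is `sum(bit_n * 2^n)`.
#'
#' @param neighbors Numeric vector of `p` neighbor intensities in order
#'   `n = 0 .. p - 1`.
#' @param center Center intensity.
#' @param threshold Step-function threshold (default 1: strict `>` on
#'   integer images, as used throughout; 0 gives the conventional `>=`).
#' @return Integer code in `[0, 2^p - 1]`.
#' @examples
#' lbp_code_from_neighbors(c(6, 4, 7, 5, 3, 8, 2, 5), 5)  # 37
#' @export
lbp_code_from_neighbors <- function(neighbors, center, threshold = 1) {
  bits <- (neighbors - center) >= threshold
  sum(bits * 2^(seq_along(neighbors) - 1L))
}

#' Classic LBP code at one pixel
#'
#' Samples `p` neighbors on the circle of radius `R` around the center
#' (start angle 0 degrees, counter-clockwise, bilinear interpolation at
#' fractional positions) and thresholds each against the center with the step
#' `S(x) = 1` iff `x >= threshold`. The default threshold is 1, i.e. a strict
#' "greater than center" test on integer images; set `threshold = 0` for the
#' conventional `>=` comparison.
#'
#' @param image Intensity matrix.
#' @param center Length-2 integer vector `(row, col)` of the center pixel.
#' @param spec A [nbhd_spec()].
#' @param threshold Step-function threshold; bit `n` is set when
#'   `neighbor_n - center >= threshold`.
#' @return Integer code in `[0, 2^p - 1]`.
#' @export
lbp_code <- function(image, center, spec = nbhd_spec(), threshold = 1) {
  image <- gray_image(image)
  i <- center[1]; j <- center[2]; R <- spec$R
  if (i - R < 1 || j - R < 1 || i + R > nrow(image) || j + R > ncol(image)) {
    stop("center is closer than R pixels to the image border", call. = FALSE)
  }
  off <- circle_offsets(spec)
  vals <- bilinear_sample(image, i + off$dr, j + off$dc)
  lbp_code_from_neighbors(vals, image[i, j], threshold)
}

#' Sector means around one pixel
#'
#' For each angular sector of the window partition, the arithmetic mean of the
#' intensities at that sector's offsets, plus the grand mean `mu` of the `p`
#' sector means. These are the quantities AvN-LBP thresholds.
#'
#' @inheritParams lbp_code
#' @param partition A [sector_partition()]; computed from `spec` when omitted.
#' @return A list with `means` (length `p`) and `mu`.
#' @export
sector_means <- function(image, center, spec = nbhd_spec(),
                         partition = sector_partition(spec)) {
  image <- gray_image(image)
  i <- center[1]; j <- center[2]; R <- spec$R
  if (i - R < 1 || j - R < 1 || i + R > nrow(image) || j + R > ncol(image)) {
    stop("window does not fit inside the image at this center", call. = FALSE)
  }
  if (any(vapply(partition, nrow, 1L) == 0L)) {
    stop("sector partition has an empty sector; lower p or raise R", call. = FALSE)
  }
  means <- vapply(partition, function(off) {
    mean(image[cbind(i + off[, "di"], j + off[, "dj"])])
  }, numeric(1))
  list(means = means, mu = mean(means))
}

#' AvN-LBP code from sector means
#'
#' Thresholds each sector mean against the grand mean of the sector means with
#' `S(x) = 1` iff `x >= 0` and accumulates `2^n` over sectors `n = 0..p-1`.
#' A perfectly flat window therefore yields `2^p - 1` (every difference is
#' exactly zero).
#'
#' @param means Numeric vector of `p` sector means, or the list returned by
#'   [sector_means()].
#' @param mu Grand mean; defaults to `mean(means)`.
#' @return Integer code in `[0, 2^p - 1]`.
#' @examples
#' avn_lbp_code(c(160.33, 157.5, 172.66, 157.33, 161.66, 172.66, 192.83, 157.83))
#' @export
avn_lbp_code <- function(means, mu = NULL) {
  if (is.list(means)) {
    mu <- means$mu
    means <- means$means
  }
  if (is.null(mu)) mu <- mean(means)
  bits <- (means - mu) >= 0
  sum(bits * 2^(seq_along(means) - 1L))
}

#' Per-pixel descriptor code map
#'
#' Computes the chosen descriptor at every interior pixel (those whose
#' `(2R+1) x (2R+1)` window fits inside the image; border pixels are skipped,
#' never padded). Fully vectorized via shifted submatrices.
#'
#' @inheritParams lbp_code
#' @param variant `"avn"` (sector-averaged) or `"classic"`.
#' @return An `(N - 2R) x (M - 2R)` integer matrix of codes.
#' @export
lbp_code_map <- function(image, spec = nbhd_spec(),
                         variant = c("avn", "classic"), threshold = 1) {
  variant <- match.arg(variant)
  image <- gray_image(image)
  R <- spec$R
  N <- nrow(image); M <- ncol(image)
  if (N < 2 * R + 1 || M < 2 * R + 1) {
    stop("image smaller than the descriptor window", call. = FALSE)
  }
  rows <- (R + 1):(N - R)
  cols <- (R + 1):(M - R)
  pow <- 2^(0:(spec$p - 1L))
  codes <- matrix(0, length(rows), length(cols))

  if (variant == "avn") {
    part <- sector_partition(spec)
    sector_mean_mats <- lapply(part, function(off) {
      acc <- 0
      for (k in seq_len(nrow(off))) {
        acc <- acc + image[rows + off[k, "di"], cols + off[k, "dj"], drop = FALSE]
      }
      acc / nrow(off)
    })
    mu <- Reduce(`+`, sector_mean_mats) / spec$p
    for (n in seq_len(spec$p)) {
      codes <- codes + pow[n] * ((sector_mean_mats[[n]] - mu) >= 0)
    }
  } else {
    centers <- image[rows, cols, drop = FALSE]
    off <- circle_offsets(spec)
    for (n in seq_len(spec$p)) {
      dr <- off$dr[n]; dc <- off$dc[n]
      if (dr == round(dr) && dc == round(dc)) {
        nb <- image[rows + dr, cols + dc, drop = FALSE]
      } else {
        r0 <- floor(dr); c0 <- floor(dc)
        fr <- dr - r0;   fc <- dc - c0
        nb <- (1 - fr) * (1 - fc) * image[rows + r0,     cols + c0,     drop = FALSE] +
              (1 - fr) * fc       * image[rows + r0,     cols + c0 + 1, drop = FALSE] +
              fr       * (1 - fc) * image[rows + r0 + 1, cols + c0,     drop = FALSE] +
              fr       * fc       * image[rows + r0 + 1, cols + c0 + 1, drop = FALSE]
      }
      codes <- codes + pow[n] * ((nb - centers) >= threshold)
    }
  }
  codes
}

#' Descriptor histogram of an image
#'
#' Tabulates the per-pixel codes of [lbp_code_map()] into a histogram of
#' length `2^p`. Counts sum to the number of interior (coded) pixels,
#' `(N - 2R) * (M - 2R)`.
#'
#' @inheritParams lbp_code_map
#' @return An integer vector of length `2^p`, names `"0" ... "2^p - 1"`.
#' @export
lbp_histogram <- function(image, spec = nbhd_spec(),
                          variant = c("avn", "classic"), threshold = 1) {
  codes <- lbp_code_map(image, spec, variant, threshold)
  counts <- tabulate(as.vector(codes) + 1L, nbins = 2^spec$p)
  names(counts) <- 0:(2^spec$p - 1L)
  counts
}

#' Descriptor histograms for a table of images
#'
#' The tidy entry point for feature extraction: takes a tibble with an image
#' list-column (as produced by [generate_textures()] or built from
#' [read_gray_image()]) and appends a histogram list-column.
#'
#' @param images A data frame with columns `id`, `label` and a list-column
#'   `pixels` of intensity matrices.
#' @param spec A [nbhd_spec()].
#' @param variant `"avn"` or `"classic"`.
#' @param threshold Classic-LBP step threshold (ignored for `"avn"`).
#' @return The input tibble with an added list-column `hist`.
#' @export
compute_histograms <- function(images, spec = nbhd_spec(),
                               variant = c("avn", "classic"), threshold = 1) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(images), "pixels" %in% names(images))
  out <- tibble::as_tibble(images)
  out$hist <- purrr::map(out$pixels, lbp_histogram,
                         spec = spec, variant = variant, threshold = threshold)
  out
}

#' Scale histograms to the unit interval
#'
#' Divides each histogram by its maximum count, the scaling used before FAM
#' training and retrieval distances (complement coding needs `[0, 1]`
#' features). An all-zero histogram maps to itself.
#'
#' @param hist A counts vector, or a list of them.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_histogram <- function(hist) {
  if (is.list(hist)) return(lapply(hist, normalize_histogram))
  m <- max(hist)
  if (m == 0) return(hist)
  hist / m
}

#' Feature matrix from a histogram table
#'
#' Stacks the `hist` list-column of [compute_histograms()] into a numeric
#' matrix (rows = images) scaled to `[0, 1]` by [normalize_histogram()],
#' ready for [fam_train()].
#'
#' @param hist_tbl Output of [compute_histograms()].
#' @return A numeric matrix with rownames from `hist_tbl$id`.
#' @export
feature_matrix <- function(hist_tbl) {
  stopifnot("hist" %in% names(hist_tbl))
  x <- do.call(rbind, normalize_histogram(hist_tbl$hist))
  rownames(x) <- hist_tbl$id
  x
}
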