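#' Construct and validate a grayscale image
#'
#' Images are plain integer matrices with intensities in `[0, 255]`; rows are
#' image rows (y grows downward), columns are image columns. Everything in the
#' package that consumes pixels goes through this check.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`.
#' @return The validated matrix (storage mode integer-valued, class unchanged).
#' @examples
#' img <- gray_image(matrix(0:24 * 10, 5, 5))
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("image contains missing or non-finite intensities", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  pixels
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit grayscale files are read as-is; color inputs are converted by the
#' Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B) with a message. PGM
#' (P2/P5) is parsed directly.
#'
#' @param path File path ending in .png, .tif/.tiff or .pgm.
#' @return An intensity matrix in `[0, 255]` (see [gray_image()]).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = return(gray_image(read_pgm(path))),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      message("color image '", basename(path), "' converted to grayscale by luminance")
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  gray_image(round(arr * 255))
}

#' Write a grayscale image to PNG
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param path Output path (.png).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- gray_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

# Minimal PGM reader (ASCII P2 and binary P5, maxval <= 255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tokens <- character(0)
  while (length(tokens) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
  }
  dims <- as.integer(tokens[1:3])
  w <- dims[1]; h <- dims[2]; maxval <- dims[3]
  if (maxval > 255) stop("16-bit PGM not supported", call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Zero-mean Gaussian noise with variance `var(image) / 10^(snr_db / 10)`
#' (SNR in decibels, variance ratio convention) is added, then intensities are
#' rounded and clipped back to `[0, 255]`. Uses the current RNG state; seed
#' with [set.seed()] for reproducibility. `snr_db = Inf` returns the image
#' unchanged.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param snr_db Target SNR in dB; `Inf` means no noise.
#' @param var_floor Noise-variance base used when the image is constant
#'   (zero signal variance); default 1.
#' @return A noised intensity matrix of the same dimensions.
#' @export
add_gaussian_noise <- function(image, snr_db, var_floor = 1) {
  image <- gray_image(image)
  if (is.infinite(snr_db) && snr_db > 0) return(image)
  if (!is.finite(snr_db)) stop("`snr_db` must be finite or +Inf", call. = FALSE)
  sig_var <- stats::var(as.vector(image))
  if (sig_var == 0) sig_var <- var_floor
  noise_sd <- sqrt(sig_var / 10^(snr_db / 10))
  noised <- image + stats::rnorm(length(image), mean = 0, sd = noise_sd)
  out <- pmin(pmax(round(noised), 0), 255)
  dim(out) <- dim(image)
  out
}
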