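# Independent straight-line oracles used to cross-check the package
# implementations. Written as plain double loops on purpose: no shared code
# with the vectorized paths in R/.

# seeded random test image
random_image <- function(n, m = n, seed = 1, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(sample(lo:hi, n * m, replace = TRUE), n, m)
}

# brute-force per-pixel classic LBP map: explicit trig + bilinear at each pixel
oracle_classic_map <- function(image, p, R, threshold = 1) {
  N <- nrow(image); M <- ncol(image)
  out <- matrix(NA_real_, N - 2 * R, M - 2 * R)
  for (i in (R + 1):(N - R)) for (j in (R + 1):(M - R)) {
    code <- 0
    for (n in 0:(p - 1)) {
      a <- 2 * pi * n / p
      ri <- i - R * sin(a); cj <- j + R * cos(a)
      ri <- round(ri, 9); cj <- round(cj, 9)
      r0 <- floor(ri); c0 <- floor(cj)
      fr <- ri - r0; fc <- cj - c0
      val <- (1 - fr) * (1 - fc) * image[r0, c0] +
        (1 - fr) * fc * image[r0, min(c0 + 1, M)] +
        fr * (1 - fc) * image[min(r0 + 1, N), c0] +
        fr * fc * image[min(r0 + 1, N), min(c0 + 1, M)]
      if (val - image[i, j] >= threshold) code <- code + 2^n
    }
    out[i - R, j - R] <- code
  }
  out
}

# brute-force AvN-LBP map: per-pixel offset enumeration and angle binning
oracle_avn_map <- function(image, p, R) {
  N <- nrow(image); M <- ncol(image)
  theta <- 360 / p
  out <- matrix(NA_real_, N - 2 * R, M - 2 * R)
  for (i in (R + 1):(N - R)) for (j in (R + 1):(M - R)) {
    sums <- numeric(p); cnts <- numeric(p)
    for (di in -R:R) for (dj in -R:R) {
      if (di == 0 && dj == 0) next
      ang <- (atan2(-di, dj) * 180 / pi + 360) %% 360
      s <- floor((ang + 1e-9) / theta) %% p
      sums[s + 1] <- sums[s + 1] + image[i + di, j + dj]
      cnts[s + 1] <- cnts[s + 1] + 1
    }
    means <- sums / cnts
    mu <- mean(means)
    code <- 0
    for (n in 0:(p - 1)) if (means[n + 1] - mu >= 0) code <- code + 2^n
    out[i - R, j - R] <- code
  }
  out
}

# straight-line re-implementation of the FAM training/prediction loop
oracle_fam <- function(x, labels, rho, alpha, beta, eps, epochs) {
  labels <- as.character(labels)
  cap <- function(r) min(r, 1 - 1e-9)
  rho_base <- cap(rho)
  W <- NULL; cl <- character(0); seen <- character(0)
  for (e in seq_len(epochs)) {
    for (i in seq_len(nrow(x))) {
      a <- x[i, ]; AI <- c(a, 1 - a); l <- labels[i]
      if (!(l %in% seen)) {
        W <- rbind(W, AI); cl <- c(cl, l); seen <- c(seen, l)
        next
      }
      rho_cur <- rho_base
      Tj <- numeric(nrow(W))
      for (j in seq_len(nrow(W))) {
        Tj[j] <- sum(pmin(AI, W[j, ])) / (alpha + sum(W[j, ]))
      }
      committed <- FALSE
      for (J in order(-Tj, seq_along(Tj))) {
        m <- sum(pmin(AI, W[J, ])) / sum(AI)
        if (m < rho_cur) next
        if (cl[J] == l) {
          W[J, ] <- beta * pmin(AI, W[J, ]) + (1 - beta) * W[J, ]
          committed <- TRUE
          break
        }
        rho_cur <- cap(m + eps)
      }
      if (!committed) {
        W <- rbind(W, AI); cl <- c(cl, l)
      }
    }
  }
  rownames(W) <- NULL
  list(W = W, labels = cl, alpha = alpha)
}

oracle_fam_predict <- function(model, x) {
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    AI <- c(x[i, ], 1 - x[i, ])
    best <- -Inf; bj <- 1
    for (j in seq_len(nrow(model$W))) {
      Tj <- sum(pmin(AI, model$W[j, ])) / (model$alpha + sum(model$W[j, ]))
      if (Tj > best) { best <- Tj; bj <- j }
    }
    out[i] <- model$labels[bj]
  }
  out
}

# overlapping Gaussian-cluster feature set: three classes in [0,1]^d whose
# clouds overlap enough to provoke category proliferation
overlap_clusters <- function(n_per_class = 20, d = 4, sd = 0.16, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0.3, d), rep(0.5, d), rep(0.7, d))
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(stats::rnorm(n_per_class * d, centers[k, ], sd), n_per_class, d, byrow = TRUE)
  }))
  x <- pmin(pmax(x, 0), 1)
  list(x = x, labels = rep(c("a", "b", "c"), each = n_per_class))
}

# small labeled texture set run through the descriptor, as feature tables
texture_features <- function(n_classes = 3, per_class = 8, snr_db = Inf,
                             seed = 1, variant = "avn", spec = nbhd_spec()) {
  imgs <- generate_textures(
    texture_spec(n_classes = n_classes, images_per_class = per_class,
                 snr_db = snr_db), seed = seed)
  compute_histograms(imgs, spec, variant)
}
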