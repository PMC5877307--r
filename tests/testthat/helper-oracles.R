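# Independent oracles. These deliberately avoid the package's code paths:
# the k-NN oracle sorts a full distance table, the MFCC oracle computes the
# spectrum with an explicit real DFT (cos/sin matrices) instead of fft(),
# and the break oracle scans epochs one by one.

oracle_knn <- function(query, X, labels, k) {
  d <- apply(X, 1, function(row) sqrt(sum((row - query)^2)))
  tab <- data.frame(idx = seq_along(d), dist = d, label = labels)
  tab <- tab[order(tab$dist, tab$idx), ]
  sel <- tab[seq_len(min(k, nrow(tab))), ]
  counts <- table(sel$label)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1L) return(winners)
  # vote tie: walk neighbours nearest-first until one of the tied labels
  for (lab in sel$label) if (lab %in% winners) return(lab)
}

oracle_mfcc <- function(x, rate, cfg) {
  # pre-emphasis, sample by sample
  y <- numeric(length(x))
  y[1] <- x[1]
  for (t in 2:length(x)) y[t] <- x[t] - cfg$preemphasis * x[t - 1]
  flen <- round(cfg$frame_ms * rate / 1000)
  hop <- round(cfg$hop_ms * rate / 1000)
  nf <- (length(y) - flen) %/% hop + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  nfft <- 2^ceiling(log2(flen))
  nb <- nfft %/% 2 + 1
  # explicit real DFT
  nn <- 0:(nfft - 1)
  kk <- 0:(nb - 1)
  Cm <- cos(2 * pi * outer(nn, kk) / nfft)
  Sm <- sin(2 * pi * outer(nn, kk) / nfft)
  frames <- matrix(0, nf, nfft)
  for (i in seq_len(nf)) {
    seg <- y[((i - 1) * hop + 1):((i - 1) * hop + flen)] * ham
    frames[i, seq_len(flen)] <- seg
  }
  power <- (frames %*% Cm)^2 + (frames %*% Sm)^2  # nf x nb
  # mel filterbank, filter by filter
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  fmax <- if (is.null(cfg$fmax_hz)) rate / 2 else cfg$fmax_hz
  pts <- imel(seq(mel(cfg$fmin_hz), mel(fmax),
                  length.out = cfg$n_mel_filters + 2))
  binf <- (kk) * rate / nfft
  E <- matrix(0, nf, cfg$n_mel_filters)
  for (m in seq_len(cfg$n_mel_filters)) {
    w <- numeric(nb)
    for (b in seq_len(nb)) {
      f <- binf[b]
      if (f > pts[m] && f < pts[m + 1])
        w[b] <- (f - pts[m]) / (pts[m + 1] - pts[m])
      else if (f >= pts[m + 1] && f < pts[m + 2])
        w[b] <- (pts[m + 2] - f) / (pts[m + 2] - pts[m + 1])
    }
    E[, m] <- power %*% w
  }
  logE <- log(pmax(E, cfg$log_floor))
  # orthonormal DCT-II, coefficient by coefficient
  N <- cfg$n_mel_filters
  out <- matrix(0, nf, cfg$n_coeffs)
  for (k in seq_len(cfg$n_coeffs)) {
    basis <- sqrt(2 / N) * cos(pi * k * ((0:(N - 1)) + 0.5) / N)
    out[, k] <- logE %*% basis
  }
  out
}

oracle_breaks <- function(motion, max_break, min_flank) {
  n <- length(motion)
  hits <- list()
  i <- 1
  while (i <= n) {
    if (motion[i] == "active") {
      j <- i
      while (j < n && motion[j + 1] == "active") j <- j + 1
      len <- j - i + 1
      before <- 0; k <- i - 1
      while (k >= 1 && motion[k] == "still") { before <- before + 1; k <- k - 1 }
      after <- 0; k <- j + 1
      while (k <= n && motion[k] == "still") { after <- after + 1; k <- k + 1 }
      if (len <= max_break && before >= min_flank && after >= min_flank)
        hits[[length(hits) + 1]] <- c(start = i, len = len)
      i <- j + 1
    } else i <- i + 1
  }
  hits
}

spectral_flatness <- function(x) {
  p <- Mod(stats::fft(x))^2
  p <- p[2:(length(x) %/% 2)]  # drop DC and fold
  exp(mean(log(p + 1e-300))) / mean(p)
}

band_power_fraction <- function(x, rate, band) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * rate / length(x)
  half <- f <= rate / 2
  inband <- half & f >= band[1] & f <= band[2]
  sum(p[inband]) / sum(p[half])
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
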