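# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# pure tone, length n seconds
tone <- function(freq, dur_s, fs, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(1 / fs, dur_s, by = 1 / fs) + phase)
}

# brute-force least-squares Gaussian fit on a fixed histogram by grid search
grid_gauss_fit <- function(xs, ys, mu_grid, sigma_grid) {
  best <- c(mu = NA, sigma = NA, sse = Inf)
  for (mu in mu_grid) for (sg in sigma_grid) {
    g <- exp(-(xs - mu)^2 / (2 * sg^2))
    A <- sum(ys * g) / sum(g^2)           # closed-form amplitude
    sse <- sum((ys - A * g)^2)
    if (sse < best["sse"]) best <- c(mu = mu, sigma = sg, sse = sse)
  }
  best
}

# textbook fuzzy c-means (Bezdek), fixed initial centers
reference_fcm <- function(x, centers, m = 2, iters = 200, tol = 1e-9) {
  x <- as.matrix(x)
  v <- as.matrix(centers)
  k <- nrow(v)
  for (it in seq_len(iters)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(v) +
      outer(rep(1, nrow(x)), rowSums(v^2))
    d2 <- pmax(d2, 1e-300)
    u <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
    vn <- t(u^m) %*% x / colSums(u^m)
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
  }
  list(u = u, centers = v, fpc = mean(rowSums(u^2)))
}

# Rayleigh test p-value for circular concentration
rayleigh_p <- function(theta) {
  n <- length(theta)
  R <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
  z <- n * R^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# raw periodogram total power (Parseval reference)
periodogram_power <- function(x, fs) {
  n <- length(x)
  sum(Mod(stats::fft(x))^2) / n^2 * n / fs * (fs / n)  # = mean(x^2)
}

# interval overlap of detected vs truth events
match_events <- function(detected, truth) {
  if (nrow(detected) == 0 || nrow(truth) == 0)
    return(list(recall = NA_real_, precision = NA_real_))
  recall <- mean(vapply(seq_len(nrow(truth)), function(i)
    any(detected$onset_s < truth$offset_s[i] &
          detected$offset_s > truth$onset_s[i]), logical(1)))
  precision <- mean(vapply(seq_len(nrow(detected)), function(i)
    any(truth$onset_s < detected$offset_s[i] &
          truth$offset_s > detected$onset_s[i]), logical(1)))
  list(recall = recall, precision = precision)
}

# small default synthetic configuration for quick tests
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 120, fs = 1000, regions = "cortex",
                   cooccur_prob = 0, seed = 1)
  do.call(synth_config, utils::modifyList(defaults, args))
}
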