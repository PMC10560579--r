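# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_arg("configuration error: field '%s' must be a single number in [%s, %s]",
             name, format(min), format(max))
  invisible(x)
}

# maximal runs of TRUE -> matrix with columns start, end (1-based, inclusive)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# analytic signal via FFT (Hilbert transform); x real vector
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# union of half-open intervals given as two-column matrix [onset, offset)
interval_union <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

# total length of intersection of two interval sets (each a 2-col matrix)
interval_overlap_time <- function(a, b) {
  a <- interval_union(a); b <- interval_union(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

interval_total_time <- function(a) {
  a <- interval_union(a)
  if (nrow(a) == 0) 0 else sum(a[, 2] - a[, 1])
}

events_to_intervals <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(matrix(numeric(0), ncol = 2))
  cbind(events$onset_s, events$offset_s)
}

# slice a signal vector by a [t0, t1) time interval (seconds from start)
slice_signal <- function(x, fs, t0, t1) {
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(length(x), ceiling(t1 * fs))
  if (i1 < i0) return(numeric(0))
  x[i0:i1]
}

# deterministic child seed derived from a base seed and a stream index;
# kept below 2^31 so it is a valid R integer
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

empty_events <- function() {
  data.frame(event_id = integer(0), region = character(0),
             onset_s = numeric(0), offset_s = numeric(0),
             duration_s = numeric(0), mean_rms_uv = numeric(0),
             max_rms_uv = numeric(0), neg_peak_uv = numeric(0),
             n_peaks = integer(0), rejection_reason = character(0))
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# trapezoidal integral of y over x restricted to [lo, hi] with linear
# interpolation at the band edges
band_integral <- function(x, y, lo, hi) {
  if (lo >= hi) stop_arg("band edges must satisfy lo < hi")
  xi <- sort(unique(c(x[x > lo & x < hi], lo, hi)))
  yi <- stats::approx(x, y, xout = xi, rule = 2)$y
  pracma::trapz(xi, yi)
}
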