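make_tone_fixture <- function(freq = 10, dur = 2, fs = 500, amp = 100) {
  set.seed(20)
  noise <- rnorm(30 * fs, 0, 1)
  x <- noise
  seg <- tone(freq, dur, fs, amp = amp)
  x[(10 * fs + 1):(10 * fs + length(seg))] <- x[(10 * fs + 1):(10 * fs + length(seg))] + seg
  ev <- data.frame(event_id = 1L, region = "cortex", onset_s = 10,
                   offset_s = 10 + dur, duration_s = dur)
  baseline <- baseline_psd(noise, fs, NULL)
  list(x = x, ev = ev, baseline = baseline, fs = fs)
}

test_that("features of a pure 10 Hz tone match closed forms", {
  fx <- make_tone_fixture()
  f <- compute_features(fx$ev, fx$x, fx$fs, spike_times = c(10.5, 11.2), fx$baseline)
  expect_equal(unname(f["duration"]), 2)
  expect_equal(unname(f["iti"]), 0.1, tolerance = 0.005)       # 10 Hz troughs
  expect_equal(unname(f["flatness"]), 1, tolerance = 0.05)     # stationary
  expect_equal(unname(f["negative_peak"]), -100, tolerance = 0.05)
  expect_equal(unname(f["max_rms"]), 100 / sqrt(2), tolerance = 0.05 * 71)
  expect_equal(unname(f["spike_rate"]), 1)                     # 2 spikes / 2 s
  # spectral fractions: nearly all normalized power in theta-alpha
  expect_gt(unname(f["rel_theta_alpha"]), 0.8)
  expect_lt(unname(f["rel_beta_low_gamma"]), 0.1)
  # slope on the 500 S/s grid: max |diff| of a 10 Hz, 100 uV tone
  expect_equal(unname(f["max_slope"]), 100 * 2 * sin(pi * 10 / 500),
               tolerance = 3)
  expect_false(attr(f, "iti_defaulted"))
})

test_that("events without two qualifying troughs default ITI to the duration", {
  fs <- 500
  set.seed(21)
  x <- rnorm(10 * fs, 0, 5)
  x[(2 * fs):(2 * fs + 250)] <- x[(2 * fs):(2 * fs + 250)] - 200 *
    exp(-((0:250 - 125) / 50)^2)     # one big trough, no oscillation
  ev <- data.frame(event_id = 1L, onset_s = 2, offset_s = 2.5)
  baseline <- baseline_psd(rnorm(10 * fs, 0, 5), fs, NULL)
  suppressWarnings(f <- compute_features(ev, x, fs, numeric(0), baseline))
  expect_true(attr(f, "iti_defaulted"))
  expect_equal(unname(f["iti"]), 0.5)
})

test_that("PCA embedding is deterministic and matches an eigen-decomposition oracle", {
  set.seed(22)
  X <- matrix(rnorm(200 * 9), 200)
  colnames(X) <- paste0("f", 1:9)
  emb <- normalize_and_embed(X)
  expect_equal(dim(emb$scores), c(200, 3))
  # oracle: eigenvectors of the correlation matrix
  ev <- eigen(cor(X))
  expect_equal(abs(emb$loadings[, 1]), abs(ev$vectors[, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(emb$explained_var, (ev$values / sum(ev$values))[1:3],
               tolerance = 1e-8)
  # sign convention: dominant loading positive, reruns identical
  expect_true(all(vapply(1:3, function(j)
    emb$loadings[which.max(abs(emb$loadings[, j])), j] > 0, logical(1))))
  expect_identical(emb$scores, normalize_and_embed(X)$scores)
  # duplicated rows embed identically
  emb2 <- normalize_and_embed(rbind(X, X))
  expect_equal(emb2$scores[1:200, ], emb2$scores[201:400, ], tolerance = 1e-10)
  # constant feature dropped with warning
  Xc <- cbind(X, const = 1)
  expect_warning(e3 <- normalize_and_embed(Xc), "constant")
  expect_equal(ncol(e3$loadings), 3)
  expect_equal(nrow(e3$loadings), 9)
  expect_error(normalize_and_embed(X[1:2, ]), "at least")
})

test_that("fuzzy c-means matches a reference implementation on separated clouds", {
  set.seed(23)
  X <- rbind(matrix(rnorm(160, 0, 1), ncol = 2),
             matrix(rnorm(160, 10, 1), ncol = 2))
  cl <- fuzzy_cmeans(X, 2, seed = 4)
  expect_gt(cl$fpc, 0.95)
  # near-center points are crisply assigned; cloud-edge points keep a small
  # residual membership in the far cluster under the m = 2 update
  expect_true(all(apply(cl$memberships, 1, max) > 0.9))
  expect_gt(mean(apply(cl$memberships, 1, max) > 0.99), 0.5)
  expect_equal(rowSums(cl$memberships), rep(1, 160), tolerance = 1e-9)
  # reference Bezdek loop started from the converged centers stays there and
  # reproduces memberships and FPC
  ref <- reference_fcm(X, cl$centers)
  expect_equal(ref$centers, cl$centers, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(ref$u, cl$memberships, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(cl$fpc, ref$fpc, tolerance = 1e-4)
  # a point equidistant from both centers gets memberships (0.5, 0.5)
  mid <- matrix(colMeans(cl$centers), 1)
  d2 <- rowSums((cl$centers - matrix(mid, 2, 2, byrow = TRUE))^2)
  u_mid <- unname((1 / d2) / sum(1 / d2))
  expect_equal(u_mid, c(0.5, 0.5), tolerance = 1e-6)
  # k = 1: trivial partition
  c1 <- fuzzy_cmeans(X, 1)
  expect_equal(c1$fpc, 1)
  expect_true(all(c1$memberships == 1))
  expect_error(fuzzy_cmeans(X[0, , drop = FALSE], 2), "empty")
})

test_that("FPC selects the generative number of clusters", {
  set.seed(24)
  two <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 8), ncol = 2))
  expect_equal(select_k_by_fpc(two, 2:5, seed = 1)$best_k, 2)
  three <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 9), ncol = 2),
                 matrix(c(rnorm(50, -9), rnorm(50, 9)), ncol = 2))
  expect_equal(select_k_by_fpc(three, 2:5, seed = 1)$best_k, 3)
  # single Gaussian cloud: decreasing FPC curve triggers the flat-curve warning
  one <- matrix(rnorm(300), ncol = 3)
  expect_warning(sel <- select_k_by_fpc(one, 2:5, seed = 1), "single cluster")
  expect_equal(sel$best_k, 2)
  expect_true(all(diff(sel$fpc) < 0))
  expect_error(select_k_by_fpc(one, 1:3), "trivial")
})

test_that("label assignment applies the strict 0.6 rule and the spectral identity", {
  feats <- cbind(rel_beta_low_gamma = c(0.05, 0.06, 0.3, 0.31),
                 duration = c(1, 1, 4, 4))
  mk <- function(u1) structure(list(memberships = cbind(u1, 1 - u1),
                                    n_clusters = 2L), class = "fuzzy_clustering")
  # cluster 2 has higher beta-low gamma -> NGB
  cl <- mk(c(0.9, 0.8, 0.1, 0.2))
  lab <- assign_labels(cl, feats)
  expect_equal(lab$ngb_cluster, 2)
  expect_equal(lab$labels, c("SB", "SB", "NGB", "NGB"))
  # membership 0.61 classified, 0.60 and 0.55 are UC (strict "exceed")
  cl2 <- mk(c(0.61, 0.60, 0.55, 0.39))
  expect_equal(assign_labels(cl2, feats)$labels, c("SB", "UC", "UC", "NGB"))
  # tie on both criteria is refused
  ftie <- cbind(rel_beta_low_gamma = rep(0.2, 4), duration = rep(2, 4))
  expect_error(assign_labels(cl, ftie), "unresolved")
  expect_error(assign_labels(structure(list(memberships = matrix(1, 4, 1),
                                            n_clusters = 1L),
                                       class = "fuzzy_clustering"), feats),
               "2 clusters")
})
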