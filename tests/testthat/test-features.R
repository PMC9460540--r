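fs <- 250
t5 <- seq(0, 5, by = 1 / fs)[-1]

test_that("statistical features match their moment definitions", {
  expect_equal(statistical_features(rep(3.2, 100))[1, ],
               tibble::tibble(var = 0, skew = 0, kurt = 0, md = 3.2,
                              degenerate = TRUE))
  expect_equal(statistical_features(c(-1, 0, 1))$skew, 0)
  x <- withr::with_seed(1, rnorm(20000))
  sf <- statistical_features(x)
  expect_equal(sf$kurt, 3, tolerance = 0.1)   # non-excess convention
  expect_equal(sf$skew, 0, tolerance = 0.1)
  expect_equal(sf$var, stats::var(x))
  expect_equal(sf$md, stats::median(x))
  expect_false(sf$degenerate)
})

test_that("morphological features read peaks and extremes", {
  expect_equal(morphological_features(c(0, 1, 0, -1, 0)),
               tibble::tibble(am = 0.4, mp = 1, max = 1, min = -1))
  const <- morphological_features(rep(2.5, 10))
  expect_equal(const$am, 2.5)
  expect_equal(const$max, 2.5)
  expect_equal(const$min, 2.5)
  # monotone segment: no interior maximum, mp falls back to the global max
  expect_equal(morphological_features(1:10)$mp, 10)
  # all local maxima of a sampled sinusoid sit at the amplitude
  a <- 2 * sin(2 * pi * 8 * t5)
  expect_equal(morphological_features(a)$mp, 2, tolerance = 0.02)
})

test_that("band powers obey the sinusoid and flat-spectrum oracles", {
  x <- sin(2 * pi * 10 * t5)
  bp <- spectral_features(x, fs)
  expect_equal(bp$bpa, 0.5, tolerance = 0.05)     # A^2/2 for unit amplitude
  expect_lt(bp$bpd + bp$bpt + bp$bpb, 0.02)
  expect_equal(spectral_features(numeric(1250), fs),
               tibble::tibble(bpd = 0, bpt = 0, bpa = 0, bpb = 0, bpg = 0))
  # white noise: band power proportional to the number of PSD bins in band
  bands <- band_definitions()
  nbins <- vapply(seq_len(nrow(bands)), function(i)
    sum(0:125 >= bands$lo[i] & 0:125 <= bands$hi[i]), numeric(1))
  reps <- withr::with_seed(7, replicate(100, {
    b <- spectral_features(rnorm(1250), fs)
    unlist(b)
  }))
  ratio <- rowMeans(reps) / nbins
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 0.1)
  expect_error(spectral_features(x, fs, band_definitions(gamma_hi = 130)),
               "Nyquist")
})

test_that("band powers sum to at most the total signal power", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, as.numeric(stats::filter(rnorm(1250), 0.7,
                                                         "recursive")))
    bp <- spectral_features(x, fs)
    expect_lt(sum(unlist(bp)), mean(x^2) * 1.05)
  }
})

test_that("phase metrics obey their synchrony oracles", {
  x <- sin(2 * pi * 10 * t5)
  y <- sin(2 * pi * 10 * t5 + pi / 2)
  expect_equal(connectivity_weight(x, x, fs, "plv"), 1, tolerance = 1e-6)
  expect_equal(connectivity_weight(x, x, fs, "pli"), 0)  # zero lag discounted
  expect_equal(connectivity_weight(x, y, fs, "pli"), 1, tolerance = 1e-6)
  expect_equal(connectivity_weight(x, x, fs, "coh"), 1, tolerance = 1e-9)
  expect_equal(connectivity_weight(x, x, fs, "crosscorr"), 1, tolerance = 1e-9)
  expect_error(connectivity_weight(x, y[-1], fs, "plv"), "equal length")
})

test_that("PLV dominates PLI pairwise on narrow-band signals", {
  for (seed in 1:5) {
    xy <- withr::with_seed(seed, {
      shared <- sin(2 * pi * 10 * t5 + cumsum(rnorm(length(t5), sd = 0.02)))
      list(x = shared + 0.3 * rnorm(length(t5)),
           y = sin(2 * pi * 10 * t5 + 0.3) + 0.3 * rnorm(length(t5)))
    })
    plv <- connectivity_weight(xy$x, xy$y, fs, "plv")
    pli <- connectivity_weight(xy$x, xy$y, fs, "pli")
    expect_gte(plv + 1e-12, pli)
  }
})

test_that("cross-correlation maximum matches stats::ccf", {
  for (seed in 1:3) {
    xy <- withr::with_seed(seed, list(x = rnorm(500), y = rnorm(500)))
    ours <- connectivity_weight(xy$x, xy$y, fs = 100, "crosscorr",
                                max_lag_s = 1)
    ref <- max(abs(stats::ccf(xy$x, xy$y, lag.max = 100, plot = FALSE)$acf))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("adjacency matrices are symmetric, zero-diagonal and bounded", {
  segs <- withr::with_seed(3, lapply(1:3, function(i) rnorm(1250)))
  names(segs) <- c("0-1", "1-2", "2-3")
  for (m in c("crosscorr", "coh", "plv", "pli")) {
    adj <- connectivity_adjacency(segs, fs, m)
    expect_equal(adj, t(adj))
    expect_equal(diag(adj), c("0-1" = 0, "1-2" = 0, "2-3" = 0))
    expect_true(all(adj >= 0 & adj <= 1))
    # node strength of a 3-node graph with weights in [0,1] lies in [0,2]
    expect_true(all(node_strength(adj) >= 0 & node_strength(adj) <= 2))
  }
})

test_that("node strength sums incident edge weights", {
  ones <- matrix(1, 3, 3) - diag(3)
  expect_equal(unname(node_strength(ones)), c(2, 2, 2))
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 0.3
  adj[1, 3] <- adj[3, 1] <- 0.5
  expect_equal(node_strength(adj), c(0.8, 0.3, 0.5))
  expect_equal(unname(node_strength(matrix(0, 3, 3))), c(0, 0, 0))
})

test_that("extracted rows carry 17 finite features with expected counts", {
  f <- small_features()
  expect_equal(nrow(f), 6L * 12L)  # 6 windows x 12 channels
  feats <- as.matrix(f[, feature_names()])
  expect_equal(ncol(feats), 17L)
  expect_true(all(is.finite(feats)))
  expect_false(any(f$degenerate))
})

test_that("extraction is invariant to channel order and matches the per-metric path", {
  s <- small_session()
  segs <- segment_session(s)
  shuffled <- withr::with_seed(4, segs[sample(nrow(segs)), ])
  f1 <- extract_features(segs, s$fs)
  f2 <- extract_features(shuffled, s$fs)
  expect_equal(f1, f2)
  # fast path agrees with connectivity_adjacency metric by metric
  g <- dplyr::filter(segs, hemisphere == "Right", pass == "Pass2", window == 1)
  seglist <- g$samples
  names(seglist) <- g$pair
  row <- dplyr::filter(f1, hemisphere == "Right", pass == "Pass2",
                       window == 1)
  for (m in c("crosscorr", "coh", "plv", "pli")) {
    ns <- node_strength(connectivity_adjacency(seglist, s$fs, m))
    expect_equal(row[[m]], unname(ns[row$pair]), tolerance = 1e-12)
  }
})

test_that("incomplete channel groups are excluded with a warning", {
  s <- small_session()
  segs <- segment_session(s)
  crippled <- segs[!(segs$pair == "0-1" & segs$window == 1 &
                       segs$hemisphere == "Left"), ]
  expect_warning(f <- extract_features(crippled, s$fs), "incomplete")
  expect_equal(nrow(f), nrow(small_features()) - 3L)
})

test_that("amplitude scaling propagates with the right powers", {
  s <- small_session()
  segs <- segment_session(s)
  g <- dplyr::filter(segs, hemisphere == "Left", pass == "Pass1",
                     window <= 2)
  scaled <- g
  scaled$samples <- lapply(scaled$samples, function(x) 3 * x)
  f <- extract_features(g, s$fs)
  fs3 <- extract_features(scaled, s$fs)
  expect_equal(fs3$var, 9 * f$var)
  expect_equal(fs3$bpg, 9 * f$bpg, tolerance = 1e-9)
  expect_equal(fs3$am, 3 * f$am)
  expect_equal(fs3$mp, 3 * f$mp)
  expect_equal(fs3$max, 3 * f$max)
  for (m in c("crosscorr", "coh", "plv", "pli")) {
    expect_equal(fs3[[m]], f[[m]], tolerance = 1e-9)
  }
})
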