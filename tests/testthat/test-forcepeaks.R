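test_that("Gaussian body fit recovers mean and sd within 2%", {
  set.seed(42)
  x <- rnorm(1e5, 120, 30)
  fit <- fitForceDistribution(x)
  expect_lt(abs(fit@mean / 120 - 1), 0.02)
  expect_lt(abs(fit@sd / 30 - 1), 0.02)
  expect_lt(max(abs(fit@deviation)), 4)
  ## no real tail: threshold flagged unreliable
  th <- selectForceThreshold(fit)
  expect_false(th$reliable)
})

test_that("an injected high-force tail produces a deviation maximum there", {
  set.seed(43)
  x <- c(rnorm(95000, 120, 30), runif(5000, 250, 400))
  fit <- fitForceDistribution(x)
  sel <- fit@mids > 250
  expect_gt(max(fit@deviation[sel]), 5)
  th <- selectForceThreshold(fit)
  expect_true(th$reliable)
  expect_gt(th$threshold, 250 - fit@binWidth)
})

test_that("threshold lands at the onset of a decaying tail", {
  ## a tail that decays from its onset (as rupture tails do) puts the
  ## deviation maximum at the onset
  set.seed(44)
  x <- c(rnorm(95000, 120, 30), 250 + rexp(5000, 1 / 30))
  th <- selectForceThreshold(fitForceDistribution(x))
  expect_lt(abs(th$threshold - 250), 2 * 5)
})

test_that("degenerate force samples are a fit error", {
  expect_error(fitForceDistribution(rep(100, 2000)), "degenerate")
  expect_error(fitForceDistribution(rnorm(100)), "at least 1000")
})

test_that("threshold selection is stable under sample-size rescaling", {
  draw <- function(n, seed) {
    set.seed(seed)
    c(rnorm(round(0.95 * n), 120, 30), 250 + rexp(round(0.05 * n), 1 / 30))
  }
  t1 <- selectForceThreshold(fitForceDistribution(draw(2e4, 7)))$threshold
  t2 <- selectForceThreshold(fitForceDistribution(draw(2e5, 8)))$threshold
  expect_lte(abs(t1 - t2), 5)   # within one bin
})

test_that("a monotone ramp yields no peaks (boundary rule)", {
  tr <- ForceTrace(1:100, cbind(0, 0, seq(0, 300, length.out = 100)),
                   cbind(0, 0, 1:100))
  ps <- detectPeaks(tr, threshold = 50)
  expect_equal(nrow(peaks(ps)), 0L)
})

test_that("every returned peak satisfies the threshold and prominence", {
  sim <- simulatePull(SimParams(noiseSd = 15), seed = 21)
  ps <- detectPeaks(sim$trace, threshold = 90)
  pk <- peaks(ps)
  expect_true(all(pk$force >= 90))
  expect_true(all(pk$prominence >= 30))
  expect_true(all(pk$extension <= max(extensions(sim$trace))))
})

test_that("sawtooth ruptures are located at the rupture frames", {
  nOK <- 0L; nTot <- 0L
  for (s in 1:20) {
    sim <- simulatePull(SimParams(noiseSd = 15), seed = 400 + s)
    ev <- events(sim$truth)
    thr <- 70
    tTrue <- sort(unique(ev$time[ev$force >= thr + 20]))
    pk <- peaks(detectPeaks(sim$trace, threshold = thr))
    for (t0 in tTrue) {
      nTot <- nTot + 1L
      ## the apex sits on a noisy, gently sloped ramp: at sigma = 15 pN its
      ## localisation is good to a few tens of ps, far below the ~1000 ps
      ## event spacing
      if (any(abs(pk$time - t0) <= 80)) nOK <- nOK + 1L
    }
  }
  expect_gt(nOK / nTot, 0.95)
})

test_that("pure noise produces essentially no false peaks at mean + 5 sd", {
  set.seed(500)
  n <- vapply(1:200, function(i) {
    nrow(peaks(detectPeaks(noiseTrace(), threshold = 200)))
  }, numeric(1))
  expect_lte(mean(n), 0.1)
})

test_that("peak density integrates to 1 and resolves two clusters", {
  set.seed(9)
  pk1 <- data.frame(run = "a", time = 1:40,
                    extension = rnorm(40, 150, 10),
                    force = rnorm(40, 120, 8), prominence = 50)
  pk2 <- data.frame(run = "a", time = 41:80,
                    extension = rnorm(40, 500, 10),
                    force = rnorm(40, 320, 8), prominence = 50)
  ps <- new("PeakSet", peaks = rbind(pk1, pk2), threshold = 0)
  kd <- peakDensity(ps, bandwidth = c(20, 20))
  dx <- diff(kd$extension[1:2]); dy <- diff(kd$force[1:2])
  expect_equal(sum(kd$density) * dx * dy, 1, tolerance = 1e-3)
  ## modes near the cluster centroids (within one bandwidth)
  top <- which(kd$density == max(kd$density), arr.ind = TRUE)[1, ]
  modes <- order(kd$density, decreasing = TRUE)
  m1 <- arrayInd(modes[1], dim(kd$density))
  ## locate local maxima: take density restricted to each half-plane
  lowHalf <- kd$extension < 325
  i1 <- which.max(apply(kd$density[lowHalf, ], 1, max))
  j1 <- which.max(kd$density[lowHalf, ][i1, ])
  expect_lt(abs(kd$extension[lowHalf][i1] - 150), 20)
  expect_lt(abs(kd$force[j1] - 120), 20)
  i2 <- which.max(apply(kd$density[!lowHalf, ], 1, max))
  j2 <- which.max(kd$density[!lowHalf, ][i2, ])
  expect_lt(abs(kd$extension[!lowHalf][i2] - 500), 20)
  expect_lt(abs(kd$force[j2] - 320), 20)
  ## single peak: bump centred on it
  one <- new("PeakSet", peaks = pk1[1, ], threshold = 0)
  kd1 <- peakDensity(one)
  w <- which(kd1$density == max(kd1$density), arr.ind = TRUE)
  expect_lt(abs(kd1$extension[w[1]] - pk1$extension[1]), 5)
  expect_error(peakDensity(one, bandwidth = c(-1, 20)), "bandwidth")
})
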