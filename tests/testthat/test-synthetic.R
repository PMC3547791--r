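test_that("identical seeds give bit-identical runs, different seeds differ", {
  a <- simulatePull(quickParams(), seed = 7)
  b <- simulatePull(quickParams(), seed = 7)
  expect_identical(forceVectors(a$trace), forceVectors(b$trace))
  expect_identical(events(a$truth), events(b$truth))
  c <- simulatePull(quickParams(), seed = 8)
  expect_false(identical(events(a$truth)$time, events(c$truth)$time))
})

test_that("no-event limit is the pure WLC loading curve of the linker", {
  p <- SimParams(nRepeats = 1, k0 = 1e-30, noiseSd = 0,
                 linkerContour = 200, pullDistance = 170)
  sim <- simulatePull(p, seed = 1)
  expect_equal(nrow(events(sim$truth)), 0L)
  x <- extensions(sim$trace)
  f <- forceMagnitudes(sim$trace)
  ## stored force equals the WLC force of the stored extension
  expect_lt(max(abs(wlcForce(x, 200) - f)), 1e-6)
  ## and equals the spring force k (X - x)
  X <- 0.05 * frameTimes(sim$trace)
  expect_lt(max(abs(20 * (X - x) - f)), 1e-6)
})

test_that("force-independent rupture times are exponential with rate 2 k0", {
  ## one repeat = two Bell halves, each at rate k0 when bellDx = 0, so the
  ## first rupture is exponential with rate 2 k0
  k0 <- 0.02
  p <- SimParams(nRepeats = 1, k0 = k0, bellDx = 0, pullDistance = 40,
                 frameInterval = 4, noiseSd = 0, halfCoupling = 0)
  set.seed(901)
  tt <- replicate(2000, {
    ev <- events(simulatePull(p)$truth)
    if (nrow(ev)) ev$time[1L] else NA_real_
  })
  tt <- tt[!is.na(tt)]
  se <- (1 / (2 * k0)) / sqrt(length(tt))
  expect_lt(abs(mean(tt) - 1 / (2 * k0)), 3 * se + 0.05)  # + discretisation
})

test_that("ligand stabilisation raises rupture forces of repeats 1-5", {
  meanForce <- function(bound, seeds) {
    f <- unlist(lapply(seeds, function(s) {
      ev <- events(simulatePull(SimParams(bound = bound), seed = s)$truth)
      ev$force[ev$repeatId <= 5]
    }))
    mean(f)
  }
  fB <- meanForce(TRUE, 1:25)
  fF <- meanForce(FALSE, 1:25)
  expect_gt(fB, fF)
  expect_gt(fB - fF, 30)      # a 4 kBT shift is far larger than noise
})

test_that("ligand binding restricts the first two unfoldings to r7 then r6", {
  hits <- vapply(1:40, function(s) {
    rk <- unfoldingOrder(simulatePull(SimParams(bound = TRUE),
                                      seed = 1000 + s)$truth)
    rk[7] == 1L && rk[6] == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("released contour accounting is exact", {
  sim <- simulatePull(SimParams(), seed = 12)
  ev <- events(sim$truth)
  expect_equal(nrow(ev), 14L)
  expect_equal(ev$cumContour, 30 + seq_len(14) * 56.8, tolerance = 1e-12)
  ## final extension equals the Marko-Siggia inversion of the final force
  n <- nFrames(sim$trace)
  x <- extensions(sim$trace)[n]
  Lc <- ev$cumContour[14]
  fEnd <- wlcForce(x, Lc)
  ## noise-free force from the spring: k (X - x)
  X <- 0.05 * max(frameTimes(sim$trace))
  expect_equal(fEnd, 20 * (X - x), tolerance = 1e-5)
})

test_that("native template has adjacent-only inter-repeat contacts and a
           correctly placed ligand", {
  tpl <- makeNativeTemplate(7, 32, ligandRepeats = 1:6)
  nc <- nativeContacts(tpl$coords, tpl$topology, tpl$repeatMap)
  inter <- nc[nc$repeatI != nc$repeatJ, ]
  expect_true(nrow(inter) > 0)
  expect_true(all(inter$repeatJ - inter$repeatI == 1L))
  ## ligand proximity: every repeat 1-6 has atoms within 5 A, repeat 7 none
  res <- tpl$topology@residues
  atoms <- tpl$topology@atoms
  rep7 <- integer(0)
  ligIdx <- which(res$chain[match(atoms$resid, res$resid)] == "ligand")
  lig <- tpl$coords[ligIdx, , drop = FALSE]
  for (r in 1:7) {
    sel <- which(res$repeatId[match(atoms$resid, res$resid)] %in% r)
    dmin <- min(apply(tpl$coords[sel, , drop = FALSE], 1, function(a)
      min(sqrt(colSums((t(lig) - a)^2)))))
    if (r <= 6) expect_lt(dmin, 5) else expect_gt(dmin, 5)
  }
  ## deterministic construction
  tpl2 <- makeNativeTemplate(7, 32, ligandRepeats = 1:6)
  expect_identical(tpl$coords, tpl2$coords)
})

test_that("jitter-free frames equal the native template before rupture", {
  sim <- simulatePull(quickParams(), seed = 3)
  tpl <- makeNativeTemplate(3, 16)
  traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 50,
                               jitter = 0)
  t1 <- min(events(sim$truth)$time)
  pre <- which(frameTimes(traj) < t1 - 20)
  for (f in utils::head(pre, 3))
    expect_equal(coords(traj, f), unname(tpl$coords), tolerance = 1e-12)
})

test_that("ruptured repeats cross 10 A RMSD inside their unfolding window", {
  sim <- simulatePull(quickParams(), seed = 4)
  tpl <- makeNativeTemplate(3, 32)
  traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 20,
                               jitter = 0)
  rs <- repeatRMSD(traj, tpl$repeatMap, tpl$coords)
  mids <- unfoldingMidpoints(rs)
  tTruth <- repeatUnfoldingTimes(sim$truth)
  for (r in which(!is.na(tTruth)))
    expect_lt(abs(mids$midpoint[r] - tTruth[r]), 40 + 20)
  ## fully unfolded repeats reach RMSD > 20 A
  done <- which(!is.na(tTruth))
  expect_true(all(apply(rs$rmsd[, done, drop = FALSE], 2, max) > 20))
})

test_that("unfolding order recovered from synthesized RMSD matches truth", {
  tpl <- makeNativeTemplate(7, 32)
  ok <- vapply(1:20, function(s) {
    sim <- simulatePull(SimParams(), seed = 100 + s)
    traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 40,
                                 jitter = 0, seed = s)
    ev <- unfoldingMidpoints(repeatRMSD(traj, tpl$repeatMap, tpl$coords))
    identical(ev$rank, unfoldingOrder(sim$truth))
  }, logical(1))
  expect_true(all(ok))
})

test_that("rupture times outside the trace span are a consistency error", {
  sim <- simulatePull(quickParams(), seed = 3)
  tpl <- makeNativeTemplate(3, 16)
  bad <- sim$truth
  bad@events$time[1] <- bad@duration + 1000
  bad@events <- bad@events[order(bad@events$time), ]
  expect_error(synthesizeTrajectory(bad, tpl), "outside")
})

test_that("invalid simulator parameters are rejected", {
  expect_error(SimParams(springK = -1), "positive")
  expect_error(SimParams(halfCoupling = 2), "halfCoupling")
  expect_error(SimParams(bound = TRUE, nRepeats = 7,
                         ddG = c(0, 0, 0, 0, 0, 0, 3)),
               "repeats 1..6", fixed = TRUE)
})
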