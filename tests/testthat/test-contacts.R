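## small hand-built topology: one chain of Ca-only residues plus an
## optional ligand bead, for boundary-case tests
.lineTopology <- function(n, ligand = FALSE) {
  resid <- seq_len(n + ligand)
  chain <- c(rep("protein", n), if (ligand) "ligand")
  res <- data.frame(resid = resid,
                    resname = c(rep("ALA", n), if (ligand) "LIG"),
                    repeatId = c(rep(1L, n), if (ligand) NA_integer_),
                    chain = chain,
                    region = c(rep("helix", n), if (ligand) NA))
  atoms <- data.frame(resid = resid, name = "CA", element = "C")
  new("Topology", residues = res, atoms = atoms)
}

test_that("a straight chain at 3.8 A spacing has no native contacts", {
  topo <- .lineTopology(12)
  coords <- cbind(3.8 * (0:11), 0, 0)
  rmap <- RepeatMap(1, 12)
  nc <- nativeContacts(coords, topo, rmap)
  expect_equal(nrow(nc), 0L)
})

test_that("the 8 A cutoff is strict and sequence separation is > 3", {
  topo <- .lineTopology(6)
  rmap <- RepeatMap(1, 6)
  base <- cbind(100 * (0:5), 0, 0)     # far apart by default
  ## residues 1 and 6 (separation 5) at 7.9 A: contact
  c1 <- base; c1[6, ] <- c(7.9, 0, 0)
  expect_equal(nrow(nativeContacts(c1, topo, rmap)), 1L)
  ## at exactly 8.0 or 8.1 A: none (strict <)
  c2 <- base; c2[6, ] <- c(8.0, 0, 0)
  expect_equal(nrow(nativeContacts(c2, topo, rmap)), 0L)
  ## residues 1 and 4 (separation 3): excluded even at 5 A
  c3 <- base; c3[4, ] <- c(5, 0, 0)
  expect_equal(nrow(nativeContacts(c3, topo, rmap)), 0L)
})

test_that("native contacts are invariant under rigid motion", {
  tpl <- makeNativeTemplate(3, 16)
  nc <- nativeContacts(tpl$coords, tpl$topology, tpl$repeatMap)
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- t(R %*% t(tpl$coords)) + 7
  nc2 <- nativeContacts(moved, tpl$topology, tpl$repeatMap)
  expect_equal(nc[, c("i", "j")], nc2[, c("i", "j")])
})

test_that("presence starts native and vanishes when fully extended", {
  sim <- simulatePull(quickParams(), seed = 9)
  tpl <- makeNativeTemplate(3, 32)
  traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 50,
                               jitter = 0)
  nc <- nativeContacts(tpl$coords, tpl$topology, tpl$repeatMap)
  pres <- contactPresence(traj, nc)
  expect_true(all(pres[1L, ]))
  expect_false(any(pres[nrow(pres), ]))
  ## per-repeat presence decays monotonically on monotone unfolding
  for (r in 1:3) {
    sel <- nc$repeatI == r & nc$repeatJ == r
    counts <- rowSums(pres[, sel, drop = FALSE])
    expect_true(all(diff(counts) <= 2))   # allow morph-window wiggle
  }
})

test_that("recurrence boundary cases: exact 0.4 ns inclusive, flicker out", {
  tt <- seq(0, 2000, by = 4)
  n <- length(tt)
  ## present exactly from 100 to 500 ps: spans exactly 400 ps, inclusive
  p1 <- tt >= 100 & tt <= 500
  ## alternating frames: never recurrent
  p2 <- (seq_len(n) %% 2) == 0
  ## present for 396 ps only: below the window
  p3 <- tt >= 100 & tt <= 496
  rec <- recurrentContacts(cbind(p1, p2, p3), tt, minRun = 400)
  expect_equal(rec$recurrent, c(TRUE, FALSE, FALSE))
  expect_equal(rec$lastConsistent[1], 500)
})

test_that("lifetimes follow scripted schedules and average with SE", {
  tt <- seq(0, 30000, by = 100)
  mk <- function(tEnd) tt <= tEnd
  ## two runs with lifetimes 10 ns and 20 ns
  contacts <- data.frame(i = 1, j = 10, repeatI = 1, repeatJ = 1,
                         class = "other")
  lt <- contactLifetimes(list(matrix(mk(10000)), matrix(mk(20000))),
                         list(tt, tt), contacts)
  expect_equal(lt$meanLifetime, 15000)
  expect_equal(lt$seLifetime, 5000)
  ## full-length presence: lifetime = final frame time
  ltf <- contactLifetimes(list(matrix(rep(TRUE, length(tt)))), list(tt),
                          contacts)
  expect_equal(ltf$meanLifetime, 30000)
  ## a 0.6 ns transient is detected with its exact end time
  p <- tt >= 5000 & tt <= 5600
  rec <- recurrentContacts(matrix(p), tt, minRun = 400)
  expect_true(rec$recurrent[1])
  expect_equal(rec$lastConsistent[1], 5600)
})

test_that("intra-repeat contact lifetimes track the rupture order", {
  tpl <- makeNativeTemplate(7, 32)
  nc <- nativeContacts(tpl$coords, tpl$topology, tpl$repeatMap)
  intra <- which(nc$repeatI == nc$repeatJ)
  rhos <- vapply(1:5, function(s) {
    sim <- simulatePull(SimParams(), seed = 30 + s)
    traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 80,
                                 jitter = 0.3, seed = s)
    pres <- contactPresence(traj, nc)
    lt <- contactLifetimes(list(pres), list(frameTimes(traj)), nc)
    perRepeat <- tapply(lt$meanLifetime[intra], nc$repeatI[intra], mean)
    cor(perRepeat, repeatUnfoldingTimes(sim$truth), method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.9))
})

test_that("binding detection applies strict 5 A and 80% rules", {
  topo <- .lineTopology(2, ligand = TRUE)
  nF <- 100L
  coordsArr <- array(0, dim = c(3, 3, nF))
  coordsArr[2, 1, ] <- 50                    # residue 2 far away
  ## ligand bead within 5 A of residue 1 in 79 of 100 equilibration frames
  coordsArr[3, 1, ] <- c(rep(4.9, 79), rep(30, 21))
  traj <- new("PullingTrajectory", topology = topo,
              times = seq(0, by = 4, length.out = nF),
              coords = coordsArr)
  ba <- bindingAnalysis(traj, equilSpan = c(0, 396), minRun = 40)
  expect_false(ba$nativeBinder[1])           # 79% fails the strict > 80%
  ## 81 frames in contact passes
  coordsArr[3, 1, ] <- c(rep(4.9, 81), rep(30, 19))
  traj2 <- new("PullingTrajectory", topology = topo,
               times = seq(0, by = 4, length.out = nF),
               coords = coordsArr)
  ba2 <- bindingAnalysis(traj2, equilSpan = c(0, 396), minRun = 40)
  expect_true(ba2$nativeBinder[1])
  ## exactly 5.0 A never counts (strict <)
  coordsArr[3, 1, ] <- 5.0
  traj3 <- new("PullingTrajectory", topology = topo,
               times = seq(0, by = 4, length.out = nF),
               coords = coordsArr)
  expect_error(bindingAnalysis(traj3, equilSpan = c(0, 396),
                               minRun = 40), NA)
  ba3 <- bindingAnalysis(traj3, equilSpan = c(0, 396), minRun = 40)
  expect_false(ba3$nativeBinder[1])
  ## a topology without ligand atoms is a config error
  topoNoLig <- .lineTopology(2)
  trajNL <- new("PullingTrajectory", topology = topoNoLig,
                times = c(0, 4),
                coords = array(0, dim = c(2, 3, 2)))
  expect_error(bindingAnalysis(trajNL), "ligand")
})

test_that("binding loss follows the repeat unfolding sequence", {
  tpl <- makeNativeTemplate(7, 32, ligandRepeats = 1:6)
  rhos <- vapply(1:5, function(s) {
    sim <- simulatePull(SimParams(bound = TRUE), seed = 50 + s)
    traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 80,
                                 jitter = 0.3, seed = s)
    ba <- bindingAnalysis(traj)
    sel <- ba$nativeBinder
    perRepeat <- tapply(ba$meanLifetime[sel], ba$repeatId[sel], mean)
    cor(perRepeat,
        repeatUnfoldingTimes(sim$truth)[as.integer(names(perRepeat))],
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.9))
})
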