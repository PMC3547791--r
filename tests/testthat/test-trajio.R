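test_that("force-trace TSV round trip preserves every numeric field", {
  sim <- simulatePull(quickParams(), seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeForceTrace(sim$trace, f)
  tr2 <- readForceTrace(f)
  scale <- max(abs(forceVectors(sim$trace)))
  expect_lt(max(abs(forceVectors(tr2) - forceVectors(sim$trace))) / scale,
            1e-9)
  expect_lt(max(abs(anchorPositions(tr2) - anchorPositions(sim$trace))) /
              max(anchorPositions(sim$trace)), 1e-9)
  expect_equal(frameTimes(tr2), frameTimes(sim$trace))
  p <- runParams(tr2)
  expect_equal(p$speed, 0.05)
  expect_equal(p$springK, 20)
  expect_false(p$bound)
})

test_that("force-trace reader rejects non-monotonic time", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_ps\tfx_pN\tfy_pN\tfz_pN\tex_A\tey_A\tez_A",
               "0\t0\t0\t1\t0\t0\t0",
               "2\t0\t0\t1\t0\t0\t1",
               "1\t0\t0\t1\t0\t0\t2"), f)
  expect_error(readForceTrace(f), "data error")
})

test_that("two-row table reads as a length-2 trace", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# spring_k_pN_A=20",
               "time_ps\tfx_pN\tfy_pN\tfz_pN\tex_A\tey_A\tez_A",
               "0\t0\t0\t1\t0\t0\t0",
               "1\t0\t0\t2\t0\t0\t1"), f)
  tr <- readForceTrace(f)
  expect_equal(nFrames(tr), 2L)
  expect_equal(runParams(tr)$springK, 20)
})

test_that("multi-model PDB round trip preserves coordinates", {
  tpl <- makeNativeTemplate(3, 16, ligandRepeats = 1:2)
  sim <- simulatePull(quickParams(), seed = 1)
  traj <- synthesizeTrajectory(sim$truth, tpl, frameInterval = 400,
                               jitter = 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePullingTrajectory(traj, f)
  tj2 <- readPullingTrajectory(f, tpl$repeatMap,
                               frameTimes = frameTimes(traj))
  ## PDB stores 3 decimals
  expect_lt(max(abs(coords(tj2) - coords(traj))), 1e-3)
  expect_equal(nFrames(tj2), nFrames(traj))
  expect_equal(nRepeats(topology(tj2)), 3L)
})

test_that("uniform frame spacing is applied when no times are given", {
  tpl <- makeNativeTemplate(2, 8)
  traj <- new("PullingTrajectory", topology = tpl$topology,
              times = c(0, 1, 2),
              coords = array(rep(tpl$coords, 3),
                             dim = c(nrow(tpl$coords), 3, 3)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePullingTrajectory(traj, f)
  tj2 <- readPullingTrajectory(f, spacing = 4)
  expect_equal(frameTimes(tj2), c(0, 4, 8))
})

test_that("a model with a missing atom is a format error naming the model", {
  tpl <- makeNativeTemplate(2, 8)
  traj <- new("PullingTrajectory", topology = tpl$topology,
              times = c(0, 4, 8),
              coords = array(rep(tpl$coords, 3),
                             dim = c(nrow(tpl$coords), 3, 3)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePullingTrajectory(traj, f)
  lines <- readLines(f)
  atomLines <- grep("^ATOM", lines)
  model2 <- grep("^MODEL", lines)[2L]
  drop <- atomLines[atomLines > model2][1L]
  writeLines(lines[-drop], f)
  expect_error(readPullingTrajectory(f), "model 2")
})

test_that("repeat ranges outside the residue span are a config error", {
  tpl <- makeNativeTemplate(2, 8)
  traj <- new("PullingTrajectory", topology = tpl$topology,
              times = 0, coords = array(tpl$coords,
                                        dim = c(nrow(tpl$coords), 3, 1)))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePullingTrajectory(traj, f)
  badMap <- RepeatMap(first = c(1, 9), last = c(8, 40))
  expect_error(readPullingTrajectory(f, badMap), "config error")
})

test_that("repeat-map JSON round trips", {
  rm1 <- RepeatMap(first = c(1, 34), last = c(33, 66))
  f <- withr::local_tempfile(fileext = ".json")
  writeRepeatMap(rm1, f)
  rm2 <- readRepeatMap(f)
  expect_equal(repeatRanges(rm2), repeatRanges(rm1))
  expect_equal(rm2@anchorAtoms, rm1@anchorAtoms)
})

test_that("result tables are deterministic, empty tables keep the header", {
  df <- data.frame(run = c("a", "b"), force = c(123.456789, 0.000123456))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeResultsTable(df, f1)
  writeResultsTable(df, f2)
  expect_identical(readLines(f1), readLines(f2))
  fe <- withr::local_tempfile()
  writeResultsTable(df[0, ], fe)
  expect_identical(readLines(fe), "run\tforce")
})

test_that("order table uses the repeat-by-position layout", {
  ev <- do.call(rbind, lapply(1:28, function(k)
    data.frame(run = paste0("r", k), repeatId = 1:7,
               midpoint = c(7:1) * 100, rank = c(7:1), unfolded = TRUE)))
  tab <- orderContingency(ev)
  expect_equal(unname(tab["r7", ]), c(28, 0, 0, 0, 0, 0, 0))
  f <- withr::local_tempfile()
  writeOrderTable(tab, f)
  lines <- readLines(f)
  expect_equal(lines[1L], "repeat\t1st\t2nd\t3rd\t4th\t5th\t6th\t7th")
  expect_equal(lines[8L], "r7\t28\t0\t0\t0\t0\t0\t0")
})

test_that("trace validity enforces anchor/end-to-end consistency", {
  anc <- array(0, dim = c(2, 2, 3))
  anc[, 2, 3] <- c(1, 2)
  expect_silent(ForceTrace(c(0, 1), cbind(0, 0, c(1, 1)),
                           cbind(0, 0, c(1, 2)), anc))
  expect_error(ForceTrace(c(0, 1), cbind(0, 0, c(1, 1)),
                          cbind(0, 0, c(1, 2.5)), anc),
               "anchor")
})
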