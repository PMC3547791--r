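## Synthetic constant-velocity pulling: Bell kinetics at half-repeat
## granularity on top of Marko-Siggia worm-like chain elasticity.  Stands in
## for cluster-scale steered MD so that every analysis stage has seeded
## ground truth.

#' Simulate a constant-velocity pulling run
#'
#' The spring end moves at constant velocity, `X(t) = X0 + v t`; at every
#' frame the chain extension `x` solves the force balance
#' `k (X - x - Rfold) = F_WLC(x; Lc)` between the harmonic spring and the
#' Marko-Siggia restoring force of the currently unfolded contour, with
#' folded repeats contributing a rigid rise.  Each folded half-repeat is a
#' Bell element that ruptures stochastically at rate
#' `k0 exp(F dx / kBT - dG_r)`, where `dG_r` collects the repeat's intrinsic
#' stability (a gradient increasing toward the N-terminus) and, when the
#' ligand is bound, its per-repeat stabilisation `ddG_r`.  Only the
#' outermost folded repeats (the edges of the folded block) are competent to
#' unfold, reflecting that tension is relayed into the stack from the pulled
#' termini; this yields the sequential, mostly C-to-N unfolding
#' characteristic of ankyrin arrays.  Upon rupture the unfolded contour
#' grows by `L` and the force relaxes through the re-solved balance; with
#' probability `halfCoupling` the partner half of the same repeat ruptures
#' at the same instant (whole-repeat, 2L step).
#'
#' Kinetics are fixed-step Bernoulli trials at `kineticsStep` (default
#' 0.1 ps), sampled by inversion of the exact discrete survival function, so
#' runs with the same seed are bit-identical.  Gaussian noise (`noiseSd`) is
#' added to the reported force only; the dynamics are noise-free, so the
#' ground truth records exact rupture forces.
#'
#' @param params A [SimParams-class] object.
#' @param seed Integer seed; every stochastic element of the run derives
#'   from it.
#' @param runId Character run identifier stored in the outputs.
#' @return A list with elements `trace` (a [ForceTrace-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- simulatePull(SimParams(nRepeats = 2, pullDistance = 300), seed = 1)
#' sim$truth
#' @export
simulatePull <- function(params, seed = NULL, runId = "run1") {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)

  nR <- params@nRepeats
  L <- params@contourPerHalf
  rise <- params@foldedRise
  kT <- kBT(params@temperature)
  k <- params@springK
  v <- params@speed
  dtK <- params@kineticsStep
  dx <- params@bellDx
  q <- params@halfCoupling
  stab <- params@stabilityGradient * (nR - seq_len(nR)) +
    if (params@ligand) params@ddG else 0

  tEnd <- params@pullDistance / v
  frameT <- seq(0, tEnd, by = params@frameInterval)
  nF <- length(frameT)

  ## state ------------------------------------------------------------------
  foldedHalves <- rep(2L, nR)
  linkShare <- numeric(nR)
  linkShare[1L] <- linkShare[nR] <- params@linkerContour / 2
  if (nR == 1L) linkShare[1L] <- params@linkerContour
  u <- linkShare                        # unfolded contour per repeat
  Lc <- sum(u)
  Rf <- rise * nR
  X0 <- Rf                              # zero force at t = 0

  xFrame <- numeric(nF)
  fFrame <- numeric(nF)
  uMat <- matrix(0, nF, nR)
  hMat <- matrix(0L, nF, nR)
  committed <- rep(FALSE, nF)
  eventList <- list()
  tCur <- 0

  solveSeg <- function(tt) {
    xx <- .solveExtensionCpp(X0 + v * tt, Lc, Rf, k, kT,
                             params@persistence)
    ff <- k * (X0 + v * tt - xx - Rf)
    ff[ff < 0] <- 0
    list(x = xx, f = ff)
  }

  repeat {
    segIdx <- which(!committed & frameT >= tCur - 1e-9)
    gridT <- frameT[segIdx]
    lead <- length(gridT) == 0L || gridT[1L] > tCur + 1e-9
    if (lead) gridT <- c(tCur, gridT)
    sol <- solveSeg(gridT)
    if (any(!is.finite(sol$x)))
      stop("force balance failed to bracket a root near frame ",
           if (length(segIdx)) segIdx[1] else NA, call. = FALSE)

    foldedIdx <- which(foldedHalves > 0L)
    if (!length(foldedIdx)) {              # nothing left to unfold
      take <- match(frameT[segIdx], gridT)
      xFrame[segIdx] <- sol$x[take]
      fFrame[segIdx] <- sol$f[take]
      if (length(segIdx)) {
        uMat[segIdx, ] <- matrix(u, length(segIdx), nR, byrow = TRUE)
        hMat[segIdx, ] <- matrix(foldedHalves, length(segIdx), nR,
                                 byrow = TRUE)
      }
      committed[segIdx] <- TRUE
      break
    }

    edges <- unique(c(foldedIdx[1L], foldedIdx[length(foldedIdx)]))
    thresholds <- stats::rexp(length(edges))      # one per competent repeat
    cumHaz <- numeric(length(edges))
    fired <- NA_integer_; tE <- NA_real_; fE <- NA_real_

    ## walk the kinetics grid in chunks until an element fires
    chunkSize <- 40000L
    tcStart <- tCur
    while (is.na(fired) && tcStart < tEnd - 1e-9) {
      tcEnd <- min(tEnd, tcStart + chunkSize * dtK)
      subT <- seq(tcStart, tcEnd, by = dtK)
      if (length(subT) < 2L) break
      Fi <- stats::approx(gridT, sol$f, xout = subT, rule = 2)$y
      ## hazard over (t, t+dt]: use force at the step start
      stepF <- Fi[-length(Fi)]
      for (ei in seq_along(edges)) {
        r <- edges[ei]
        rate <- foldedHalves[r] * params@k0 *
          exp(stepF * dx / kT - stab[r])
        haz <- cumHaz[ei] + cumsum(rate * dtK)
        hit <- which(haz >= thresholds[ei])
        if (length(hit)) {
          tHit <- subT[hit[1L] + 1L]
          if (is.na(tE) || tHit < tE) {
            fired <- r; tE <- tHit
            fE <- Fi[hit[1L] + 1L]
          }
        }
        cumHaz[ei] <- haz[length(haz)]
      }
      tcStart <- tcEnd
    }

    ## commit frames strictly before the event (or all, if none fired)
    cutT <- if (is.na(fired)) Inf else tE
    commitFrames <- segIdx[frameT[segIdx] < cutT - 1e-9]
    take <- match(frameT[commitFrames], gridT)
    xFrame[commitFrames] <- sol$x[take]
    fFrame[commitFrames] <- sol$f[take]
    if (length(commitFrames)) {
      uMat[commitFrames, ] <- matrix(u, length(commitFrames), nR,
                                     byrow = TRUE)
      hMat[commitFrames, ] <- matrix(foldedHalves, length(commitFrames), nR,
                                     byrow = TRUE)
    }
    committed[commitFrames] <- TRUE
    if (is.na(fired)) break

    ## apply the rupture (and, with probability q, its partner half)
    applyRupture <- function(r) {
      half <- 3L - foldedHalves[r]
      foldedHalves[r] <<- foldedHalves[r] - 1L
      u[r] <<- u[r] + L
      Lc <<- Lc + L
      Rf <<- Rf - rise / 2
      eventList[[length(eventList) + 1L]] <<- data.frame(
        repeatId = r, half = half, time = tE, force = fE, cumContour = Lc)
    }
    applyRupture(fired)
    if (foldedHalves[fired] == 1L && stats::runif(1) < q)
      applyRupture(fired)
    tCur <- tE
  }

  ## assemble trace ----------------------------------------------------------
  RfFrame <- rise * rowSums(hMat) / 2
  d <- xFrame + RfFrame
  uTot <- rowSums(uMat)
  denom <- ifelse(uTot > 0, uTot, 1)
  eMat <- rise * hMat / 2 + xFrame * uMat / denom      # per-repeat extension
  cs <- apply(eMat, 1L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)   # single-repeat case
  anchorsZ <- cbind(0, t(cs))
  anchors <- array(0, dim = c(nF, nR + 1L, 3L))
  anchors[, , 3L] <- anchorsZ

  fNoisy <- fFrame + if (params@noiseSd > 0)
    stats::rnorm(nF, 0, params@noiseSd) else 0
  force <- cbind(0, 0, fNoisy)
  endToEnd <- cbind(0, 0, d)

  trace <- ForceTrace(frameT, force, endToEnd, anchors,
                      params = list(speed = v, springK = k,
                                    seed = seed, bound = params@ligand,
                                    frameInterval = params@frameInterval,
                                    temperature = params@temperature,
                                    noiseSd = params@noiseSd,
                                    nRepeats = nR, runId = runId))

  ## ground truth ------------------------------------------------------------
  ev <- if (length(eventList)) do.call(rbind, eventList) else
    data.frame(repeatId = integer(0), half = integer(0), time = numeric(0),
               force = numeric(0), cumContour = numeric(0))
  repTimes <- vapply(seq_len(nR), function(r) {
    tt <- ev$time[ev$repeatId == r]
    if (length(tt)) min(tt) else NA_real_
  }, numeric(1))
  ranks <- rep(NA_integer_, nR)
  unf <- which(!is.na(repTimes))
  ranks[unf] <- rank(repTimes[unf], ties.method = "first")

  dBar <- diff(d)
  fBar <- (fFrame[-1L] + fFrame[-nF]) / 2
  wTot <- sum(fBar * dBar)
  wRep <- vapply(seq_len(nR), function(r)
    sum(fBar * diff(eMat[, r])), numeric(1))

  truth <- new("GroundTruth", events = ev, repeatTimes = repTimes,
               orderRanks = ranks, workTotal = wTot, workPerRepeat = wRep,
               duration = tEnd)
  list(trace = trace, truth = truth)
}

#' Deterministic toy native structure of a repeat array
#'
#' Builds a compact repeat-array template for RMSD and contact analyses:
#' each repeat is a block of two antiparallel pseudo-helix strands of
#' Ca/Cb sites (the first quarter of each repeat tagged as the turn region),
#' stacked along the pulling axis with a fixed rise chosen so that native
#' contacts exist within repeats and between adjacent repeats only.
#' Optionally a chain of ligand beads is placed within 5 A of the first
#' strand of designated repeats, mimicking an elongated interface that spans
#' part of the array.
#'
#' @param nRepeats Number of repeats.
#' @param residuesPerRepeat Residues per repeat (even; default 32, two
#'   halves of 16).
#' @param ligandRepeats Integer vector of repeats contacted by the ligand
#'   (e.g. `1:6`), or `integer(0)` for no ligand.
#' @return A list with `topology` ([Topology-class]), `coords` (nAtoms x 3
#'   native coordinates, A), `repeatMap` ([RepeatMap-class]) and
#'   `ligandRepeats`.
#' @export
makeNativeTemplate <- function(nRepeats = 7L, residuesPerRepeat = 32L,
                               ligandRepeats = integer(0)) {
  nR <- as.integer(nRepeats)
  rpr <- as.integer(residuesPerRepeat)
  if (nR < 1L) stop("nRepeats must be >= 1", call. = FALSE)
  if (rpr < 8L || rpr %% 2L != 0L)
    stop("residuesPerRepeat must be an even number >= 8", call. = FALSE)
  if (length(ligandRepeats) && !all(ligandRepeats %in% seq_len(nR)))
    stop("ligandRepeats outside 1..nRepeats", call. = FALSE)

  blockRise <- 7        # A between adjacent repeat blocks (< 8 A cutoff)
  spacing <- 1.6        # A between consecutive residues within a strand
  h <- rpr %/% 2L

  resRows <- list(); atomRows <- list(); xyz <- list()
  for (r in seq_len(nR)) {
    z0 <- (r - 1L) * blockRise
    for (i in seq_len(rpr)) {
      resid <- (r - 1L) * rpr + i
      inA <- i <= h
      idx <- if (inA) i else rpr - i + 1L   # strand B runs antiparallel
      ca <- c((idx - 1L) * spacing,
              if (inA) 0 else 4.8,
              z0 + 0.8 * ((i - 1L) %% 2L))
      cb <- ca + c(0, if (inA) -1.5 else 1.5, 0.5)
      region <- if (i <= max(2L, round(rpr / 4))) "turn" else "helix"
      resRows[[resid]] <- data.frame(
        resid = resid, resname = "ALA", repeatId = r,
        chain = "protein", region = region)
      atomRows[[length(atomRows) + 1L]] <- data.frame(
        resid = resid, name = "CA", element = "C")
      atomRows[[length(atomRows) + 1L]] <- data.frame(
        resid = resid, name = "CB", element = "C")
      xyz[[length(xyz) + 1L]] <- ca
      xyz[[length(xyz) + 1L]] <- cb
    }
  }

  nProt <- nR * rpr
  lig <- sort(unique(as.integer(ligandRepeats)))
  bead <- 0L
  for (r in lig) {
    z0 <- (r - 1L) * blockRise
    for (bx in c(0.25, 0.5, 0.75) * (h - 1L) * spacing) {
      bead <- bead + 1L
      resid <- nProt + bead
      resRows[[resid]] <- data.frame(
        resid = resid, resname = "LIG", repeatId = NA_integer_,
        chain = "ligand", region = NA_character_)
      atomRows[[length(atomRows) + 1L]] <- data.frame(
        resid = resid, name = "CA", element = "C")
      xyz[[length(xyz) + 1L]] <- c(bx, -3.5, z0 + 0.4)
    }
  }

  topo <- new("Topology",
              residues = do.call(rbind, c(resRows,
                                          list(make.row.names = FALSE))),
              atoms = do.call(rbind, c(atomRows,
                                       list(make.row.names = FALSE))))
  coords <- do.call(rbind, xyz)
  rmap <- RepeatMap(first = (seq_len(nR) - 1L) * rpr + 1L,
                    last = seq_len(nR) * rpr)
  list(topology = topo, coords = coords, repeatMap = rmap,
       ligandRepeats = lig)
}

#' Synthesize a coordinate trajectory from simulated ground truth
#'
#' Converts the rupture schedule of a [GroundTruth-class] into a coordinate
#' trajectory on the toy template: each half-repeat morphs linearly from its
#' native block geometry to a straight extended segment over a window
#' centred on its rupture time, repeats downstream shift along the pulling
#' axis to accommodate the released contour, unaffected repeats keep their
#' native geometry plus Gaussian jitter, and ligand beads track a bound
#' repeat's interface until that repeat ruptures, then drift away.
#'
#' @param truth A [GroundTruth-class] from [simulatePull()].
#' @param template Output of [makeNativeTemplate()]; its repeat count must
#'   match the ground truth.
#' @param frameInterval Frame spacing in ps (default 20).
#' @param window Width of the unfolding morph window in ps (default 40).
#' @param jitter Gaussian positional jitter sd in A (default 0.3; 0 gives
#'   frames identical to the native template before the first rupture).
#' @param seed Seed for the jitter.
#' @return A [PullingTrajectory-class].
#' @export
synthesizeTrajectory <- function(truth, template, frameInterval = 20,
                                 window = 40, jitter = 0.3, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  if (!is.null(seed)) set.seed(seed)
  topo <- template$topology
  res <- topo@residues
  nR <- nRepeats(topo)
  ev <- truth@events
  if (nrow(ev) && (any(ev$repeatId > nR)))
    stop("ground truth repeat count exceeds template", call. = FALSE)
  if (nrow(ev) && any(ev$time > truth@duration + 1e-9))
    stop("rupture times outside the trace span", call. = FALSE)

  rpr <- sum(res$chain == "protein") / nR
  h <- rpr / 2
  L <- 56.8
  extSpacing <- L / h                      # A per residue when extended
  tFrames <- seq(0, truth@duration, by = frameInterval)
  nF <- length(tFrames)
  atoms <- topo@atoms
  nA <- nrow(atoms)
  native <- template$coords
  blockRise <- 7

  ## rupture time per (repeat, half); NA when never ruptured
  halfTime <- matrix(NA_real_, nR, 2L)
  for (ii in seq_len(nrow(ev)))
    halfTime[ev$repeatId[ii], ev$half[ii]] <- ev$time[ii]

  ## atom bookkeeping per repeat/half
  atomRes <- atoms$resid
  resRepeat <- res$repeatId[match(atomRes, res$resid)]
  resInRep <- atomRes - (resRepeat - 1L) * rpr
  atomHalf <- ifelse(resInRep <= h, 1L, 2L)
  isLig <- res$chain[match(atomRes, res$resid)] == "ligand"
  ligRepeatOfBead <- rep(NA_integer_, nA)
  if (any(isLig)) {
    beads <- which(isLig)
    ligRepeatOfBead[beads] <- rep(template$ligandRepeats,
                                  each = length(beads) /
                                    length(template$ligandRepeats))
  }

  coordsArr <- array(0, dim = c(nA, 3L, nF))
  clamp01 <- function(z) { z[z < 0] <- 0; z[z > 1] <- 1; z }

  for (fi in seq_len(nF)) {
    t <- tFrames[fi]
    alpha <- clamp01((t - (halfTime - window / 2)) / window)
    alpha[is.na(alpha)] <- 0
    frame <- native
    cumExtra <- 0
    for (r in seq_len(nR)) {
      sel <- which(!isLig & resRepeat == r)
      aHalf <- alpha[r, atomHalf[sel]]
      zBase <- (r - 1L) * blockRise + cumExtra
      ## extended segment along z, pulled laterally out of the stack so a
      ## half-unfolded repeat already reads ~18-20 A RMSD; a small helical
      ## dressing keeps the segment from being exactly collinear (which
      ## would make the superposition degenerate)
      extZ <- zBase + (resInRep[sel] - 1L) * extSpacing
      phase <- 2 * pi * resInRep[sel] / 3.6
      extPos <- cbind(-10 + 0.5 * cos(phase), -10 + 0.5 * sin(phase),
                      extZ)
      natPos <- native[sel, , drop = FALSE]
      natPos[, 3L] <- natPos[, 3L] + cumExtra
      frame[sel, ] <- (1 - aHalf) * natPos + aHalf * extPos
      ## ligand beads attached to this repeat
      bsel <- which(ligRepeatOfBead == r)
      if (length(bsel)) {
        bp <- native[bsel, , drop = FALSE]
        bp[, 3L] <- bp[, 3L] + cumExtra
        tdet <- halfTime[r, 1L]
        if (!is.na(tdet) && t > tdet)
          bp[, 2L] <- bp[, 2L] - min((t - tdet) * 0.5, 40)
        frame[bsel, ] <- bp
      }
      cumExtra <- cumExtra + sum(alpha[r, ] * (L - blockRise / 2))
    }
    if (jitter > 0)
      frame <- frame + matrix(stats::rnorm(nA * 3L, 0, jitter), nA, 3L)
    coordsArr[, , fi] <- frame
  }

  new("PullingTrajectory", topology = topo, times = tFrames,
      coords = coordsArr)
}
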