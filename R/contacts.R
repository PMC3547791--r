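## Native-contact and ligand-binding analysis: contact detection, recurrence
## filtering, lifetimes, and per-residue binding records.

.caCoords <- function(topo, coordMat, resids) {
  atoms <- topo@atoms
  idx <- vapply(resids, function(rr) {
    i <- which(atoms$resid == rr & atoms$name == "CA")
    if (!length(i)) stop("missing Ca for residue ", rr, call. = FALSE)
    i[1L]
  }, integer(1))
  coordMat[idx, , drop = FALSE]
}

#' Native contacts from a reference structure
#'
#' A residue pair forms a native contact when the Ca-Ca distance is
#' strictly below `cutoff` (default 8 A) in the native structure and the
#' residues are more than `minSeqSep` (default 3) apart in sequence.
#' Contacts are classified from the repeat map and the topology's region
#' annotation into intra/inter-repeat turn and helix classes.
#'
#' @param native nAtoms x 3 native coordinates.
#' @param topo A [Topology-class].
#' @param repeatMap A [RepeatMap-class].
#' @param cutoff Distance cutoff in A (strict `<`).
#' @param minSeqSep Minimum sequence separation (strict `>`).
#' @return data.frame with columns `i`, `j` (residue indices, `i < j`),
#'   `repeatI`, `repeatJ`, `class`.
#' @export
nativeContacts <- function(native, topo, repeatMap, cutoff = 8,
                           minSeqSep = 3L) {
  res <- topo@residues
  prot <- res$resid[res$chain == "protein"]
  ca <- .caCoords(topo, native, prot)
  d <- as.matrix(stats::dist(ca))
  n <- length(prot)
  pair <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(pair)) {
    sep <- abs(prot[pair[, 2L]] - prot[pair[, 1L]])
    pair <- pair[sep > minSeqSep, , drop = FALSE]
  }
  if (!nrow(pair))
    return(data.frame(i = integer(0), j = integer(0),
                      repeatI = integer(0), repeatJ = integer(0),
                      class = character(0)))
  i <- prot[pair[, 1L]]; j <- prot[pair[, 2L]]
  repOf <- res$repeatId[match(prot, res$resid)]
  regOf <- res$region[match(prot, res$resid)]
  ri <- repOf[pair[, 1L]]; rj <- repOf[pair[, 2L]]
  gi <- regOf[pair[, 1L]]; gj <- regOf[pair[, 2L]]
  cls <- ifelse(gi == "helix" & gj == "helix",
                ifelse(ri == rj, "intra-repeat helix", "inter-repeat helix"),
         ifelse(gi == "turn" & gj == "turn",
                ifelse(ri == rj, "intra-repeat turn", "inter-repeat turn"),
                "other"))
  cls[is.na(cls)] <- "other"
  data.frame(i = i, j = j, repeatI = ri, repeatJ = rj, class = cls)
}

#' Per-frame presence of contacts along a trajectory
#'
#' A contact is present at a frame when the Ca-Ca distance is strictly
#' below the cutoff at that frame.
#'
#' @param traj A [PullingTrajectory-class].
#' @param contacts data.frame with columns `i`, `j` (as [nativeContacts()]).
#' @param cutoff Distance cutoff in A.
#' @return Logical matrix nFrames x nContacts.
#' @export
contactPresence <- function(traj, contacts, cutoff = 8) {
  topo <- topology(traj)
  atoms <- topo@atoms
  caIdx <- function(rr) which(atoms$resid == rr & atoms$name == "CA")[1L]
  ii <- vapply(contacts$i, caIdx, integer(1))
  jj <- vapply(contacts$j, caIdx, integer(1))
  nF <- nFrames(traj)
  pres <- matrix(FALSE, nF, nrow(contacts))
  for (f in seq_len(nF)) {
    cc <- traj@coords[, , f]
    dv <- cc[ii, , drop = FALSE] - cc[jj, , drop = FALSE]
    pres[f, ] <- sqrt(rowSums(dv^2)) < cutoff
  }
  pres
}

#' Recurrence filter for contact presence series
#'
#' A contact is recurrent when some maximal run of consecutive
#' present-frames spans at least `minRun` ps (span measured from the first
#' to the last frame of the run, boundary inclusive).  The last-consistent
#' time of a recurrent contact is the end time of its last qualifying run.
#' Contacts present only in isolated or alternating frames are filtered
#' out as transient flickers.
#'
#' @param presence Logical matrix nFrames x nContacts
#'   (from [contactPresence()]).
#' @param time Frame times in ps.
#' @param minRun Minimum consistent span in ps (default 400, i.e. 0.4 ns).
#' @return A list with `recurrent` (logical per contact) and
#'   `lastConsistent` (ps; `NA` for never-recurrent contacts).
#' @export
recurrentContacts <- function(presence, time, minRun = 400) {
  if (length(time) != nrow(presence))
    stop("frame times do not match the presence matrix", call. = FALSE)
  nC <- ncol(presence)
  recurrent <- logical(nC)
  lastT <- rep(NA_real_, nC)
  for (cix in seq_len(nC)) {
    p <- presence[, cix]
    if (!any(p)) next
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      span <- time[ends[k]] - time[starts[k]]
      if (span >= minRun - 1e-9) {
        recurrent[cix] <- TRUE
        lastT[cix] <- time[ends[k]]
      }
    }
  }
  list(recurrent = recurrent, lastConsistent = lastT)
}

#' Contact lifetimes across runs
#'
#' The lifetime of a contact in one run is the end time of the last
#' consistent (recurrence-filtered) stretch in which it was observed;
#' contacts never observed consistently get lifetime 0.  Lifetimes are
#' averaged across runs with their standard error.
#'
#' @param presenceList List of logical presence matrices, one per run
#'   (same contacts in the same order).
#' @param timeList List of frame-time vectors matching `presenceList`.
#' @param contacts Contact data.frame ([nativeContacts()]).
#' @param minRun Recurrence span in ps (default 400).
#' @return `contacts` with added columns `meanLifetime`, `seLifetime`,
#'   `everRecurrent`, plus a `lifetimes` attribute (runs x contacts
#'   matrix, ps).
#' @export
contactLifetimes <- function(presenceList, timeList, contacts,
                             minRun = 400) {
  nRun <- length(presenceList)
  if (nRun < 1L) stop("need at least one run", call. = FALSE)
  lt <- matrix(0, nRun, nrow(contacts))
  for (k in seq_len(nRun)) {
    rec <- recurrentContacts(presenceList[[k]], timeList[[k]], minRun)
    lt[k, ] <- ifelse(rec$recurrent, rec$lastConsistent, 0)
  }
  contacts$meanLifetime <- colMeans(lt)
  contacts$seLifetime <- apply(lt, 2L, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  contacts$everRecurrent <- colSums(lt > 0) > 0
  attr(contacts, "lifetimes") <- lt
  contacts
}

#' Ligand-binding residues and binding lifetimes
#'
#' A protein residue is involved in binding at a frame when at least one of
#' its atoms is strictly within `cutoff` (default 5 A) of any ligand atom.
#' Native binders are the residues involved in binding in more than
#' `nativeFrac` (default 0.8, strict) of the equilibration span.  Binding
#' lifetimes per run are the last consistent binding time, by default
#' passed through the same recurrence filter as contacts (disable with
#' `recurrenceFilter = FALSE` to use the raw last observation).
#'
#' @param trajList A [PullingTrajectory-class] or list of them (runs).
#' @param equilSpan Length-2 numeric, time range (ps) of the equilibration
#'   stretch used to define native binders.
#' @param cutoff Atom-atom distance cutoff in A (strict `<`).
#' @param nativeFrac Fraction of equilibration frames required for a native
#'   binder (strict `>`).
#' @param minRun Recurrence span in ps.
#' @param recurrenceFilter Apply the recurrence filter to lifetimes.
#' @return data.frame per protein residue: `resid`, `repeatId`,
#'   `nativeBinder`, `meanLifetime`, `seLifetime`; plus a `lifetimes`
#'   attribute (runs x residues, ps).
#' @export
bindingAnalysis <- function(trajList, equilSpan = c(0, 200), cutoff = 5,
                            nativeFrac = 0.8, minRun = 400,
                            recurrenceFilter = TRUE) {
  if (is(trajList, "PullingTrajectory")) trajList <- list(trajList)
  topo <- topology(trajList[[1L]])
  res <- topo@residues
  atoms <- topo@atoms
  ligAtomIdx <- which(res$chain[match(atoms$resid, res$resid)] == "ligand")
  if (!length(ligAtomIdx))
    stop("no ligand atoms in the topology", call. = FALSE)
  protRes <- res$resid[res$chain == "protein"]
  protAtomIdx <- which(atoms$resid %in% protRes)
  resFac <- factor(atoms$resid[protAtomIdx], levels = protRes)

  bindingPerRun <- lapply(trajList, function(traj) {
    nF <- nFrames(traj)
    bound <- matrix(FALSE, nF, length(protRes))
    for (f in seq_len(nF)) {
      cc <- traj@coords[, , f]
      lig <- cc[ligAtomIdx, , drop = FALSE]
      pa <- cc[protAtomIdx, , drop = FALSE]
      d2min <- rep(Inf, nrow(pa))
      for (la in seq_len(nrow(lig))) {
        dv <- pa - matrix(lig[la, ], nrow(pa), 3L, byrow = TRUE)
        d2min <- pmin(d2min, rowSums(dv^2))
      }
      bound[f, ] <- tapply(d2min, resFac, min) < cutoff^2
    }
    bound
  })

  ## native binders from the equilibration span of the first run
  t1 <- frameTimes(trajList[[1L]])
  eq <- which(t1 >= equilSpan[1L] & t1 <= equilSpan[2L])
  if (!length(eq))
    stop("equilibration span contains no frames", call. = FALSE)
  frac <- colMeans(bindingPerRun[[1L]][eq, , drop = FALSE])
  nativeBinder <- frac > nativeFrac

  nRun <- length(trajList)
  lt <- matrix(0, nRun, length(protRes))
  for (k in seq_len(nRun)) {
    tt <- frameTimes(trajList[[k]])
    if (recurrenceFilter) {
      rec <- recurrentContacts(bindingPerRun[[k]], tt, minRun)
      lt[k, ] <- ifelse(rec$recurrent, rec$lastConsistent, 0)
    } else {
      lt[k, ] <- apply(bindingPerRun[[k]], 2L, function(p)
        if (any(p)) tt[max(which(p))] else 0)
    }
  }
  out <- data.frame(resid = protRes,
                    repeatId = res$repeatId[match(protRes, res$resid)],
                    nativeBinder = nativeBinder,
                    bindingFraction = frac,
                    meanLifetime = colMeans(lt),
                    seLifetime = apply(lt, 2L, function(v)
                      if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                      else 0))
  attr(out, "lifetimes") <- lt
  out
}
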