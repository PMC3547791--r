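## Readers and writers: multi-model PDB trajectories, TSV force traces with
## comment-line metadata, JSON repeat maps, deterministic result tables.

#' Read a multi-model PDB pulling trajectory
#'
#' One frame per MODEL record.  Atom ordering must be consistent across
#' models; a model with a deviating atom count is reported as a format
#' error naming the model.  Frame times are taken from `frameTimes` when
#' given, otherwise uniform spacing (default 4 ps) starting at 0.  Ligand
#' residues are recognized by residue name `"LIG"`; when a
#' [RepeatMap-class] is supplied its ranges assign protein residues to
#' repeats and must lie within the residue span.
#'
#' @param path PDB file path.
#' @param repeatMap Optional [RepeatMap-class].
#' @param frameTimes Optional explicit frame times (ps).
#' @param spacing Uniform frame spacing in ps when `frameTimes` is absent.
#' @return A [PullingTrajectory-class].
#' @export
readPullingTrajectory <- function(path, repeatMap = NULL,
                                  frameTimes = NULL, spacing = 4) {
  lines <- readLines(path)
  modelStarts <- grep("^MODEL", lines)
  isAtom <- grepl("^(ATOM|HETATM)", lines)
  if (length(modelStarts) >= 1L) {
    modelEnds <- grep("^ENDMDL", lines)
    if (length(modelEnds) != length(modelStarts))
      stop("format error: unmatched MODEL/ENDMDL records", call. = FALSE)
    counts <- mapply(function(s, e) sum(isAtom[s:e]), modelStarts,
                     modelEnds)
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop("format error: model ", bad, " has ", counts[bad],
           " atoms, expected ", counts[1L], call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  nAtoms <- nrow(atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nF <- nrow(xyz)

  resTab <- unique(atom[, c("resno", "resid")])
  isLig <- resTab$resid == "LIG"
  repeatId <- rep(NA_integer_, nrow(resTab))
  if (!is.null(repeatMap)) {
    rr <- repeatRanges(repeatMap)
    protSpan <- range(resTab$resno[!isLig])
    if (min(rr$first) < protSpan[1L] || max(rr$last) > protSpan[2L])
      stop("config error: repeat range outside the residue span",
           call. = FALSE)
    for (k in seq_len(nrow(rr)))
      repeatId[!isLig & resTab$resno >= rr$first[k] &
                 resTab$resno <= rr$last[k]] <- rr$repeatId[k]
  }
  topo <- new("Topology",
              residues = data.frame(resid = resTab$resno,
                                    resname = resTab$resid,
                                    repeatId = repeatId,
                                    chain = ifelse(isLig, "ligand",
                                                   "protein"),
                                    region = NA_character_),
              atoms = data.frame(resid = atom$resno, name = atom$elety,
                                 element = substr(atom$elety, 1L, 1L)))
  coords <- array(0, dim = c(nAtoms, 3L, nF))
  for (f in seq_len(nF))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  tt <- if (!is.null(frameTimes)) frameTimes else (seq_len(nF) - 1L) * spacing
  new("PullingTrajectory", topology = topo, times = tt, coords = coords)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A [PullingTrajectory-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePullingTrajectory <- function(traj, path) {
  topo <- topology(traj)
  res <- topo@residues
  atoms <- topo@atoms
  m <- match(atoms$resid, res$resid)
  nF <- nFrames(traj)
  xyz <- matrix(0, nF, nrow(atoms) * 3L)
  for (f in seq_len(nF))
    xyz[f, ] <- as.vector(t(traj@coords[, , f]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = atoms$resid,
                   resid = res$resname[m],
                   elety = atoms$name,
                   chain = ifelse(res$chain[m] == "ligand", "B", "A"))
  invisible(path)
}

## force-trace TSV ------------------------------------------------------------

.traceMetaKeys <- c(speed = "speed_A_ps", springK = "spring_k_pN_A",
                    seed = "seed", bound = "bound",
                    frameInterval = "frame_interval_ps",
                    temperature = "temperature_K", noiseSd = "noise_sd_pN",
                    nRepeats = "n_repeats", runId = "run_id")

#' Write a force trace as TSV with metadata comments
#'
#' Leading `# key=value` comment lines carry the run metadata
#' (`# spring_k_pN_A=20`, `# speed_A_ps=0.01`, `# seed=...`), followed by a
#' tab-separated table: time, force vector, end-to-end vector, and one
#' column triple per anchor.  Values are written with 10 significant
#' digits, so a write-read round trip preserves every numeric field to
#' better than 1e-9 relative error.
#'
#' @param trace A [ForceTrace-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeForceTrace <- function(trace, path) {
  p <- runParams(trace)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(.traceMetaKeys)) {
    val <- p[[nm]]
    if (!is.null(val) && !is.na(val))
      writeLines(sprintf("# %s=%s", .traceMetaKeys[[nm]], format(val)),
                 con)
  }
  anc <- anchorPositions(trace)
  nAnch <- dim(anc)[2L]
  df <- data.frame(time_ps = trace@time,
                   fx_pN = trace@force[, 1L], fy_pN = trace@force[, 2L],
                   fz_pN = trace@force[, 3L],
                   ex_A = trace@endToEnd[, 1L], ey_A = trace@endToEnd[, 2L],
                   ez_A = trace@endToEnd[, 3L])
  for (k in seq_len(nAnch))
    for (ax in 1:3)
      df[[sprintf("a%d_%s_A", k, c("x", "y", "z")[ax])]] <- anc[, k, ax]
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- apply(vapply(df, function(col) sprintf("%.10g", col),
                       character(nrow(df))), 1L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a force trace written by [writeForceTrace()]
#'
#' @param path TSV path (tab- or comma-separated, declared column header,
#'   `# key=value` metadata comments).
#' @return A [ForceTrace-class].
#' @export
readForceTrace <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (any(diff(df$time_ps) <= 0))
    stop("data error: time column is not strictly increasing",
         call. = FALSE)
  nAnch <- sum(grepl("^a\\d+_x_A$", names(df)))
  anc <- array(0, dim = c(nrow(df), nAnch, 3L))
  for (k in seq_len(nAnch))
    for (ax in 1:3)
      anc[, k, ax] <- df[[sprintf("a%d_%s_A", k, c("x", "y", "z")[ax])]]
  params <- list()
  for (nm in names(.traceMetaKeys)) {
    raw <- meta[[.traceMetaKeys[[nm]]]]
    if (is.null(raw)) next
    params[[nm]] <- if (nm == "runId") raw
      else if (nm == "bound") as.logical(raw)
      else as.numeric(raw)
  }
  ForceTrace(df$time_ps,
             cbind(df$fx_pN, df$fy_pN, df$fz_pN),
             cbind(df$ex_A, df$ey_A, df$ez_A),
             anc, params)
}

## repeat-map JSON ------------------------------------------------------------

#' Read a repeat map from JSON
#'
#' Expected layout:
#' `{"repeats": [{"repeatId": 1, "first": 1, "last": 33}, ...],
#'   "anchorAtoms": {"nTerm": "N", "cTerm": "C", "boundary": "CA"}}`.
#'
#' @param path JSON path.
#' @return A [RepeatMap-class].
#' @export
readRepeatMap <- function(path) {
  js <- jsonlite::fromJSON(path)
  RepeatMap(first = js$repeats$first, last = js$repeats$last,
            repeatId = js$repeats$repeatId,
            anchorAtoms = as.list(js$anchorAtoms))
}

#' Write a repeat map to JSON
#'
#' @param repeatMap A [RepeatMap-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRepeatMap <- function(repeatMap, path) {
  jsonlite::write_json(list(repeats = repeatRanges(repeatMap),
                            anchorAtoms = repeatMap@anchorAtoms),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## result tables --------------------------------------------------------------

#' Write an analysis table deterministically
#'
#' Tab-separated, fixed column order, numbers at fixed precision
#' (`%.6g`), no row names: the same input always produces byte-identical
#' output.  An empty table produces a header-only file.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(df, path, digits = 6L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- vapply(seq_along(df), function(j) {
      col <- df[[j]]
      if (is.numeric(col) && !is.integer(col))
        sprintf(paste0("%.", digits, "g"), col)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
    writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Write an unfolding-order contingency table
#'
#' Writes the repeat-by-position table in the standard layout: one row per
#' repeat (`r1` .. `rR`), one column per order position (`1st` .. ), integer
#' counts.
#'
#' @param tab Matrix from [orderContingency()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOrderTable <- function(tab, path) {
  df <- data.frame(repeat. = rownames(tab), tab, check.names = FALSE)
  names(df)[1L] <- "repeat"
  writeResultsTable(df, path)
}
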