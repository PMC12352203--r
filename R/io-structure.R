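#' Extract the per-residue B-factor track from a structure model
#'
#' For AlphaFold models the B-factor column stores the per-residue model
#' confidence (pLDDT, 0-100), identical for all atoms of a residue. One value
#' per residue is returned: the B-factor of the CA atom, falling back to the
#' first atom of the residue. PDB and mmCIF are read via bio3d.
#'
#' @param path PDB or mmCIF file.
#' @param chain optional chain selector; required when the file holds more
#'   than one chain.
#' @return a [PerResidueTrack-class] named `"pLDDT"`.
#' @export
readStructureBfactorTrack <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no polymer chain in ", path)
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("ambiguous chain: file has chains ",
           paste(chains, collapse = ", "), "; supply 'chain'")
    chain <- chains
  } else if (!chain %in% chains) {
    stop("chain selector '", chain, "' not found")
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  resKey <- paste(atoms$resno, atoms$insert)
  firstOfRes <- !duplicated(resKey)
  resOrder <- resKey[firstOfRes]
  b <- vapply(resOrder, function(k) {
    rows <- atoms[resKey == k, , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca)) ca$b[1] else rows$b[1]
  }, numeric(1))
  id <- sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE)
  perResidueTrack(id, "pLDDT", unname(b))
}

#' Repaint structure B-factors with a per-residue track
#'
#' Rewrites the B-factor field of every `ATOM`/`HETATM` record of a PDB file
#' so that all atoms of residue *i* carry `100 * values[i]`, formatted as
#' fixed two-decimal. Everything else in the file -- coordinates, atom
#' numbering, residue numbering, remarks -- is preserved byte for byte.
#' Residues with a missing track value are painted `0.00` and reported.
#'
#' @param pathIn input PDB file (one chain).
#' @param track a [PerResidueTrack-class] with values in `[0, 1]`, one per
#'   residue of the structure.
#' @param pathOut output PDB file.
#' @return `pathOut`, invisibly.
#' @export
writePaintedStructure <- function(pathIn, track, pathOut) {
  if (!file.exists(pathIn)) stop("file not found: ", pathIn)
  if (grepl("\\.cif$", pathIn, ignore.case = TRUE))
    stop("repainting supports PDB input; convert mmCIF to PDB first")
  v <- trackValues(track)
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("track values must lie in [0, 1] for repainting")
  lines <- readLines(pathIn)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom)) stop("no ATOM/HETATM records in ", pathIn)
  recs <- lines[isAtom]
  # residue identity: chain (col 22) + resseq (cols 23-26) + icode (col 27)
  resKey <- paste0(substr(recs, 22, 22), substr(recs, 23, 26),
                   substr(recs, 27, 27))
  resIndex <- match(resKey, unique(resKey))
  nRes <- max(resIndex)
  if (nRes != length(v))
    stop(sprintf("length mismatch: structure has %d residues, track has %d",
                 nRes, length(v)))
  painted <- v[resIndex]
  missing <- is.na(painted)
  if (any(missing)) {
    message(sum(is.na(v)), " residue(s) had missing track values; painted 0.00")
    painted[missing] <- 0
  }
  bf <- sprintf("%6.2f", 100 * painted)
  # pad short records out to the B-factor field if needed
  recs <- formatC(recs, width = 66, flag = "-")
  substr(recs, 61, 66) <- bf
  lines[isAtom] <- recs
  writeLines(lines, pathOut)
  invisible(pathOut)
}
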