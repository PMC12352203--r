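#' Read a multi-predictor disorder profile CSV
#'
#' Expects a CSV with a `res_index` column (contiguous from 1), a `res`
#' residue-letter column, and one numeric column per disorder predictor.
#' Returns one [PerResidueTrack-class] per predictor column, in column order.
#'
#' @param path CSV file.
#' @param proteinId accession to attach to the tracks.
#' @param naAllowed if `TRUE` (default) cells reading `NA` (or empty) become
#'   missing markers; if `FALSE` they are an error.
#' @return named list of [PerResidueTrack-class] objects.
#' @export
readDisorderCsv <- function(path, proteinId = "unknown", naAllowed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (!all(c("res_index", "res") %in% names(df)))
    stop("disorder CSV needs 'res_index' and 'res' columns")
  idx <- as.integer(df$res_index)
  n <- length(idx)
  if (n == 0L) stop("empty disorder profile")
  if (anyDuplicated(idx))
    stop("duplicate residue index ", idx[duplicated(idx)][1])
  expect <- seq_len(n)
  if (!identical(idx, expect)) {
    gap <- setdiff(expect, idx)[1]
    stop("residue index not contiguous from 1: gap at ", gap)
  }
  predCols <- setdiff(names(df), c("res_index", "res"))
  if (length(predCols) == 0L) stop("no predictor columns found")
  tracks <- lapply(predCols, function(col) {
    raw <- df[[col]]
    isNa <- is.na(raw) | raw == "" | toupper(raw) == "NA"
    if (any(isNa) && !naAllowed)
      stop(sprintf("missing score in column '%s' at residue %d",
                   col, which(isNa)[1]))
    val <- suppressWarnings(as.numeric(raw))
    badCell <- which(!isNa & is.na(val))
    if (length(badCell))
      stop(sprintf("non-numeric score '%s' in column '%s' at residue %d",
                   raw[badCell[1]], col, badCell[1]))
    val[isNa] <- NA_real_
    perResidueTrack(proteinId, col, val)
  })
  names(tracks) <- predCols
  tracks
}

#' Write per-residue tracks as a disorder-profile CSV
#'
#' Writes `res_index`, `res`, then one column per track, in the dialect read
#' back by [readDisorderCsv()].
#'
#' @param tracks list of [PerResidueTrack-class] of equal length.
#' @param seq optional [ProteinSequence-class] supplying the `res` column;
#'   `"X"` is used when absent.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDisorderCsv <- function(tracks, path, seq = NULL) {
  stopifnot(length(tracks) >= 1L)
  n <- length(trackValues(tracks[[1]]))
  res <- if (is.null(seq)) rep("X", n) else seq@residues
  out <- data.frame(res_index = seq_len(n), res = res)
  for (tr in tracks) out[[trackName(tr)]] <- trackValues(tr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a FuzDrop-style droplet-promoting probability profile
#'
#' Expects a CSV of per-residue droplet-promoting probabilities with columns
#' `res_index`, `res`, `p_DP`, preceded by a header comment line carrying the
#' protein-level phase-separation probability, `# pLLPS=<value>`.
#'
#' @param path CSV file.
#' @param proteinId accession to attach.
#' @return list with `track` (a [PerResidueTrack-class] named `"p_DP"`) and
#'   `pLLPS` (numeric scalar in `[0, 1]`).
#' @export
readFuzdropProfile <- function(path, proteinId = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("pLLPS\\s*=\\s*([0-9.eE+-]+)", hdr))
  hit <- which(vapply(m, length, 0L) == 2L)
  if (length(hit) == 0L) stop("missing pLLPS header line ('# pLLPS=<x>')")
  pLLPS <- as.numeric(m[[hit[1]]][2])
  if (is.na(pLLPS) || pLLPS < 0 || pLLPS > 1)
    stop("pLLPS outside [0, 1]: ", pLLPS)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) <= 1L) stop("empty profile")
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!"p_DP" %in% names(df)) stop("missing 'p_DP' column")
  v <- as.numeric(df$p_DP)
  if (any(is.na(v))) stop("non-numeric p_DP value")
  if (any(v < 0 | v > 1))
    stop("p_DP outside [0, 1] at residue ", which(v < 0 | v > 1)[1])
  list(track = perResidueTrack(proteinId, "p_DP", v), pLLPS = pLLPS)
}

#' Write a FuzDrop-style profile
#'
#' @param track a [PerResidueTrack-class] of droplet-promoting probabilities.
#' @param pLLPS protein-level phase-separation probability.
#' @param path output file.
#' @param seq optional [ProteinSequence-class] for the `res` column.
#' @return `path`, invisibly.
#' @export
writeFuzdropProfile <- function(track, pLLPS, path, seq = NULL) {
  n <- length(track)
  res <- if (is.null(seq)) rep("X", n) else seq@residues
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pLLPS=%.6g", pLLPS), con)
  utils::write.csv(data.frame(res_index = seq_len(n), res = res,
                              p_DP = trackValues(track)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
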