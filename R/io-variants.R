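#' Parse a missense variant string
#'
#' Accepts the one-letter form `"G61E"` and the three-letter HGVS-like form
#' `"p.Gly61Glu"` (the `p.` prefix is optional for both). Returns the
#' normalized components.
#'
#' @param variant variant string.
#' @return list with `ref`, `pos` (integer), `alt` in one-letter form.
#' @examples
#' parseVariant("p.Gly61Glu")
#' parseVariant("G61E")
#' @export
parseVariant <- function(variant) {
  v <- sub("^p\\.", "", trimws(variant))
  m1 <- regmatches(v, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", v))[[1]]
  if (length(m1) == 4L) {
    ref <- toupper(m1[2]); alt <- toupper(m1[4])
    if (!(ref %in% .AA20) || !(alt %in% .AA20))
      stop("unparseable variant string: ", variant)
    return(list(ref = ref, pos = as.integer(m1[3]), alt = alt))
  }
  m3 <- regmatches(v, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", v))[[1]]
  if (length(m3) == 4L) {
    fix <- function(x) paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
    ref <- .AA3TO1[fix(m3[2])]; alt <- .AA3TO1[fix(m3[4])]
    if (is.na(ref) || is.na(alt))
      stop("unparseable variant string: ", variant)
    return(list(ref = unname(ref), pos = as.integer(m3[3]), alt = unname(alt)))
  }
  stop("unparseable variant string: ", variant)
}

#' Read an AlphaMissense-style substitution table
#'
#' Expects a tab-separated file in the public AlphaMissense UniProt
#' substitution dialect: columns `uniprot_id`, `protein_variant`,
#' `am_pathogenicity`, `am_class`, with `#` comment lines. Rows are filtered
#' to `proteinId` and variant strings parsed into (ref, pos, alt).
#'
#' @param path TSV file.
#' @param proteinId accession to retain.
#' @return a [VariantScoreTable-class].
#' @export
readAlphaMissense <- function(path, proteinId) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("uniprot_id", "protein_variant", "am_pathogenicity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"am_class" %in% names(df)) df$am_class <- NA_character_
  df <- df[df$uniprot_id == proteinId, , drop = FALSE]
  if (nrow(df) == 0L)
    return(variantScoreTable(proteinId, integer(), character(), character(),
                             numeric(), character()))
  parsed <- lapply(df$protein_variant, parseVariant)
  ref <- vapply(parsed, `[[`, "", "ref")
  pos <- vapply(parsed, `[[`, 1L, "pos")
  alt <- vapply(parsed, `[[`, "", "alt")
  score <- as.numeric(df$am_pathogenicity)
  if (any(is.na(score))) stop("non-numeric pathogenicity score")
  if (any(score < 0 | score > 1))
    stop("pathogenicity score outside [0, 1]")
  if (any(ref == alt))
    stop("ref == alt in variant ", df$protein_variant[which(ref == alt)[1]])
  key <- paste(pos, alt)
  if (anyDuplicated(key))
    stop("duplicate (position, alt) row: ", key[duplicated(key)][1])
  variantScoreTable(proteinId, pos, ref, alt, score, df$am_class)
}

#' Write a VariantScoreTable in the AlphaMissense TSV dialect
#'
#' @param table a [VariantScoreTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlphaMissense <- function(table, path) {
  e <- variantEntries(table)
  out <- data.frame(uniprot_id = proteinId(table),
                    protein_variant = paste0(e$ref, e$pos, e$alt),
                    am_pathogenicity = e$score,
                    am_class = ifelse(is.na(e$class), "", e$class))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-variant pathogenicity scores", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
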