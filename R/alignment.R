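# Alignments are character matrices (taxa x sites, rownames = taxa) over the
# 20-residue alphabet plus '-'.  Ambiguity codes 'X', '?' and '.' are coerced
# to '-' on read: the substitution model is a pure 20-state process and
# ambiguous residues must not enter it.

#' Read a protein alignment from FASTA
#'
#' @param path Path to a FASTA file of equal-length, uniquely named sequences.
#' @return A character matrix (taxa x sites) with gaps as `-`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms))
    stop("duplicate FASTA headers: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- nms[which(lens != lens[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has length ",
         lens[which(lens != lens[1])[1]], " but '", nms[1], "' has length ",
         lens[1], call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- nms
  normalize_alignment(mat)
}

normalize_alignment <- function(mat) {
  mat[mat %in% c("X", "?", ".", "*")] <- "-"
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, "-"))
  if (length(bad))
    stop("alignment contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  mat
}

#' Write an alignment to FASTA
#'
#' @param alignment Character matrix as returned by [read_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  lines <- character(2L * nrow(alignment))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(alignment))
  lines[c(FALSE, TRUE)] <- apply(alignment, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# Integer encoding of an alignment: 1..20 for residues, NA for gaps.
encode_alignment <- function(alignment) {
  m <- match(alignment, AA_ALPHABET)
  dim(m) <- dim(alignment)
  rownames(m) <- rownames(alignment)
  m
}
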