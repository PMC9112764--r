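#' Read reference genomes from a multi-FASTA file
#'
#' Loads one or more reference replicons. Sequences are case-folded to upper
#' case and the identifier of each record is the first whitespace-delimited
#' token of its header line, following common aligner behaviour.
#'
#' @param path Path to a FASTA file (plain or gzip/bgzip compressed).
#' @return A named character vector, one element per record, alphabet
#'   restricted to `A`, `C`, `G`, `T`, `N`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 plasmid", "acgtACGT"), fa)
#' read_reference(fa)
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("reference FASTA not found: ", path))
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("failed to parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(seqs) == 0L) {
    abort(paste0("reference FASTA '", path, "' contains no records"))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate reference id(s) in '", path, "': ", paste(dup, collapse = ", ")))
  }
  out <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    abort(paste0(
      "non-nucleotide characters (outside A/C/G/T/N) in reference record(s): ",
      paste(ids[bad], collapse = ", ")
    ))
  }
  setNames(out, ids)
}
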