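#' Pile up filtered alignments on reference positions
#'
#' Applies the alignment filter, expands every passing record to per-position
#' base calls, and resolves each (position, fragment) to at most one base so
#' that a DNA fragment — both mates of a paired-end read together — counts
#' once per reference column. Where the two mates overlap and disagree the
#' fragment contributes nothing at that column (conflicting evidence);
#' deleted (`-`) and `N` calls never contribute. Base qualities are not used.
#'
#' @param alignments Alignment tibble from [read_alignments()],
#'   coordinate-sorted within each reference.
#' @param refs Named character vector of reference sequences, as returned by
#'   [read_reference()]. Used to validate reference ids and coordinates.
#' @param min_mapq Minimum mapping quality (default 20).
#' @return A tibble with one row per retained base call: `ref_id`, `pos`
#'   (1-based), `fragment_id`, `base` (one of A/C/G/T), sorted by
#'   `(ref_id, pos, fragment_id)`.
#' @seealso [pileup_counts()] for per-column allele counts.
#' @export
build_pileup <- function(alignments, refs, min_mapq = 20) {
  stopifnot(is.character(refs), !is.null(names(refs)))
  empty <- tibble(
    ref_id = character(), pos = integer(),
    fragment_id = character(), base = character()
  )
  if (nrow(alignments) == 0L) {
    return(empty)
  }
  unknown <- setdiff(unique(alignments$ref_id), names(refs))
  if (length(unknown) > 0L) {
    abort(paste0(
      "alignments reference id(s) absent from the reference FASTA: ",
      paste(unknown, collapse = ", ")
    ))
  }
  unsorted <- alignments |>
    group_by(.data$ref_id) |>
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (any(!unsorted$ok)) {
    abort(paste0(
      "alignments are not coordinate-sorted within reference(s): ",
      paste(unsorted$ref_id[!unsorted$ok], collapse = ", ")
    ))
  }
  aln <- filter_alignments(alignments, min_mapq = min_mapq)
  if (nrow(aln) == 0L) {
    return(empty)
  }
  over <- nchar(aln$aligned_seq) + aln$pos - 1L > nchar(refs[aln$ref_id])
  if (any(over)) {
    abort(paste0(
      "alignment extends past the end of its reference (first offender: read '",
      aln$fragment_id[which(over)[1]], "' on ", aln$ref_id[which(over)[1]], ")"
    ))
  }

  widths <- nchar(aln$aligned_seq)
  calls <- tibble(
    ref_id = rep(aln$ref_id, widths),
    pos = rep(aln$pos, widths) + sequence(widths) - 1L,
    fragment_id = rep(aln$fragment_id, widths),
    base = unlist(strsplit(aln$aligned_seq, "", fixed = TRUE), use.names = FALSE)
  )
  calls |>
    filter(.data$base %in% c("A", "C", "G", "T")) |>
    distinct(.data$ref_id, .data$pos, .data$fragment_id, .data$base) |>
    add_count(.data$ref_id, .data$pos, .data$fragment_id) |>
    filter(n == 1L) |>
    select(-"n") |>
    arrange(.data$ref_id, .data$pos, .data$fragment_id)
}

#' Per-column allele counts of a pileup
#'
#' @param pileup Tibble from [build_pileup()].
#' @return A tibble `ref_id`, `pos`, `base`, `n` — the number of distinct
#'   fragments supporting each base at each covered reference position.
#' @export
pileup_counts <- function(pileup) {
  pileup |>
    count(.data$ref_id, .data$pos, .data$base, name = "n") |>
    arrange(.data$ref_id, .data$pos, desc(.data$n), .data$base)
}
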