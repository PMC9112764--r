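SAM_FLAG_PAIRED <- 0x1L
SAM_FLAG_PROPER <- 0x2L
SAM_FLAG_UNMAPPED <- 0x4L
SAM_FLAG_MATE_UNMAPPED <- 0x8L
SAM_FLAG_REVERSE <- 0x10L
SAM_FLAG_MATE_REVERSE <- 0x20L
SAM_FLAG_FIRST <- 0x40L
SAM_FLAG_LAST <- 0x80L
SAM_FLAG_SECONDARY <- 0x100L
SAM_FLAG_QCFAIL <- 0x200L
SAM_FLAG_DUP <- 0x400L
SAM_FLAG_SUPPLEMENTARY <- 0x800L

#' Read short-read alignments from SAM or BAM
#'
#' Reads mapped alignment records into a tibble, one row per record, with the
#' read sequence laid out in reference space: soft-clipped and inserted bases
#' are removed and deleted reference positions appear as `-`, so that
#' character `k` of `aligned_seq` sits at reference position `pos + k - 1`.
#' SAM input is converted to a coordinate-sorted BAM on the fly.
#'
#' No filtering is applied here; secondary, duplicate, QC-fail and
#' supplementary records are all returned (unmapped records carry no
#' coordinates and are dropped by the reader). Use [filter_alignments()].
#'
#' @param path Path to a SAM (`.sam`) or BAM file, coordinate-sorted.
#' @return A tibble with columns `fragment_id` (the read name; shared by both
#'   mates of a pair), `ref_id`, `pos` (1-based leftmost reference position),
#'   `mapq`, `flag`, and `aligned_seq`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE, indexDestination = TRUE),
      error = function(e) abort(paste0("failed to parse SAM '", path, "': ", conditionMessage(e)))
    )
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq", "seq"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(gal) == 0L) {
    return(tibble(
      fragment_id = character(), ref_id = character(), pos = integer(),
      mapq = integer(), flag = integer(), aligned_seq = character()
    ))
  }
  mc <- S4Vectors::mcols(gal)
  refseq <- GenomicAlignments::sequenceLayer(mc$seq, GenomicAlignments::cigar(gal))
  tibble(
    fragment_id = mc$qname,
    ref_id = as.character(GenomicAlignments::seqnames(gal)),
    pos = GenomicAlignments::start(gal),
    mapq = as.integer(mc$mapq),
    flag = as.integer(mc$flag),
    aligned_seq = as.character(refseq)
  )
}

#' Alignment record filter
#'
#' `alignment_passes()` reproduces the classical pileup filter: a record is
#' kept iff its mapping quality is at least `min_mapq` (boundary inclusive)
#' and none of the unmapped / QC-fail / duplicate / secondary flag bits is
#' set. Supplementary alignments are excluded as well so that a fragment can
#' contribute at most one base per reference column. `filter_alignments()`
#' applies the same rule to an alignment tibble.
#'
#' @param flag Integer vector of SAM flag fields.
#' @param mapq Integer vector of mapping qualities.
#' @param min_mapq Minimum mapping quality, default 20.
#' @return `alignment_passes()`: a logical vector; `filter_alignments()`: the
#'   filtered tibble.
#' @examples
#' alignment_passes(flag = 0L, mapq = 20L)   # TRUE
#' alignment_passes(flag = 0L, mapq = 19L)   # FALSE
#' alignment_passes(flag = 1024L, mapq = 60L) # duplicate -> FALSE
#' @export
alignment_passes <- function(flag, mapq, min_mapq = 20) {
  excluded <- bitwOr(
    bitwOr(SAM_FLAG_UNMAPPED, SAM_FLAG_QCFAIL),
    bitwOr(bitwOr(SAM_FLAG_DUP, SAM_FLAG_SECONDARY), SAM_FLAG_SUPPLEMENTARY)
  )
  bitwAnd(as.integer(flag), excluded) == 0L & mapq >= min_mapq
}

#' @rdname alignment_passes
#' @param alignments A tibble as returned by [read_alignments()].
#' @export
filter_alignments <- function(alignments, min_mapq = 20) {
  filter(alignments, alignment_passes(.data$flag, .data$mapq, min_mapq))
}
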