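DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Configuration for the strain-mixture simulator
#'
#' Captures the desk-scale study conditions the simulator emulates: one or
#' more random reference replicons, 1-3 strain haplotypes per replicon that
#' differ from the base reference by point substitutions, and paired-end
#' short reads (2 x 101 bp by default) drawn uniformly along each strain
#' with normally distributed insert sizes and uniform substitution errors.
#'
#' @param seed Integer RNG seed; a fixed seed makes every downstream file
#'   byte-identical.
#' @param n_refs Number of reference replicons.
#' @param ref_length Length of each replicon in bp.
#' @param n_strains Strain haplotypes per replicon (1-3).
#' @param snv_rate Per-bp probability of a between-strain substitution site.
#' @param read_length Read length in bp (default 101).
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp;
#'   draws are truncated below at `read_length`.
#' @param depth Fold sequencing coverage per strain.
#' @param error_rate Per-base substitution error rate of the reads.
#' @param max_snv_gap Optional upper bound on the gap between consecutive
#'   SNV sites. `NULL` (default) places sites as a Bernoulli process
#'   (geometric gaps); when set, gaps are drawn uniformly on
#'   `[2/snv_rate - max_snv_gap, max_snv_gap]`, which preserves the marginal
#'   site rate while guaranteeing every pair of neighbouring sites is
#'   spannable by a fragment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_refs = 1, ref_length = 10000, n_strains = 2,
                       snv_rate = 0.005, read_length = 101,
                       insert_mean = 300, insert_sd = 30,
                       depth = 30, error_rate = 0.001, max_snv_gap = NULL) {
  stopifnot(
    ref_length > 0, n_refs >= 1, n_strains >= 1, n_strains <= 3,
    snv_rate >= 0, snv_rate <= 1, error_rate >= 0, error_rate <= 1,
    read_length > 0, depth > 0, insert_sd >= 0
  )
  if (insert_mean < read_length) {
    abort("infeasible geometry: insert_mean is shorter than read_length")
  }
  if (insert_mean + 4 * insert_sd > ref_length) {
    abort("infeasible geometry: inserts do not fit inside the reference")
  }
  if (!is.null(max_snv_gap)) {
    stopifnot(max_snv_gap >= 1)
    if (snv_rate > 0 && 2 / snv_rate - max_snv_gap > max_snv_gap) {
      abort("max_snv_gap too small for the requested snv_rate (mean gap 1/snv_rate unreachable)")
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_refs = as.integer(n_refs),
      ref_length = as.integer(ref_length), n_strains = as.integer(n_strains),
      snv_rate = snv_rate, read_length = as.integer(read_length),
      insert_mean = insert_mean, insert_sd = insert_sd,
      depth = depth, error_rate = error_rate, max_snv_gap = max_snv_gap
    ),
    class = "sim_config"
  )
}

draw_snv_positions <- function(cfg) {
  L <- cfg$ref_length
  if (cfg$snv_rate <= 0) {
    return(integer(0))
  }
  if (is.null(cfg$max_snv_gap)) {
    return(which(runif(L) < cfg$snv_rate))
  }
  m <- cfg$max_snv_gap
  a <- max(1, round(2 / cfg$snv_rate) - m)
  pos <- integer(0)
  cur <- 0L
  repeat {
    cur <- cur + as.integer(floor(runif(1, a, m + 1)))
    if (cur > L) break
    pos <- c(pos, cur)
  }
  pos
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) {
    return(seqs)
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  for (i in hit) {
    flat[i] <- sample(setdiff(DNA_BASES, flat[i]), 1L)
  }
  vapply(
    split(flat, rep(seq_along(lens), lens)),
    paste0, character(1), collapse = ""
  )
}

#' Simulate a strain mixture with ground truth
#'
#' Draws random reference replicons, derives strain haplotypes by point
#' substitutions (each SNV site assigns a substituted base to one strain,
#' drawn uniformly), and samples paired-end fragments uniformly along each
#' strain with per-base substitution errors. Everything is deterministic
#' under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `plr_sim`: list with `cfg`, `refs` (named
#'   character), `strains` (tibble `ref_id`, `strain`, `sequence`), `snvs`
#'   (tibble `ref_id`, `pos`, `ref_base`, one `strain_<k>` column per
#'   strain), and `fragments` (tibble `fragment_id`, `ref_id`, `strain`,
#'   `start`, `insert`, `r1_seq`, `r2_seq`; both sequences in reference
#'   orientation, errors applied).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$ref_length
  rl <- cfg$read_length
  refs <- setNames(
    vapply(
      seq_len(cfg$n_refs),
      function(i) paste0(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
      character(1)
    ),
    paste0("ref_", seq_len(cfg$n_refs))
  )

  snvs <- list()
  strains <- list()
  for (rid in names(refs)) {
    base_chars <- strsplit(refs[[rid]], "", fixed = TRUE)[[1]]
    pos <- draw_snv_positions(cfg)
    strain_chars <- replicate(cfg$n_strains, base_chars, simplify = FALSE)
    allele_tbl <- NULL
    if (length(pos) > 0L && cfg$n_strains >= 2L) {
      carrier <- sample.int(cfg$n_strains, length(pos), replace = TRUE)
      alt <- vapply(
        base_chars[pos],
        function(b) sample(setdiff(DNA_BASES, b), 1L),
        character(1), USE.NAMES = FALSE
      )
      for (k in seq_along(pos)) {
        strain_chars[[carrier[k]]][pos[k]] <- alt[k]
      }
      allele_tbl <- tibble(ref_id = rid, pos = pos, ref_base = base_chars[pos])
      for (s in seq_len(cfg$n_strains)) {
        allele_tbl[[paste0("strain_", s)]] <- ifelse(carrier == s, alt, base_chars[pos])
      }
    } else {
      allele_tbl <- tibble(ref_id = character(), pos = integer(), ref_base = character())
      for (s in seq_len(cfg$n_strains)) {
        allele_tbl[[paste0("strain_", s)]] <- character()
      }
    }
    snvs[[rid]] <- allele_tbl
    strains[[rid]] <- tibble(
      ref_id = rid,
      strain = seq_len(cfg$n_strains),
      sequence = vapply(strain_chars, paste0, character(1), collapse = "")
    )
  }
  strains <- bind_rows(strains)
  snvs <- bind_rows(snvs)

  n_frag <- max(1L, as.integer(round(cfg$depth * L / (2 * rl))))
  frags <- list()
  for (i in seq_len(nrow(strains))) {
    rid <- strains$ref_id[i]
    s <- strains$strain[i]
    hap <- strains$sequence[i]
    ins <- pmax(rl, as.integer(round(rnorm(n_frag, cfg$insert_mean, cfg$insert_sd))))
    ins <- pmin(ins, L)
    start <- as.integer(floor(runif(n_frag) * (L - ins + 1))) + 1L
    r1 <- substring(hap, start, start + rl - 1L)
    r2_start <- pmax(start, start + ins - rl)
    r2 <- substring(hap, r2_start, r2_start + rl - 1L)
    frags[[i]] <- tibble(
      fragment_id = sprintf("%s_s%d_f%06d", rid, s, seq_len(n_frag)),
      ref_id = rid, strain = s,
      start = start, insert = ins,
      r1_seq = add_read_errors(r1, cfg$error_rate),
      r2_seq = add_read_errors(r2, cfg$error_rate)
    )
  }
  fragments <- bind_rows(frags) |>
    arrange(.data$ref_id, .data$start, .data$fragment_id)

  structure(
    list(cfg = cfg, refs = refs, strains = strains, snvs = snvs, fragments = fragments),
    class = "plr_sim"
  )
}

#' @export
print.plr_sim <- function(x, ...) {
  cat(
    "<plr_sim> ", length(x$refs), " replicon(s) x ", x$cfg$ref_length, " bp, ",
    x$cfg$n_strains, " strain(s), ", nrow(x$snvs), " SNV site(s), ",
    nrow(x$fragments), " paired-end fragment(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Perfect-knowledge alignments for simulated reads
#'
#' Places every simulated read at its true origin on the base reference
#' (substitution-only haplotypes leave coordinates unchanged), producing
#' coordinate-sorted, properly paired records with mapping quality 60 and
#' full-match CIGARs. This lets the whole pipeline be exercised without an
#' external aligner; read errors and strain SNVs appear as mismatches in the
#' pileup, exactly as an aligner would report them.
#'
#' @param sim A `plr_sim` from [simulate_community()].
#' @return A tibble of SAM fields (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`), two rows per
#'   fragment, coordinate-sorted.
#' @seealso [write_sam()], [as_alignments()]
#' @export
simulate_alignments <- function(sim) {
  stopifnot(inherits(sim, "plr_sim"))
  fr <- sim$fragments
  rl <- sim$cfg$read_length
  r2_pos <- pmax(fr$start, fr$start + fr$insert - rl)
  r1 <- tibble(
    qname = fr$fragment_id,
    flag = 99L,
    rname = fr$ref_id,
    pos = fr$start,
    mapq = 60L,
    cigar = paste0(rl, "M"),
    rnext = "=",
    pnext = r2_pos,
    tlen = fr$insert,
    seq = fr$r1_seq,
    qual = strrep("I", rl)
  )
  r2 <- r1 |>
    mutate(
      flag = 147L,
      pos = r2_pos,
      pnext = fr$start,
      tlen = -fr$insert,
      seq = fr$r2_seq
    )
  bind_rows(r1, r2) |>
    arrange(match(.data$rname, names(sim$refs)), .data$pos, .data$qname, .data$flag)
}

#' Write a SAM-field tibble to a SAM file
#'
#' @param sam Tibble from [simulate_alignments()].
#' @param refs Named character vector of reference sequences (for `@SQ`
#'   header lines).
#' @param path Output path (should end in `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, refs, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq, sam$cigar,
    sam$rnext, sam$pnext, sam$tlen, sam$seq, sam$qual
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Convert simulated SAM records to the alignment-tibble schema
#'
#' Fast path for in-memory testing: equivalent to writing the records with
#' [write_sam()] and reading them back with [read_alignments()] (simulated
#' CIGARs are full matches, so the aligned sequence is the read sequence).
#'
#' @param sam Tibble from [simulate_alignments()].
#' @return A tibble in the schema of [read_alignments()].
#' @export
as_alignments <- function(sam) {
  tibble(
    fragment_id = sam$qname,
    ref_id = sam$rname,
    pos = sam$pos,
    mapq = sam$mapq,
    flag = sam$flag,
    aligned_seq = sam$seq
  )
}

#' Write all simulator outputs to a directory
#'
#' Writes the base references (`ref.fasta`), strain haplotypes
#' (`strains.fasta`), paired reads (`reads_1.fastq`, `reads_2.fastq`; R2 in
#' sequencing orientation), ground-truth alignments (`alignments.sam`) and
#' the SNV truth table (`truth_snvs.tsv`).
#'
#' @param sim A `plr_sim` from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "plr_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- list(
    ref_fasta = file.path(dir, "ref.fasta"),
    strains_fasta = file.path(dir, "strains.fasta"),
    fastq_1 = file.path(dir, "reads_1.fastq"),
    fastq_2 = file.path(dir, "reads_2.fastq"),
    sam = file.path(dir, "alignments.sam"),
    truth = file.path(dir, "truth_snvs.tsv")
  )
  refset <- Biostrings::DNAStringSet(sim$refs)
  Biostrings::writeXStringSet(refset, p$ref_fasta, width = 70)
  strainset <- Biostrings::DNAStringSet(sim$strains$sequence)
  names(strainset) <- paste0(sim$strains$ref_id, "_strain", sim$strains$strain)
  Biostrings::writeXStringSet(strainset, p$strains_fasta, width = 70)

  fr <- sim$fragments
  qual <- strrep("I", sim$cfg$read_length)
  readr::write_lines(
    as.vector(rbind(paste0("@", fr$fragment_id, "/1"), fr$r1_seq, "+", qual)),
    p$fastq_1
  )
  readr::write_lines(
    as.vector(rbind(paste0("@", fr$fragment_id, "/2"), revcomp(fr$r2_seq), "+", qual)),
    p$fastq_2
  )
  write_sam(simulate_alignments(sim), sim$refs, p$sam)
  readr::write_tsv(sim$snvs, p$truth, progress = FALSE)
  invisible(p)
}
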