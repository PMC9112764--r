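# Shared fixture builders. All fixtures are generated in code; nothing binary
# is stored.

# One alignment-tibble row in the schema of read_alignments().
aln_row <- function(fragment_id, ref_id, pos, seq, mapq = 30L, flag = 0L) {
  tibble::tibble(
    fragment_id = fragment_id, ref_id = ref_id, pos = as.integer(pos),
    mapq = as.integer(mapq), flag = as.integer(flag), aligned_seq = seq
  )
}

# Write a SAM file from raw field lists (for CIGAR-level tests).
write_raw_sam <- function(path, refs, records) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(refs), "\tLN:", nchar(refs))
  )
  writeLines(c(header, records), path)
  path
}

# The worked example: a 13-bp container, bubbles at offsets 3/6/9/12 with
# haplotypes (T,A,C,G) and (C,G,T,T), covered by eight single-end reads that
# chain across the bubbles with partial overlaps.
worked_example <- function() {
  hap1 <- "AATAAAAACAAGA"
  hap2 <- "AACAAGAATAATA"
  spans <- list(
    r1 = list(hap = 1L, from = 1L, to = 8L),   # (T,A,-,-)
    r2 = list(hap = 1L, from = 4L, to = 11L),  # (-,A,C,-)
    r3 = list(hap = 1L, from = 7L, to = 13L),  # (-,-,C,G)
    r4 = list(hap = 1L, from = 3L, to = 9L),   # (T,A,C,-)
    r5 = list(hap = 2L, from = 3L, to = 9L),   # (C,G,T,-)
    r6 = list(hap = 2L, from = 1L, to = 8L),   # (C,G,-,-)
    r7 = list(hap = 2L, from = 4L, to = 11L),  # (-,G,T,-)
    r8 = list(hap = 2L, from = 9L, to = 13L)   # (-,-,T,T)
  )
  aln <- dplyr::bind_rows(lapply(names(spans), function(nm) {
    s <- spans[[nm]]
    hap <- if (s$hap == 1L) hap1 else hap2
    aln_row(nm, "ref_1", s$from, substr(hap, s$from, s$to))
  })) |>
    dplyr::arrange(pos, fragment_id)
  list(
    aln = aln,
    refs = c(ref_1 = strrep("A", 13)),
    hap1 = hap1, hap2 = hap2,
    bubble_offsets = c(3L, 6L, 9L, 12L),
    vectors = c(
      "TA--", "-AC-", "--CG", "TAC-",
      "CGT-", "CG--", "-GT-", "--TT"
    )
  )
}

# Random bubble-vector sets for clustering checks: each vector has >= 2
# informative elements (the bubble-linking requirement).
random_vector_set <- function(n, B) {
  draw_one <- function() {
    repeat {
      v <- sample(c("A", "C", "G", "T", "-"), B, replace = TRUE,
                  prob = c(0.125, 0.125, 0.125, 0.125, 0.5))
      if (sum(v != "-") >= 2L) {
        return(paste0(v, collapse = ""))
      }
    }
  }
  tibble::tibble(elements = vapply(seq_len(n), function(i) draw_one(), character(1)))
}

# Independent clustering oracle: full pairwise distance matrix, connected
# components of the zero-distance graph (igraph).
oracle_membership <- function(elements) {
  n <- length(elements)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1L) {
    edges <- integer(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (plrforge::vector_distance(elements[i], elements[j]) == 0) {
          edges <- c(edges, i, j)
        }
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  igraph::components(g)$membership
}

# Are two cluster labellings the same partition?
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, integer(1)))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, integer(1)))])
  )
}
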