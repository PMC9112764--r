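#' Generate pseudo-long reads from alignments and references
#'
#' Runs the full PLR pipeline in memory: filter and pile up the alignments,
#' break each reference into coverage containers, build each container's
#' normal/bubble graph, extract and cluster bubble-linking vectors, integrate
#' each cluster into a bubble combination, and assemble one variant-aware
#' sequence (V-PLR) per combination.
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file, or a tibble
#'   from [read_alignments()].
#' @param reference Path to a multi-FASTA, or a named character vector from
#'   [read_reference()].
#' @param min_mapq Minimum mapping quality for a read to enter the pileup
#'   (default 20).
#' @param min_container_len Minimum container length in bp (default 100).
#' @param min_rel_freq Relative-frequency cutoff for bubble alleles
#'   (default 0.5).
#' @param min_cluster_support Minimum total multiplicity for a cluster to
#'   seed a PLR path (default 1, i.e. no filter).
#' @return An object of class `plr_gen`: a list with
#'   \describe{
#'     \item{plrs}{tibble of V-PLRs, see [assemble_paths()]}
#'     \item{containers}{container tibble with `n_bubbles`, `n_vectors`,
#'       `n_clusters`, `n_plrs` and a `graph` list-column}
#'     \item{summary}{per-reference counts}
#'     \item{params}{the parameters used}
#'   }
#' @seealso [run_plr_gen()] for the file-in/file-out driver,
#'   [mask_to_nplr()] for N-PLRs.
#' @export
plr_gen <- function(alignments, reference,
                    min_mapq = 20, min_container_len = 100,
                    min_rel_freq = 0.5, min_cluster_support = 1) {
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      stopifnot(length(reference) == 1L)
      reference <- read_reference(reference)
    }
  } else {
    abort("'reference' must be a FASTA path or a named character vector")
  }
  if (is.character(alignments)) {
    alignments <- read_alignments(alignments)
  }
  pileup <- build_pileup(alignments, reference, min_mapq = min_mapq)
  containers <- build_containers(pileup, min_container_len = min_container_len)
  ref_order <- names(reference)
  containers <- containers |>
    arrange(match(.data$ref_id, ref_order), .data$start)
  graphs <- build_graphs(containers, pileup, min_rel_freq = min_rel_freq)

  per_container <- purrr::map(seq_len(nrow(graphs)), function(i) {
    g <- graphs$graph[[i]]
    B <- nrow(g$bubbles)
    vectors <- extract_bubble_vectors(g, pileup)
    clustered <- cluster_vectors(vectors)
    if (nrow(clustered) > 0L && min_cluster_support > 1) {
      keep <- clustered |>
        group_by(.data$cluster) |>
        summarise(support = sum(.data$multiplicity), .groups = "drop") |>
        filter(.data$support >= min_cluster_support)
      clustered <- clustered |>
        filter(.data$cluster %in% keep$cluster) |>
        mutate(cluster = match(.data$cluster, sort(unique(.data$cluster))))
    }
    combos <- build_combinations(clustered, B, context = g$container_id)
    plrs <- assemble_paths(g, combos)
    list(
      plrs = plrs,
      n_vectors = if (nrow(vectors)) sum(vectors$multiplicity) else 0L,
      n_clusters = if (nrow(clustered)) max(clustered$cluster) else 0L
    )
  })

  plrs <- bind_rows(purrr::map(per_container, "plrs"))
  containers_out <- graphs |>
    mutate(
      n_vectors = vapply(per_container, function(x) as.integer(x$n_vectors), integer(1)),
      n_clusters = vapply(per_container, function(x) as.integer(x$n_clusters), integer(1)),
      n_plrs = vapply(per_container, function(x) nrow(x$plrs), integer(1))
    )
  summary <- containers_out |>
    group_by(.data$ref_id) |>
    summarise(
      n_containers = n(),
      covered_bp = sum(.data$width),
      n_bubbles = sum(.data$n_bubbles),
      n_vectors = sum(.data$n_vectors),
      n_clusters = sum(.data$n_clusters),
      n_plrs = sum(.data$n_plrs),
      .groups = "drop"
    ) |>
    arrange(match(.data$ref_id, ref_order))

  structure(
    list(
      plrs = plrs,
      containers = containers_out,
      summary = summary,
      params = list(
        min_mapq = min_mapq,
        min_container_len = min_container_len,
        min_rel_freq = min_rel_freq,
        min_cluster_support = min_cluster_support
      )
    ),
    class = "plr_gen"
  )
}

#' @export
print.plr_gen <- function(x, ...) {
  g <- glance(x)
  cat("<plr_gen> ", g$n_plrs, " PLR(s) from ", g$n_containers,
    " container(s) on ", g$n_refs, " reference(s)\n",
    "  variant containers (>1 PLR): ", g$n_variant_containers,
    "; bubble columns: ", g$n_bubbles, "\n",
    "  total ", g$total_bp, " bp, N50 ", g$n50, " bp\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn plr_gen One row per emitted PLR (sequence included, graph
#'   internals dropped).
#' @param x,object A `plr_gen` object.
#' @param ... Unused.
#' @export
tidy.plr_gen <- function(x, ...) {
  x$plrs |>
    mutate(length = nchar(.data$sequence)) |>
    select(
      "ref_id", "start", "end", "container_id", "path_index", "length",
      "n_variant_positions", "support", "sequence"
    )
}

#' @describeIn plr_gen One-row run summary: reference, container, bubble and
#'   PLR counts, total bases and N50.
#' @export
glance.plr_gen <- function(x, ...) {
  lens <- nchar(x$plrs$sequence)
  tibble(
    n_refs = nrow(x$summary),
    n_containers = nrow(x$containers),
    n_variant_containers = sum(x$containers$n_plrs > 1L),
    n_bubbles = sum(x$containers$n_bubbles),
    n_plrs = nrow(x$plrs),
    total_bp = sum(lens),
    n50 = n50(lens)
  )
}

#' @describeIn plr_gen Histogram of PLR lengths, variant-carrying containers
#'   highlighted.
#' @export
autoplot.plr_gen <- function(object, ...) {
  d <- tidy(object) |>
    mutate(kind = ifelse(.data$n_variant_positions > 0L, "with bubbles", "monoallelic"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.8, position = "stack") +
    ggplot2::labs(x = "PLR length (bp)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Run the PLR pipeline on files and write outputs
#'
#' File-level driver behind the command-line interface: reads alignments and
#' references, runs [plr_gen()], optionally collapses to N-PLRs, and writes
#' the FASTA plus optional BED/manifest side outputs. Succeeds (with a
#' warning) even when no PLR is produced.
#'
#' @inheritParams plr_gen
#' @param out_fasta Output FASTA path.
#' @param nplr_mode Emit one N-masked PLR per container instead of V-PLRs.
#' @param drop_n Exclude PLRs containing `N` from the FASTA.
#' @param bed Optional path for a BED of container intervals.
#' @param manifest Optional path for a per-PLR TSV manifest.
#' @param quiet Suppress the per-reference summary message.
#' @return The `plr_gen` object, invisibly.
#' @export
run_plr_gen <- function(alignments, reference, out_fasta,
                        min_mapq = 20, min_container_len = 100,
                        min_rel_freq = 0.5, min_cluster_support = 1,
                        nplr_mode = FALSE, drop_n = FALSE,
                        bed = NULL, manifest = NULL, quiet = FALSE) {
  res <- plr_gen(
    alignments, reference,
    min_mapq = min_mapq, min_container_len = min_container_len,
    min_rel_freq = min_rel_freq, min_cluster_support = min_cluster_support
  )
  plrs <- if (nplr_mode) mask_to_nplr(res$plrs) else res$plrs
  write_plr_fasta(plrs, out_fasta, drop_n = drop_n)
  if (!is.null(bed)) {
    write_containers_bed(res$containers |> select(-"graph"), bed)
  }
  if (!is.null(manifest)) {
    readr::write_tsv(plr_manifest(plrs), manifest, progress = FALSE)
  }
  if (!quiet) {
    s <- res$summary
    for (i in seq_len(nrow(s))) {
      inform(paste0(
        s$ref_id[i], ": ", s$n_containers[i], " container(s), ",
        s$n_bubbles[i], " bubble column(s), ", s$n_clusters[i],
        " cluster(s), ", s$n_plrs[i], " PLR(s)"
      ))
    }
  }
  invisible(res)
}
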