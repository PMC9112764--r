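#' Classify one alignment column by allele frequency
#'
#' Retains every base whose count is at least `min_rel_freq` times the count
#' of the most frequent base (boundary inclusive: a base at exactly half the
#' top count is kept under the default 0.5). One retained base makes the
#' column part of a normal node; two or more make it a bubble column, one
#' bubble node per retained nucleotide.
#'
#' @param counts Named numeric vector of per-base counts (names among
#'   A/C/G/T), at least one positive entry.
#' @param min_rel_freq Relative-frequency cutoff against the most frequent
#'   base (default 0.5).
#' @return Named integer vector of the retained alleles, ordered by
#'   decreasing count then alphabetically. Length 1 means a normal column.
#' @examples
#' classify_column(c(A = 10, C = 4))        # A only: 0.4 < 0.5 discarded
#' classify_column(c(A = 10, C = 5))        # bubble: 0.5 retained
#' classify_column(c(A = 8, C = 8, G = 3))  # bubble A/C
#' @export
classify_column <- function(counts, min_rel_freq = 0.5) {
  stopifnot(length(counts) >= 1L, all(names(counts) %in% c("A", "C", "G", "T")))
  m <- max(counts)
  keep <- counts[counts >= min_rel_freq * m]
  keep <- keep[order(-keep, names(keep))]
  setNames(as.integer(keep), names(keep))
}

#' Build the PLR graph of one container
#'
#' Converts the container's column alignment into an ordered sequence of
#' normal nodes (maximal runs of single-nucleotide columns, carrying the
#' consensus aligned base — not the reference base) and bubble columns
#' (columns with two or more retained nucleotides after the
#' relative-frequency filter). Node order along the container defines the
#' graph's directed edges implicitly.
#'
#' @param container One row of the tibble from [build_containers()].
#' @param pileup Pileup tibble from [build_pileup()].
#' @param min_rel_freq Passed to [classify_column()].
#' @return An object of class `plr_graph`: a list with `container_id`,
#'   `ref_id`, `start`, `end`, `width`, `consensus` (character vector of
#'   length `width`; bubble offsets hold the most frequent allele),
#'   `bubbles` (tibble `offset`, `pos`, `alleles` list-column of named
#'   counts), and `normal_nodes` (tibble `start_offset`, `end_offset`,
#'   `seq`). Offsets are 1-based within the container.
#' @export
build_graph <- function(container, pileup, min_rel_freq = 0.5) {
  stopifnot(nrow(container) == 1L)
  cols <- pileup |>
    filter(.data$ref_id == container$ref_id,
           .data$pos >= container$start, .data$pos <= container$end) |>
    count(.data$pos, .data$base, name = "n") |>
    group_by(.data$pos) |>
    summarise(
      alleles = list(classify_column(setNames(.data$n, .data$base), min_rel_freq)),
      .groups = "drop"
    ) |>
    arrange(.data$pos)
  width <- container$end - container$start + 1L
  if (nrow(cols) != width || any(cols$pos != seq(container$start, container$end))) {
    abort(paste0(
      "container ", container$container_id,
      " is not contiguously covered by the supplied pileup"
    ))
  }
  n_alleles <- lengths(cols$alleles)
  consensus <- vapply(cols$alleles, function(a) names(a)[1], character(1))
  is_bubble <- n_alleles >= 2L
  bubbles <- tibble(
    offset = which(is_bubble),
    pos = cols$pos[is_bubble],
    alleles = cols$alleles[is_bubble]
  )
  normal_nodes <- tibble(
    start_offset = integer(), end_offset = integer(), seq = character()
  )
  if (any(!is_bubble)) {
    off <- which(!is_bubble)
    run <- cumsum(c(1L, diff(off) != 1L))
    normal_nodes <- tibble(offset = off, run = run) |>
      group_by(.data$run) |>
      summarise(
        start_offset = min(.data$offset), end_offset = max(.data$offset),
        .groups = "drop"
      ) |>
      mutate(seq = vapply(
        seq_len(n()),
        function(i) paste0(consensus[start_offset[i]:end_offset[i]], collapse = ""),
        character(1)
      )) |>
      select("start_offset", "end_offset", "seq")
  }
  structure(
    list(
      container_id = container$container_id,
      ref_id = container$ref_id,
      start = container$start,
      end = container$end,
      width = width,
      consensus = consensus,
      bubbles = bubbles,
      normal_nodes = normal_nodes
    ),
    class = "plr_graph"
  )
}

#' Build PLR graphs for every container
#'
#' @param containers Tibble from [build_containers()].
#' @param pileup Tibble from [build_pileup()].
#' @param min_rel_freq Passed to [classify_column()].
#' @return The `containers` tibble with two extra columns: `n_bubbles` and a
#'   `graph` list-column of [build_graph()] objects.
#' @export
build_graphs <- function(containers, pileup, min_rel_freq = 0.5) {
  graphs <- purrr::map(
    seq_len(nrow(containers)),
    function(i) build_graph(containers[i, ], pileup, min_rel_freq)
  )
  containers |>
    mutate(
      graph = graphs,
      n_bubbles = vapply(graphs, function(g) nrow(g$bubbles), integer(1))
    )
}

#' @export
print.plr_graph <- function(x, ...) {
  cat(
    "<plr_graph> ", x$container_id, ": ", x$ref_id, ":", x$start, "-", x$end,
    " (", x$width, " bp, ", nrow(x$normal_nodes), " normal node(s), ",
    nrow(x$bubbles), " bubble column(s))\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn build_graph Tidy a PLR graph into one row per node: `type`
#'   (`normal`/`bubble`), container offsets, genomic interval, and for
#'   bubbles the retained alleles as a compact string like `A:12/C:9`.
#' @param x A `plr_graph`.
#' @param ... Unused.
#' @export
tidy.plr_graph <- function(x, ...) {
  nn <- x$normal_nodes |>
    mutate(
      type = "normal",
      alleles = NA_character_,
      label = .data$seq
    ) |>
    select("type", "start_offset", "end_offset", "label", "alleles")
  bb <- x$bubbles |>
    mutate(
      type = "bubble",
      start_offset = .data$offset,
      end_offset = .data$offset,
      label = vapply(.data$alleles, function(a) paste(names(a), collapse = "/"), character(1)),
      alleles = vapply(
        .data$alleles,
        function(a) paste(paste0(names(a), ":", a), collapse = "/"),
        character(1)
      )
    ) |>
    select("type", "start_offset", "end_offset", "label", "alleles")
  bind_rows(nn, bb) |>
    arrange(.data$start_offset) |>
    mutate(
      container_id = x$container_id,
      ref_id = x$ref_id,
      start = x$start + .data$start_offset - 1L,
      end = x$start + .data$end_offset - 1L
    ) |>
    select(
      "container_id", "ref_id", "type", "start_offset", "end_offset",
      "start", "end", "label", "alleles"
    )
}

#' @describeIn build_graph Plot the node layout of a PLR graph: normal nodes
#'   as segments, bubble columns as points labelled with their alleles.
#' @param object A `plr_graph`.
#' @export
autoplot.plr_graph <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      data = d[d$type == "normal", ],
      ggplot2::aes(x = .data$start_offset, xend = .data$end_offset, y = 0, yend = 0),
      linewidth = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = d[d$type == "bubble", ],
      ggplot2::aes(x = .data$start_offset, y = 0),
      shape = 23, size = 3, fill = "orange"
    ) +
    ggplot2::geom_text(
      data = d[d$type == "bubble", ],
      ggplot2::aes(x = .data$start_offset, y = 0.12, label = .data$label),
      size = 3
    ) +
    ggplot2::scale_y_continuous(limits = c(-0.5, 0.5), breaks = NULL) +
    ggplot2::labs(
      x = paste0("offset in ", object$container_id, " (",
                 object$ref_id, ":", object$start, "-", object$end, ")"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
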