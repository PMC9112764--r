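#' Assemble PLR paths into sequences
#'
#' Walks one container left to right, copying normal-node bases and, at each
#' bubble column, the corresponding element of one bubble combination; a `-`
#' element (unlinked bubble) is rendered as `N`. One sequence is produced per
#' combination, so a container with no bubbles or no linking evidence yields
#' exactly one sequence. Each emitted sequence has the container's length:
#' exactly one bubble node enters the path at any bubble column.
#'
#' @param graph A `plr_graph` from [build_graph()].
#' @param combinations Tibble from [build_combinations()]; every `elements`
#'   string must have length equal to the graph's bubble count.
#' @return A tibble, one row per PLR: `ref_id`, `start`, `end` (1-based,
#'   inclusive), `container_id`, `path_index`, `sequence`,
#'   `n_variant_positions` (the container's bubble count `B`), `support`,
#'   and a `bubble_offsets` list-column (1-based offsets within the
#'   container).
#' @export
assemble_paths <- function(graph, combinations) {
  B <- nrow(graph$bubbles)
  if (nrow(combinations) == 0L) {
    abort("no combinations supplied; expected at least the all-'-' fallback")
  }
  if (any(nchar(combinations$elements) != B)) {
    abort(paste0(
      "combination length does not match bubble count (", B, ") in ",
      graph$container_id
    ))
  }
  offsets <- graph$bubbles$offset
  seqs <- vapply(seq_len(nrow(combinations)), function(k) {
    v <- graph$consensus
    if (B > 0L) {
      el <- strsplit(combinations$elements[k], "", fixed = TRUE)[[1]]
      el[el == "-"] <- "N"
      v[offsets] <- el
    }
    paste0(v, collapse = "")
  }, character(1))
  tibble(
    ref_id = graph$ref_id,
    start = graph$start,
    end = graph$end,
    container_id = graph$container_id,
    path_index = seq_len(nrow(combinations)),
    sequence = seqs,
    n_variant_positions = B,
    support = combinations$support,
    bubble_offsets = replicate(nrow(combinations), offsets, simplify = FALSE)
  )
}

#' Mask variant positions to produce N-PLRs
#'
#' For each container, collapses its variant-aware PLRs (V-PLRs) to a single
#' record with `N` at every bubble column and the shared normal bases
#' elsewhere. Used to quantify how much the resolved variant bases — rather
#' than mere read elongation — contribute downstream.
#'
#' @param plrs Tibble from [assemble_paths()] (possibly several containers),
#'   with its `bubble_offsets` list-column.
#' @return A tibble of the same shape, one row per container, `path_index`
#'   1, `support` summed over the collapsed V-PLRs.
#' @export
mask_to_nplr <- function(plrs) {
  if (nrow(plrs) == 0L) {
    return(plrs)
  }
  groups <- plrs |>
    group_by(.data$ref_id, .data$container_id, .data$start, .data$end) |>
    dplyr::group_split()
  purrr::map(groups, function(g) {
    if (length(unique(nchar(g$sequence))) != 1L) {
      abort(paste0("V-PLRs of ", g$container_id[1], " differ in length"))
    }
    offsets <- g$bubble_offsets[[1]]
    v <- strsplit(g$sequence[1], "", fixed = TRUE)[[1]]
    if (length(offsets) > 0L) v[offsets] <- "N"
    g[1, ] |>
      mutate(
        path_index = 1L,
        sequence = paste0(v, collapse = ""),
        support = sum(g$support)
      )
  }) |>
    bind_rows() |>
    arrange(.data$ref_id, .data$start)
}

plr_headers <- function(plrs) {
  paste0(
    plrs$ref_id, ":", plrs$start, "-", plrs$end,
    "|plr", plrs$path_index,
    "|support=", plrs$support,
    "|vars=", plrs$n_variant_positions
  )
}

#' Write PLR sequences as FASTA
#'
#' Records are named `<ref_id>:<start>-<end>|plr<path_index>|support=<s>|vars=<n>`
#' with a 1-based inclusive interval.
#'
#' @param plrs Tibble from [assemble_paths()] or [mask_to_nplr()].
#' @param path Output path.
#' @param line_width Sequence line wrap width (default 70).
#' @param drop_n Drop PLRs containing any `N` before writing (default FALSE;
#'   unresolved bubbles are normally emitted as `N`).
#' @return `path`, invisibly.
#' @export
write_plr_fasta <- function(plrs, path, line_width = 70, drop_n = FALSE) {
  if (drop_n && nrow(plrs) > 0L) {
    plrs <- filter(plrs, !grepl("N", .data$sequence, fixed = TRUE))
  }
  if (nrow(plrs) == 0L) {
    warn(paste0("no PLR sequences to write; '", path, "' will be an empty FASTA"))
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(plrs$sequence)
  names(x) <- plr_headers(plrs)
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Per-PLR manifest table
#'
#' @param plrs Tibble from [assemble_paths()] or [mask_to_nplr()].
#' @return A tibble with one row per PLR: `ref_id`, `start`, `end`,
#'   `container_id`, `path_index`, `length`, `n_variant_positions`,
#'   `support`.
#' @export
plr_manifest <- function(plrs) {
  plrs |>
    mutate(length = nchar(.data$sequence)) |>
    select(
      "ref_id", "start", "end", "container_id", "path_index",
      "length", "n_variant_positions", "support"
    )
}

#' N50 of a set of sequence lengths
#'
#' The length `L` such that sequences of length at least `L` together cover
#' half of the total length.
#'
#' @param lengths Numeric vector of sequence lengths.
#' @return The N50, or `NA` for an empty input.
#' @examples
#' n50(c(2, 2, 2, 3, 3))  # 3
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) {
    return(NA_real_)
  }
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
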