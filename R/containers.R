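#' Break references into PLR containers at coverage gaps
#'
#' A PLR container is a maximal run of consecutive reference positions each
#' covered by at least one filtered base call; a single uncovered position
#' breaks the reference. Containers shorter than `min_container_len` are
#' discarded (strictly shorter: a container exactly at the cutoff survives).
#'
#' @param pileup Tibble from [build_pileup()] (any tibble with `ref_id` and
#'   `pos` columns works).
#' @param min_container_len Minimum retained container length in bp
#'   (default 100).
#' @return A tibble `container_id`, `ref_id`, `start`, `end` (1-based,
#'   inclusive), `width`, sorted by `(ref_id, start)`.
#' @export
build_containers <- function(pileup, min_container_len = 100) {
  empty <- tibble(
    container_id = character(), ref_id = character(),
    start = integer(), end = integer(), width = integer()
  )
  if (nrow(pileup) == 0L) {
    return(empty)
  }
  runs <- pileup |>
    distinct(.data$ref_id, .data$pos) |>
    arrange(.data$ref_id, .data$pos) |>
    group_by(.data$ref_id) |>
    mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) |>
    group_by(.data$ref_id, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos), .groups = "drop") |>
    mutate(width = .data$end - .data$start + 1L) |>
    filter(.data$width >= min_container_len) |>
    arrange(.data$ref_id, .data$start)
  if (nrow(runs) == 0L) {
    return(empty)
  }
  runs |>
    mutate(container_id = paste0("container_", row_number())) |>
    select("container_id", "ref_id", "start", "end", "width")
}

#' Write container intervals as BED
#'
#' Standard BED: 0-based half-open intervals, columns chrom / chromStart /
#' chromEnd / name.
#'
#' @param containers Tibble from [build_containers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_containers_bed <- function(containers, path) {
  bed <- containers |>
    mutate(bed_start = .data$start - 1L) |>
    select("ref_id", "bed_start", "end", "container_id")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
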