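#' Extract bubble vectors from bubble-linking fragments
#'
#' A bubble-linking fragment spans two or more bubble columns of a
#' container's graph (for paired-end data the whole DNA fragment defined by
#' the two mates is one linking unit). Each linking fragment is represented
#' as a vector over the container's `B` bubble columns with elements in
#' `{A, C, G, T, -}`: its retained allele where it covers a bubble column,
#' `-` where it does not (or where it carries a filtered-out low-frequency or
#' non-ACGT call). Identical vectors are collapsed with summed multiplicity.
#'
#' @param graph A `plr_graph` from [build_graph()].
#' @param pileup Pileup tibble from [build_pileup()] (per-fragment calls).
#' @return A tibble `elements` (string of length `B`), `multiplicity`,
#'   `first_bubble` (index of the first informative bubble column), sorted
#'   by `(first_bubble, -multiplicity, elements)`. Empty when `B < 2` or no
#'   fragment links two bubbles.
#' @export
extract_bubble_vectors <- function(graph, pileup) {
  empty <- tibble(
    elements = character(), multiplicity = integer(), first_bubble = integer()
  )
  B <- nrow(graph$bubbles)
  if (B < 2L) {
    return(empty)
  }
  bj <- tibble(
    pos = graph$bubbles$pos,
    j = seq_len(B),
    retained = purrr::map(graph$bubbles$alleles, names)
  )
  sub <- pileup |>
    filter(.data$ref_id == graph$ref_id, .data$pos %in% bj$pos) |>
    left_join(bj, by = "pos") |>
    filter(mapply(function(b, r) b %in% r, .data$base, .data$retained))
  if (nrow(sub) == 0L) {
    return(empty)
  }
  vecs <- sub |>
    group_by(.data$fragment_id) |>
    summarise(
      n_informative = n(),
      elements = {
        v <- rep("-", B)
        v[j] <- base
        paste0(v, collapse = "")
      },
      .groups = "drop"
    ) |>
    filter(.data$n_informative >= 2L)
  if (nrow(vecs) == 0L) {
    return(empty)
  }
  vecs |>
    count(.data$elements, name = "multiplicity") |>
    mutate(first_bubble = as.integer(regexpr("[ACGT]", .data$elements))) |>
    arrange(.data$first_bubble, desc(.data$multiplicity), .data$elements) |>
    select("elements", "multiplicity", "first_bubble")
}

#' Consistency distance between two bubble vectors
#'
#' Sums, over bubble positions where both vectors are informative (neither is
#' `-`), an indicator of disagreement. Two vectors sharing no informative
#' position have no defined distance; a fixed sentinel larger than 1 —
#' `B + 1`, where `B` is the vector length — is returned so such pairs can
#' never be merged at a distance cutoff of 0.
#'
#' @param v1,v2 Strings of equal length over `A/C/G/T/-`.
#' @return A non-negative number; `nchar(v1) + 1` signals a non-comparable
#'   pair (see [vectors_comparable()]).
#' @examples
#' vector_distance("TA--", "TA--")  # 0
#' vector_distance("TA--", "CA--")  # 1
#' vector_distance("TA--", "--TT")  # 5 = B + 1, non-comparable
#' @export
vector_distance <- function(v1, v2) {
  if (nchar(v1) != nchar(v2)) {
    abort("bubble vectors have different lengths")
  }
  a <- strsplit(v1, "", fixed = TRUE)[[1]]
  b <- strsplit(v2, "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) {
    return(nchar(v1) + 1L)
  }
  sum(a[both] != b[both])
}

#' @rdname vector_distance
#' @return `vectors_comparable()`: `TRUE` iff the two vectors share at least
#'   one informative position.
#' @export
vectors_comparable <- function(v1, v2) {
  if (nchar(v1) != nchar(v2)) {
    abort("bubble vectors have different lengths")
  }
  a <- strsplit(v1, "", fixed = TRUE)[[1]]
  b <- strsplit(v2, "", fixed = TRUE)[[1]]
  any(a != "-" & b != "-")
}

#' Cluster bubble vectors at distance cutoff 0
#'
#' Single-linkage agglomerative clustering of bubble vectors under the
#' consistency distance, cut at 0. At that cutoff agglomeration merges
#' exactly the pairs at distance 0 and their transitive closure, i.e. the
#' connected components of the zero-distance graph; the implementation uses
#' union-find over those edges, which is deterministic and fast. Identical
#' vectors are collapsed (summed multiplicity) first; this cannot change the
#' components.
#'
#' Cluster numbering is deterministic: clusters are ordered by the minimum
#' first-bubble position of their members, ties broken by descending support
#' (total multiplicity) then by the lexicographically smallest member.
#'
#' @param vectors Tibble with an `elements` column (equal-length strings over
#'   `A/C/G/T/-`); optional `multiplicity` (default 1).
#' @return The collapsed tibble with columns `elements`, `multiplicity`,
#'   `first_bubble` and `cluster` (integer, 1-based), rows ordered by
#'   `(cluster, first_bubble, -multiplicity, elements)`.
#' @export
cluster_vectors <- function(vectors) {
  empty <- tibble(
    elements = character(), multiplicity = integer(),
    first_bubble = integer(), cluster = integer()
  )
  if (nrow(vectors) == 0L) {
    return(empty)
  }
  if (!"multiplicity" %in% names(vectors)) {
    vectors$multiplicity <- 1L
  }
  v <- vectors |>
    group_by(.data$elements) |>
    summarise(multiplicity = sum(.data$multiplicity), .groups = "drop") |>
    mutate(first_bubble = as.integer(regexpr("[ACGT]", .data$elements))) |>
    arrange(.data$first_bubble, desc(.data$multiplicity), .data$elements)
  if (length(unique(nchar(v$elements))) != 1L) {
    abort("bubble vectors have different lengths")
  }
  n <- nrow(v)
  mat <- matrix(
    unlist(strsplit(v$elements, "", fixed = TRUE), use.names = FALSE),
    nrow = n, byrow = TRUE
  )
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    inf <- mat != "-"
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        shared <- inf[i, ] & inf[j, ]
        if (any(shared) && all(mat[i, shared] == mat[j, shared])) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  key <- v |>
    mutate(root = root) |>
    group_by(.data$root) |>
    summarise(
      min_fb = min(.data$first_bubble),
      support = sum(.data$multiplicity),
      lex = min(.data$elements),
      .groups = "drop"
    ) |>
    arrange(.data$min_fb, desc(.data$support), .data$lex) |>
    mutate(cluster = row_number())
  v |>
    mutate(root = root) |>
    left_join(select(key, "root", "cluster"), by = "root") |>
    select(-"root") |>
    arrange(.data$cluster, .data$first_bubble, desc(.data$multiplicity), .data$elements)
}

#' Build one bubble combination per cluster
#'
#' Integrates each cluster's vectors into a consensus allele assignment over
#' all `B` bubble columns: at each position the common informative element of
#' the member vectors, or `-` where no member informs that column (a bubble
#' that no linking fragment ties to another bubble stays `-` in every
#' combination and is later rendered as `N`). With no linking vectors at all,
#' or with `B < 2`, a single all-`-` combination is returned so the container
#' still yields one sequence.
#'
#' Clusters produced at distance cutoff 0 are expected to be conflict-free;
#' a transitive conflict (members disagreeing at a shared position despite
#' pairwise zero distances through intermediates) is resolved by
#' multiplicity-weighted majority, ties to the alphabetically smallest base,
#' and flagged in the `conflict` column with a warning.
#'
#' @param clustered Tibble from [cluster_vectors()].
#' @param B Number of bubble columns in the container's graph.
#' @param context Optional string (e.g. a container id) used in conflict
#'   warnings.
#' @return A tibble `cluster`, `elements` (string of length `B`), `support`
#'   (total multiplicity; 0 for the no-evidence fallback), `conflict`
#'   (logical), ordered by `cluster`.
#' @export
build_combinations <- function(clustered, B, context = NULL) {
  fallback <- tibble(
    cluster = 1L,
    elements = strrep("-", B),
    support = 0L,
    conflict = FALSE
  )
  if (B < 2L || nrow(clustered) == 0L) {
    return(fallback)
  }
  if (unique(nchar(clustered$elements))[1] != B) {
    abort("bubble vector length does not match the number of bubble columns")
  }
  groups <- clustered |>
    arrange(.data$cluster, .data$first_bubble, desc(.data$multiplicity), .data$elements) |>
    group_by(.data$cluster) |>
    dplyr::group_split()
  out <- purrr::map(groups, function(g) {
    m <- matrix(
      unlist(strsplit(g$elements, "", fixed = TRUE), use.names = FALSE),
      ncol = B, byrow = TRUE
    )
    cons <- character(B)
    conflict <- FALSE
    for (p in seq_len(B)) {
      col <- m[, p]
      ok <- col != "-"
      if (!any(ok)) {
        cons[p] <- "-"
        next
      }
      if (length(unique(col[ok])) > 1L) conflict <- TRUE
      tab <- tapply(g$multiplicity[ok], col[ok], sum)
      cons[p] <- names(tab)[order(-tab, names(tab))][1]
    }
    tibble(
      cluster = g$cluster[1],
      elements = paste0(cons, collapse = ""),
      support = sum(g$multiplicity),
      conflict = conflict
    )
  }) |>
    bind_rows() |>
    arrange(.data$cluster)
  if (any(out$conflict)) {
    warn(paste0(
      "transitive conflict within cluster(s) ",
      paste(out$cluster[out$conflict], collapse = ", "),
      if (!is.null(context)) paste0(" of ", context) else "",
      "; resolved by multiplicity-weighted majority"
    ))
  }
  out
}
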