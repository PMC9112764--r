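wx_graph_and_pileup <- function() {
  wx <- worked_example()
  pu <- build_pileup(wx$aln, wx$refs)
  cont <- build_containers(pu, min_container_len = 1)
  list(wx = wx, pu = pu, g = build_graph(cont, pu))
}

test_that("bubble vectors capture each linking fragment's alleles, '-' elsewhere", {
  f <- wx_graph_and_pileup()
  vec <- extract_bubble_vectors(f$g, f$pu)
  expect_setequal(vec$elements, f$wx$vectors)
  expect_true(all(vec$multiplicity == 1L))
  expect_equal(vec$first_bubble[1], 1L)
})

test_that("fragments informative at fewer than two bubbles are excluded, mates act as one unit", {
  refs <- c(r1 = strrep("A", 12))
  # two haplotype backbones create bubbles at positions 3 and 9
  backbone <- dplyr::bind_rows(
    aln_row("h1a", "r1", 1, "AATAAAAACAAA"),
    aln_row("h1b", "r1", 1, "AATAAAAACAAA"),
    aln_row("h2a", "r1", 1, "AAGAAAAATAAA"),
    aln_row("h2b", "r1", 1, "AAGAAAAATAAA"),
    # one-bubble fragment: informative at position 3 only
    aln_row("single", "r1", 1, "AATAA"),
    # paired fragment: mate 1 covers bubble 3, mate 2 covers bubble 9
    aln_row("pair", "r1", 2, "ATAA", flag = 99),
    aln_row("pair", "r1", 8, "ACA", flag = 147)
  )
  pu <- build_pileup(backbone, refs)
  g <- build_graph(build_containers(pu, min_container_len = 1), pu)
  expect_equal(g$bubbles$pos, c(3L, 9L))
  vec <- extract_bubble_vectors(g, pu)
  # the paired fragment acts as one unit and collapses with the h1 vectors;
  # "single" is informative at one bubble and contributes nothing
  expect_setequal(vec$elements, c("TC", "GT"))
  expect_equal(sum(vec$multiplicity), 5L)
  expect_equal(vec$multiplicity[vec$elements == "TC"], 3L)
})

test_that("the consistency distance counts disagreements over shared informative positions", {
  expect_equal(vector_distance("TA--", "TA--"), 0)
  expect_equal(vector_distance("TA--", "CA--"), 1)
  expect_equal(vector_distance("TA--", "--TT"), 5)  # B + 1 sentinel
  expect_false(vectors_comparable("TA--", "--TT"))
  expect_error(vector_distance("TA-", "TA--"), "length")
  # symmetry and identity over random pairs
  set.seed(41)
  for (i in 1:30) {
    v <- random_vector_set(2, 6)$elements
    expect_equal(vector_distance(v[1], v[2]), vector_distance(v[2], v[1]))
    expect_equal(vector_distance(v[1], v[1]), 0)
    expect_equal(
      vectors_comparable(v[1], v[2]),
      vectors_comparable(v[2], v[1])
    )
  }
})

test_that("clustering at cutoff 0 merges zero-distance pairs and their closure only", {
  # identical vectors: one cluster
  out <- cluster_vectors(tibble::tibble(elements = c("TA--", "TA--")))
  expect_equal(nrow(out), 1L)
  expect_equal(out$multiplicity, 2L)
  # distance 1: separate clusters
  out2 <- cluster_vectors(tibble::tibble(elements = c("TA--", "CA--")))
  expect_equal(out2$cluster, c(1L, 2L))
  # worked example: eight vectors, two clusters
  wx <- worked_example()
  out3 <- cluster_vectors(tibble::tibble(elements = wx$vectors))
  expect_equal(max(out3$cluster), 2L)
  expect_equal(sum(out3$multiplicity), 8L)
})

test_that("clustering matches the brute-force oracle and ignores input order", {
  set.seed(42)
  for (i in 1:20) {
    B <- sample(2:8, 1)
    n <- sample(5:50, 1)
    vs <- random_vector_set(n, B)
    out <- cluster_vectors(vs)
    # oracle works on the collapsed distinct vectors
    oracle <- oracle_membership(out$elements)
    expect_true(same_partition(out$cluster, oracle))
    # conservation: nothing dropped or duplicated
    expect_equal(sum(out$multiplicity), n)
    # permutation invariance of the full output
    out_perm <- cluster_vectors(vs[sample.int(n), , drop = FALSE])
    expect_identical(out, out_perm)
  }
})

test_that("combinations integrate chained vectors and leave unlinked bubbles as '-'", {
  cl <- cluster_vectors(tibble::tibble(elements = c("TA--", "-AC-", "--CG")))
  expect_equal(max(cl$cluster), 1L)
  comb <- build_combinations(cl, B = 4)
  expect_equal(comb$elements, "TACG")
  expect_equal(comb$support, 3L)
  expect_false(comb$conflict)

  # bubbles 3 and 4 linked by no vector anywhere stay '-'
  cl2 <- cluster_vectors(tibble::tibble(elements = "TA--"))
  expect_equal(build_combinations(cl2, B = 4)$elements, "TA--")

  # a single isolated bubble, or no linking evidence at all
  expect_equal(build_combinations(cluster_vectors(tibble::tibble(elements = character())), B = 1)$elements, "-")
  expect_equal(build_combinations(cluster_vectors(tibble::tibble(elements = character())), B = 4)$elements, "----")
})

test_that("transitive conflicts are flagged and resolved by weighted majority", {
  vs <- tibble::tibble(
    elements = c("A-C", "AG-", "-GT"),
    multiplicity = c(2L, 1L, 1L)
  )
  cl <- cluster_vectors(vs)
  expect_equal(max(cl$cluster), 1L)  # chained through shared positions
  expect_warning(comb <- build_combinations(cl, B = 3, context = "container_9"),
                 "container_9")
  expect_true(comb$conflict)
  # position 3: C (weight 2) beats T (weight 1)
  expect_equal(comb$elements, "AGC")
})
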