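pair_tbl <- function(strict, perm, gene = "cas9") {
  tibble::tibble(locus_id = sprintf("l%d", seq_along(strict)),
                 cas1_strict_cluster = strict,
                 effector_gene = rep_len(gene, length(strict)),
                 effector_permissive_cluster = perm,
                 hybrid = FALSE)
}

test_that("greedy incremental clustering follows the representative rule", {
  lens <- tibble::tibble(protein_id = c("A", "B", "C"),
                         length = c(300L, 250L, 200L))
  pairs <- tibble::tibble(p1 = c("A", "A", "B"), p2 = c("B", "C", "C"),
                          identity = c(0.95, 0.4, 0.4),
                          cov1 = 1, cov2 = 1)
  strict <- greedy_cluster(pairs, lens, 0.9, 0.9)
  expect_equal(strict$cluster_id[strict$protein_id %in% c("A", "B")],
               c("A", "A"))
  expect_equal(strict$cluster_id[strict$protein_id == "C"], "C")
  # at the permissive level everything is below threshold except A-B
  perm <- greedy_cluster(pairs, lens, 0.5, 0.33)
  expect_equal(sort(unique(perm$cluster_id)), c("A", "C"))
  expect_error(greedy_cluster(dplyr::mutate(pairs, identity = 1.5),
                              lens, 0.9, 0.9), "identity")
  empty <- greedy_cluster(pairs[0, ], lens[0, ], 0.9, 0.9)
  expect_equal(nrow(empty), 0L)
})

test_that("clustering is deterministic and matches a hand partition", {
  # six proteins, two tight trios bridged by one weak link
  lens <- tibble::tibble(protein_id = sprintf("P%d", 1:6),
                         length = c(500L, 480L, 460L, 440L, 420L, 400L))
  pairs <- tibble::tibble(
    p1 = c("P1", "P1", "P2", "P4", "P4", "P5", "P3"),
    p2 = c("P2", "P3", "P3", "P5", "P6", "P6", "P4"),
    identity = c(0.95, 0.93, 0.94, 0.96, 0.92, 0.95, 0.55),
    cov1 = 0.95, cov2 = 0.95
  )
  got <- greedy_cluster(pairs, lens, 0.9, 0.9)
  expect_equal(stats::setNames(got$cluster_id, got$protein_id),
               c(P1 = "P1", P2 = "P1", P3 = "P1",
                 P4 = "P4", P5 = "P4", P6 = "P4"))
  # row order of the pair table is irrelevant
  got2 <- greedy_cluster(pairs[sample(nrow(pairs)), ], lens, 0.9, 0.9)
  expect_equal(got2, got)
  # coverage is measured on the representative
  pairs2 <- tibble::tibble(p1 = "P9", p2 = "P1", identity = 0.95,
                           cov1 = 0.95, cov2 = 0.2)
  lens2 <- tibble::tibble(protein_id = c("P1", "P9"),
                          length = c(500L, 100L))
  got3 <- greedy_cluster(pairs2, lens2, 0.9, 0.9)
  expect_equal(sort(unique(got3$cluster_id)), c("P1", "P9"))
})

test_that("module pairs require both cas1 and an effector in the locus", {
  mk_locus <- function(id, fams) {
    tibble::tibble(locus_id = id, hits = list(tibble::tibble(
      protein_id = paste0(id, "_", seq_along(fams)), family = fams)))
  }
  loci <- dplyr::bind_rows(
    mk_locus("l1", c("cas1", "cas9")),
    mk_locus("l2", "cas1"),
    mk_locus("l3", c("cas1", "cas10", "cas12a"))
  )
  prot <- unlist(lapply(loci$hits, function(h) h$protein_id))
  strict <- tibble::tibble(protein_id = prot, cluster_id = "S1")
  perm <- tibble::tibble(protein_id = prot,
                         cluster_id = paste0("P_", prot))
  res <- extract_module_pairs(loci, strict, perm)
  expect_equal(res$n_skipped, 1L)
  expect_equal(nrow(res$pairs), 3L)
  l3 <- res$pairs[res$pairs$locus_id == "l3", ]
  expect_equal(sort(l3$effector_gene), c("cas10", "cas12"))
  expect_true(all(l3$hybrid))
  expect_false(any(res$pairs$hybrid[res$pairs$locus_id == "l1"]))
})

test_that("swap counting is the distinct-cluster spanning estimate", {
  expect_equal(count_module_swaps(
    pair_tbl(c("X", "X", "Y"), c("P", "Q", "P")))$n_events, 1L)
  expect_equal(count_module_swaps(
    pair_tbl(c("X", "Y", "Z"), c("P", "P", "P")))$n_events, 0L)
  expect_equal(count_module_swaps(pair_tbl("X", "P"))$n_events, 0L)
  expect_equal(count_module_swaps(pair_tbl("X", "P")[0, ])$n_events, 0L)
})

test_that("swap counts match exhaustive enumeration and are monotone", {
  for (seed in 1:30) {
    p <- random_pair_set(withr::with_seed(seed, sample(1:20, 1)), seed)
    got <- count_module_swaps(p)$n_events
    expect_equal(got, oracle_swaps(p))
    extra <- random_pair_set(1, seed + 500)
    expect_gte(count_module_swaps(rbind(p, extra))$n_events, got)
  }
})
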