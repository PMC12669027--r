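make_census <- function(weights, subtype, complete = TRUE,
                        taxon = "taxA") {
  gid <- names(weights)
  genomes <- tibble::tibble(genome_id = gid,
                            taxon = rep_len(taxon, length(gid)))
  loci <- tibble::tibble(genome_id = rep(gid, lengths(subtype)),
                         subtype = unlist(subtype),
                         cas_type = subtype_id_type(unlist(subtype)),
                         complete = rep_len(complete,
                                            sum(lengths(subtype))))
  list(genomes = genomes, loci = loci)
}

test_that("branch-proportional weights reproduce hand-computed cases", {
  star <- simulate_tree(4, "star")
  expect_equal(unname(compute_weights(star)), rep(0.25, 4))
  single <- simulate_tree(1)
  expect_equal(compute_weights(single), c(g001 = 1))
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(compute_weights(tr), c(A = 0.3, B = 0.3, C = 0.4))
  bad <- tr
  bad$edge.length[1] <- -1
  expect_error(compute_weights(bad), "negative")
})

test_that("weights sum to one and match the clade-extraction oracle", {
  for (seed in 1:20) {
    tr <- simulate_tree(withr::with_seed(seed, sample(3:25, 1)),
                        "coalescent", seed = seed)
    w <- compute_weights(tr)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
    expect_equal(w[order(names(w))], oracle_gsc(tr)[order(names(w))],
                 tolerance = 1e-12)
  }
})

test_that("a zero-length duplicate splits a leaf weight in half", {
  # star tree: duplicating D as a zero-length cherry halves its weight
  # and leaves every other genome's weight untouched
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  dup <- ape::read.tree(text = "(A:1,B:1,C:1,(D:0,D2:0):1);")
  w <- compute_weights(tr)
  w2 <- compute_weights(dup)
  expect_equal(w2[["D"]], w[["D"]] / 2)
  expect_equal(w2[["D2"]], w2[["D"]])
  expect_equal(w2[c("A", "B", "C")], w[c("A", "B", "C")])
  expect_equal(sum(w2), 1, tolerance = 1e-9)
})

test_that("weighted prevalence follows the genome-weight arithmetic", {
  w <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  cen <- make_census(w, list("I-B", "III-A", character(0)))
  prev <- weighted_prevalence(cen$genomes, cen$loci, w)
  expect_equal(prev$prevalence, 0.8)
  # all carriers / no carriers
  all_c <- make_census(w, list("I-B", "I-B", "I-B"))
  expect_equal(weighted_prevalence(all_c$genomes, all_c$loci,
                                   w)$prevalence, 1)
  none <- make_census(w, list(character(0), character(0), character(0)))
  expect_equal(weighted_prevalence(none$genomes, none$loci,
                                   w)$prevalence, 0)
})

test_that("uniform weights reduce weighted prevalence to counting", {
  for (seed in 1:5) {
    n <- 30
    gid <- sprintf("g%02d", 1:n)
    carrier <- withr::with_seed(seed, stats::runif(n) < 0.4)
    w <- stats::setNames(rep(1 / n, n), gid)
    cen <- make_census(w, lapply(carrier, function(cc)
      if (cc) "I-B" else character(0)))
    prev <- weighted_prevalence(cen$genomes, cen$loci, w)
    expect_equal(prev$prevalence, mean(carrier), tolerance = 1e-12)
  }
})

test_that("subtype fractions are locus-weighted and row-normalised", {
  w <- c(g1 = 0.6, g2 = 0.4)
  cen <- make_census(w, list("I-B", "III-A"))
  M <- subtype_fraction_matrix(cen$genomes, cen$loci, w)
  expect_equal(M["taxA", "I-B"], 0.6)
  expect_equal(M["taxA", "III-A"], 0.4)
  expect_equal(unname(rowSums(M)), 1)
  # two same-subtype loci in one genome both count
  cen2 <- make_census(c(g1 = 0.5, g2 = 0.5),
                      list(c("I-B", "I-B"), "III-A"))
  M2 <- subtype_fraction_matrix(cen2$genomes, cen2$loci,
                                c(g1 = 0.5, g2 = 0.5))
  expect_equal(M2["taxA", "I-B"], 1 / 1.5)
  # incomplete loci are excluded
  cen3 <- make_census(w, list("I-B", "III-A"),
                      complete = c(TRUE, FALSE))
  M3 <- subtype_fraction_matrix(cen3$genomes, cen3$loci, w)
  expect_equal(colnames(M3), "I-B")
  expect_equal(unname(M3[1, 1]), 1)
})

test_that("census statistics ignore row order", {
  w <- c(g1 = 0.2, g2 = 0.3, g3 = 0.5)
  cen <- make_census(w, list("I-B", "V-A", character(0)),
                     taxon = c("tA", "tA", "tB"))
  p1 <- weighted_prevalence(cen$genomes, cen$loci, w)
  perm <- c(3, 1, 2)
  p2 <- weighted_prevalence(cen$genomes[perm, ],
                            cen$loci[rev(seq_len(nrow(cen$loci))), ], w)
  expect_equal(p2[order(p2$group), ], p1[order(p1$group), ])
  M1 <- subtype_fraction_matrix(cen$genomes, cen$loci, w)
  M2 <- subtype_fraction_matrix(cen$genomes[perm, ], cen$loci, w)
  expect_equal(M2, M1)
})

test_that("temperature classes partition prevalence as planted", {
  n <- 40
  gid <- sprintf("g%03d", 1:n)
  ogt <- rep(c(10, 30, 60, 95), each = 10)
  carrier <- rep(c(FALSE, TRUE), 20)
  genomes <- tibble::tibble(genome_id = gid, taxon = "t", ogt = ogt)
  genomes$ogt[1] <- NA  # one genome without a known OGT
  loci <- tibble::tibble(genome_id = gid[carrier], subtype = "I-B",
                         cas_type = "I", complete = TRUE)
  tree <- simulate_tree(n, "star", labels = gid)
  res <- suppressMessages(
    prevalence_by_temperature(genomes, loci, tree))
  expect_equal(res$n_excluded, 1L)
  prev <- res$prevalence
  expect_setequal(prev$group, c("psychrophile", "mesophile",
                                "thermophile", "hyperthermophile"))
  expect_equal(prev$prevalence[prev$group == "thermophile"], 0.5)
  expect_equal(prev$prevalence[prev$group == "psychrophile"], 5 / 9)
})
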