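simmat <- function(vals, labs) {
  matrix(vals, length(labs), length(labs), dimnames = list(labs, labs))
}

test_that("the negative-log relative-score transform is exact", {
  S <- simmat(c(100, 50, 50, 80), c("A", "B"))
  D <- to_distance(S)
  expect_equal(D["A", "B"], -log(50 / 80), tolerance = 1e-12)
  expect_equal(D["A", "B"], 0.4700, tolerance = 1e-4)
  expect_equal(diag(D), c(A = 0, B = 0))
  # a score equal to the smaller self-score is distance zero
  S2 <- simmat(c(100, 80, 80, 80), c("A", "B"))
  expect_equal(to_distance(S2)["A", "B"], 0)
  # non-positive cross-scores hit the clamp ceiling
  S3 <- simmat(c(100, -5, -5, 80), c("A", "B"))
  expect_equal(to_distance(S3)["A", "B"], -log(1e-9))
  # non-positive self-scores are an input error
  S4 <- simmat(c(0, 5, 5, 80), c("A", "B"))
  expect_error(to_distance(S4), "self-score")
})

test_that("the distance transform is monotone in the cross-score", {
  for (seed in 1:20) {
    s <- withr::with_seed(seed, stats::runif(3, 1, 120))
    S <- simmat(c(100, s[1], s[1], 90), c("A", "B"))
    S2 <- S
    S2["A", "B"] <- S2["B", "A"] <- s[1] + 10
    expect_lte(to_distance(S2)["A", "B"], to_distance(S)["A", "B"])
  }
})

test_that("UPGMA agglomerates known cases exactly", {
  D2 <- simmat(c(0, 4, 4, 0), c("A", "B"))
  d2 <- upgma(D2)
  expect_equal(d2$height, 2)
  D3 <- simmat(c(0, 2, 8, 2, 0, 8, 8, 8, 0), c("A", "B", "C"))
  d3 <- upgma(D3)
  expect_equal(d3$height, c(1, 4))
  expect_equal(d3$merge[1, ], c(-2L, -1L))
  expect_error(upgma(D3[1, 1, drop = FALSE]), "two leaves")
})

test_that("all-equal distances give a caterpillar under the tie rule", {
  labs <- c("A", "B", "C", "D")
  D <- simmat(rep(2, 16), labs)
  diag(D) <- 0
  d <- upgma(D)
  expect_equal(d$height, c(1, 1, 1))
  # leaves join in label order: (A,B), then +C, then +D
  expect_equal(d$merge, rbind(c(-2L, -1L), c(-3L, 1L), c(-4L, 2L)))
})

test_that("UPGMA matches naive agglomeration and hclust on random input", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(3:8, 1))
    D <- random_distance_matrix(n, seed + 1000)
    d <- upgma(D)
    expect_equal(cophenetic_heights(d), oracle_upgma_coph(D),
                 tolerance = 1e-9)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(2 * d$height), sort(hc$height), tolerance = 1e-9)
  }
})

test_that("depth cuts behave at the extremes and nest across depths", {
  D3 <- simmat(c(0, 2, 8, 2, 0, 8, 8, 8, 0), c("A", "B", "C"))
  d3 <- upgma(D3)
  expect_equal(max(cut_at_depth(d3, 0)), 3L)
  expect_equal(max(cut_at_depth(d3, max(d3$height))), 1L)
  expect_equal(unname(cut_at_depth(d3, 2)), c(1L, 1L, 2L))
  expect_error(cut_at_depth(d3, -1), "non-negative")
  for (seed in 1:10) {
    d <- upgma(random_distance_matrix(7, seed))
    depths <- sort(withr::with_seed(seed, stats::runif(2, 0, 1.5)))
    p1 <- cut_at_depth(d, depths[1])
    p2 <- cut_at_depth(d, depths[2])
    # finer partition refines the coarser one
    expect_true(all(tapply(p2, p1, function(x) length(unique(x))) == 1L))
  }
})

test_that("grafting conserves and never duplicates leaf labels", {
  backbone <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  sub <- ape::read.tree(text = "((w:1,x:1):1,(y:1,z:1):1);")
  out <- graft(backbone, list(A = sub))
  expect_equal(sort(out$tip.label), sort(c("w", "x", "y", "z", "B", "C")))
  expect_equal(length(out$tip.label),
               length(sub$tip.label) + 2L)  # subtree leaves + unmapped tips
  expect_identical(graft(backbone, list()), backbone)
  dup <- ape::read.tree(text = "(B:1,q:1);")
  expect_error(graft(backbone, list(A = dup)), "duplicate")
  expect_error(graft(backbone, list(Z = sub)), "unknown")
})

test_that("the merge loop enforces both acceptance constraints", {
  S <- simmat(c(100, 90, 10, 90, 95, 12, 10, 12, 88), c("a", "b", "c"))
  cl <- list(a = c("s1", "s2"), b = "s3", c = c("s4", "s5"))
  # boundary: retention must strictly exceed 0.98
  res <- nj_merge(cl, S, function(m) list(retention = 0.98, new_fp = 0))
  expect_length(res$clusters, 3L)
  expect_true(all(!res$log$accepted))
  # boundary: ten new false positives are still acceptable, eleven are not
  res10 <- nj_merge(cl, S, function(m) list(retention = 1, new_fp = 10))
  expect_length(res10$clusters, 1L)
  res11 <- nj_merge(cl, S, function(m) list(retention = 1, new_fp = 11))
  expect_length(res11$clusters, 3L)
  # single cluster input returns unchanged with an empty log
  one <- nj_merge(cl["a"], S["a", "a", drop = FALSE],
                  function(m) list(retention = 1, new_fp = 0))
  expect_equal(one$clusters, cl["a"])
  expect_equal(nrow(one$log), 0L)
})

test_that("merging is bounded, logged and order-invariant", {
  S <- simmat(c(100, 90, 10, 90, 95, 12, 10, 12, 88), c("a", "b", "c"))
  cl <- list(a = c("s1", "s2"), b = "s3", c = c("s4", "s5"))
  oracle <- function(m) list(retention = 1,
                             new_fp = if (length(m) > 4) 20L else 0L)
  res <- nj_merge(cl, S, oracle)
  expect_lte(sum(res$log$accepted), length(cl) - 1L)
  expect_true(all(res$log$retention[res$log$accepted] > 0.98))
  expect_true(all(res$log$new_fp[res$log$accepted] <= 10L))
  member_sets <- function(r) {
    unname(lapply(r$clusters, sort))[order(vapply(
      lapply(r$clusters, sort), paste, "", collapse = ","))]
  }
  perm <- c("c", "a", "b")
  res_p <- nj_merge(cl[perm], S[perm, perm], oracle)
  expect_equal(member_sets(res_p), member_sets(res))
})

test_that("planted similarity blocks are recovered by depth cutting", {
  ss <- simulate_similarity(3, 3, seed = 11)
  part <- cut_at_depth(upgma(to_distance(ss$S)), 0.8)
  expect_equal(max(part), 3L)
  expect_true(all(tapply(ss$partition, part,
                         function(x) length(unique(x))) == 1L))
})
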