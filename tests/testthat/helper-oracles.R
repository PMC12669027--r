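# Independent reference implementations used to check the package's
# operations. These deliberately recompute everything from first
# principles (original matrices, explicit scans) rather than sharing code
# with the implementation.

# UPGMA by naive agglomeration: at every step the average pairwise
# distance between member sets is recomputed from the ORIGINAL matrix.
# Returns the matrix of join heights (half merge distances).
oracle_upgma_coph <- function(D) {
  clusters <- as.list(rownames(D))
  coph <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d, lab = lab)
        }
      }
    }
    coph[clusters[[best$i]], clusters[[best$j]]] <- best$d / 2
    coph[clusters[[best$j]], clusters[[best$i]]] <- best$d / 2
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# Greedy best-scoring culling by explicit simulation: repeatedly take the
# top-ranked remaining hit and accept it iff compatible with everything
# accepted so far.
oracle_select_hits <- function(hits, tol = 0L) {
  remaining <- hits
  accepted <- hits[0, , drop = FALSE]
  while (nrow(remaining) > 0L) {
    len <- remaining$p_to - remaining$p_from + 1L
    k <- order(-remaining$score, remaining$evalue, -len,
               remaining$profile_id)[1]
    cand <- remaining[k, , drop = FALSE]
    remaining <- remaining[-k, , drop = FALSE]
    compat <- TRUE
    for (r in seq_len(nrow(accepted))) {
      ov <- min(cand$p_to, accepted$p_to[r]) -
        max(cand$p_from, accepted$p_from[r]) + 1L
      if (ov > tol) {
        compat <- FALSE
        break
      }
    }
    if (compat) accepted <- rbind(accepted, cand)
  }
  accepted[order(accepted$p_from, accepted$p_to, accepted$profile_id), ,
           drop = FALSE]
}

# Module-swap count by exhaustive enumeration of distinct co-occurrences.
oracle_swaps <- function(pairs) {
  total <- 0L
  for (x in unique(pairs$cas1_strict_cluster)) {
    effs <- character(0)
    for (k in seq_len(nrow(pairs))) {
      if (pairs$cas1_strict_cluster[k] == x) {
        effs <- union(effs, pairs$effector_permissive_cluster[k])
      }
    }
    total <- total + max(0L, length(effs) - 1L)
  }
  total
}

# Branch-proportional leaf weights via explicit clade extraction.
oracle_gsc <- function(tree) {
  n <- length(tree$tip.label)
  w <- stats::setNames(numeric(n), tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= n) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    w[tips] <- w[tips] + tree$edge.length[e] / length(tips)
  }
  w / sum(w)
}

random_distance_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    labs <- sprintf("L%02d", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    vals <- round(stats::runif(n * (n - 1) / 2, 0.1, 3), 3)
    D[upper.tri(D)] <- vals
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    D
  })
}

random_hit_set <- function(n, seed, protein = "p1") {
  withr::with_seed(seed, {
    f <- sample.int(300L, n, replace = TRUE)
    len <- sample(20:150, n, replace = TRUE)
    tibble::tibble(
      protein_id = protein,
      profile_id = sprintf("prof%03d", sample.int(999L, n)),
      evalue = 10^stats::runif(n, -20, -1),
      score = round(stats::runif(n, 20, 100), 1),
      q_cov = round(stats::runif(n), 3),
      p_from = f, p_to = f + len - 1L
    )
  })
}

random_pair_set <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    locus_id = sprintf("l%03d", seq_len(n)),
    cas1_strict_cluster = sample(sprintf("S%d", 1:5), n, replace = TRUE),
    effector_gene = sample(c("cas8", "cas9", "cas10", "cas12"), n,
                           replace = TRUE),
    effector_permissive_cluster = sample(sprintf("P%d", 1:6), n,
                                         replace = TRUE),
    hybrid = FALSE
  ))
}
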