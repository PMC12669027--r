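check_simmat <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || !is.numeric(S) || nrow(S) != ncol(S)) {
    stop("similarity matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(S))) stop("similarity matrix must be labelled",
                                 call. = FALSE)
  if (!identical(rownames(S), colnames(S))) {
    stop("similarity matrix row/column labels differ", call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(S) <= 0)) {
    stop("non-positive self-score on the diagonal", call. = FALSE)
  }
  invisible(S)
}

#' Convert profile similarity scores to distances
#'
#' Relative scores `S_AB / min(S_AA, S_BB)` are converted with the negative
#' log transformation: `d_AB = -ln(clamp(rel, eps, 1))`. Cross-scores can
#' exceed a self-score in practice, so relative scores above 1 are clamped
#' to 1 (distance 0) and non-positive scores are floored at `eps`
#' (distance `-ln(eps)`).
#'
#' @param S Symmetric labelled score matrix with positive self-scores on
#'   the diagonal.
#' @param eps Clamp floor for the relative score (default 1e-9).
#' @return Symmetric non-negative distance matrix with zero diagonal.
#' @examples
#' S <- matrix(c(100, 50, 50, 80), 2, 2, dimnames = list(c("A", "B"),
#'                                                       c("A", "B")))
#' to_distance(S)["A", "B"]  # -log(50/80) = 0.470
#' @export
to_distance <- function(S, eps = 1e-9) {
  check_simmat(S)
  self <- diag(S)
  denom <- outer(self, self, pmin)
  rel <- pmin(pmax(S / denom, eps), 1)
  D <- -log(rel)
  diag(D) <- 0
  dimnames(D) <- dimnames(S)
  D
}

check_distmat <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be a square numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(D))) stop("distance matrix must be labelled",
                                 call. = FALSE)
  if (any(D < 0)) stop("negative distance", call. = FALSE)
  if (any(abs(diag(D)) > tol)) stop("distance diagonal must be zero",
                                    call. = FALSE)
  invisible(D)
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration with a deterministic tie rule: when
#' several pairs are equally close, the pair whose (lexicographically
#' smallest member label, then second-smallest) sorts first is merged.
#' Node heights are half the merge distance, so the tree is ultrametric
#' with leaves at height 0.
#'
#' @param D Symmetric labelled distance matrix, `n >= 2`.
#' @return A `cas_dendrogram`: list with `merge` (hclust-style merge
#'   matrix), `height` (node heights, half merge distances), `labels`.
#' @export
upgma <- function(D) {
  check_distmat(D)
  n <- nrow(D)
  if (n < 2L) stop("UPGMA needs at least two leaves", call. = FALSE)
  labels <- rownames(D)
  active <- seq_len(n)
  # per active cluster: id for the merge matrix, size, smallest member label
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  minlab <- labels
  Dm <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        d <- Dm[a, b]
        lab <- sort(c(minlab[a], minlab[b]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(a = a, b = b, d = d, lab = lab)
        }
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(ids[a], ids[b]))
    height[step] <- best$d / 2
    # Lance-Williams update for average linkage
    new_row <- (sizes[a] * Dm[a, ] + sizes[b] * Dm[b, ]) /
      (sizes[a] + sizes[b])
    Dm[a, ] <- new_row
    Dm[, a] <- new_row
    Dm[a, a] <- 0
    ids[a] <- step
    sizes[a] <- sizes[a] + sizes[b]
    minlab[a] <- min(minlab[a], minlab[b])
    keep <- setdiff(seq_len(k), b)
    Dm <- Dm[keep, keep, drop = FALSE]
    ids <- ids[keep]; sizes <- sizes[keep]; minlab <- minlab[keep]
    active <- active[keep]
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "cas_dendrogram")
}

#' @export
print.cas_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram with", length(x$labels), "leaves; root height",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert a dendrogram to an hclust object
#'
#' hclust heights are merge distances (twice the ultrametric node height).
#'
#' @param x A `cas_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.cas_dendrogram <- function(x, ...) {
  hc <- list(merge = x$merge, height = 2 * x$height,
             order = dendro_leaf_order(x$merge, length(x$labels)),
             labels = x$labels, method = "average",
             call = match.call(), dist.method = "profile")
  class(hc) <- "hclust"
  hc
}

dendro_leaf_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Convert a dendrogram to an ape phylogeny
#' @param x A `cas_dendrogram`.
#' @return A rooted ultrametric `phylo` whose node depths equal the
#'   dendrogram's node heights.
#' @export
dendro_to_phylo <- function(x) {
  ape::as.phylo(as.hclust.cas_dendrogram(x))
}

#' Heights at which leaf pairs join
#' @param x A `cas_dendrogram`.
#' @return Symmetric matrix of join heights (ultrametric cophenetic
#'   heights).
#' @export
cophenetic_heights <- function(x) {
  as.matrix(stats::cophenetic(as.hclust.cas_dendrogram(x))) / 2
}

#' Cut a dendrogram at a node-height depth
#'
#' Clusters are the maximal subtrees whose root height does not exceed
#' `depth` (the profile-update pipeline uses 0.8). At depth 0 every leaf is
#' its own cluster; at or above the root height there is one cluster.
#' Partitions are nested in `depth`.
#'
#' @param dendro A `cas_dendrogram`.
#' @param depth Non-negative node-height threshold.
#' @return Named integer vector mapping leaf labels to cluster ids
#'   (numbered by first appearance in label order).
#' @export
cut_at_depth <- function(dendro, depth = 0.8) {
  if (depth < 0) stop("depth must be non-negative", call. = FALSE)
  n <- length(dendro$labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  node_members <- vector("list", nrow(dendro$merge))
  members_of <- function(id) {
    if (id < 0L) -id else node_members[[id]]
  }
  for (s in seq_len(nrow(dendro$merge))) {
    m <- c(members_of(dendro$merge[s, 1]), members_of(dendro$merge[s, 2]))
    node_members[[s]] <- m
    if (dendro$height[s] <= depth + 1e-12) {
      root <- find(m[1])
      for (i in m[-1]) parent[find(i)] <- root
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  ids <- match(comp, unique(comp))
  stats::setNames(ids, dendro$labels)
}

#' Graft subtrees onto dendrogram tips
#'
#' Builds a hybrid tree: each mapped backbone tip is replaced by a rooted
#' subtree (keeping the tip's branch length as the subtree's stem), while
#' unmapped tips are unchanged. Used to hang within-cluster phylogenies
#' from a profile-similarity backbone. Leaf labels must remain globally
#' unique.
#'
#' @param backbone A rooted `phylo` (e.g. from [dendro_to_phylo()]).
#' @param tip_subtrees Named list of `phylo` objects; names must be
#'   backbone tip labels.
#' @return A `phylo` with `sum(subtree leaves) + n unmapped tips` leaves.
#' @export
graft <- function(backbone, tip_subtrees) {
  stopifnot(inherits(backbone, "phylo"))
  if (length(tip_subtrees) == 0L) return(backbone)
  if (is.null(names(tip_subtrees)) || any(names(tip_subtrees) == "")) {
    stop("tip_subtrees must be a named list", call. = FALSE)
  }
  unknown <- setdiff(names(tip_subtrees), backbone$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown backbone tip label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sub_leaves <- unlist(lapply(tip_subtrees, function(t) t$tip.label))
  final <- c(setdiff(backbone$tip.label, names(tip_subtrees)), sub_leaves)
  if (anyDuplicated(final)) {
    stop("duplicate leaf label(s) after grafting: ",
         paste(unique(final[duplicated(final)]), collapse = ", "),
         call. = FALSE)
  }
  ok <- grepl("^[A-Za-z0-9_.|-]+$", c(backbone$tip.label, sub_leaves))
  if (!all(ok)) {
    stop("leaf labels must be plain tokens (alphanumeric, '_', '.', '-', '|')",
         call. = FALSE)
  }
  nwk <- ape::write.tree(backbone)
  for (tip in names(tip_subtrees)) {
    sub_nwk <- sub(";\\s*$", "", ape::write.tree(tip_subtrees[[tip]]))
    # replace "tip:len" or bare "tip" bounded by Newick punctuation
    pat <- paste0("(?<=[(,])", gsub("([.|])", "\\\\\\1", tip),
                  "(?=[:,)])")
    nwk <- sub(pat, sub_nwk, nwk, perl = TRUE)
  }
  ape::read.tree(text = nwk)
}

#' Iterative constrained profile-cluster merging
#'
#' Implements the profile-update merge loop: at each iteration the closest
#' pair of clusters under the negative-log relative-score distance is
#' proposed; the merge oracle reports what the merged profile would retain
#' and how many new false positives it would pick up; the merge is
#' accepted only if retention exceeds `retention_min` (strictly) and the
#' new false positives do not exceed `new_fp_max` (inclusively). Accepted
#' merges replace the pair (the merged score row is the cluster-size
#' weighted mean of the parents' rows); rejected pairs are marked
#' unmergeable. The loop terminates when no unmarked pair remains, after
#' at most `n - 1` accepted merges. Ties in the closest pair are broken
#' lexicographically by label pair.
#'
#' @param clusters Named list; each element is a character vector of
#'   member sequence ids.
#' @param S Labelled similarity matrix over the cluster profiles
#'   (including self-scores), labels matching `names(clusters)`.
#' @param oracle Function of one argument (the candidate merged member
#'   vector) returning `list(retention =, new_fp =)`; deterministic.
#' @param retention_min Strict lower bound on retained fraction
#'   (default 0.98).
#' @param new_fp_max Inclusive upper bound on new false positives
#'   (default 10).
#' @return List with `clusters` (final named list) and `log` (tibble with
#'   one row per proposed merge: `step`, `a`, `b`, `distance`,
#'   `retention`, `new_fp`, `accepted`).
#' @export
nj_merge <- function(clusters, S, oracle, retention_min = 0.98,
                     new_fp_max = 10L) {
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  if (is.null(names(clusters)) || anyDuplicated(names(clusters))) {
    stop("clusters must have unique names", call. = FALSE)
  }
  log <- list()
  if (length(clusters) == 1L) {
    return(list(clusters = clusters,
                log = tibble::tibble(step = integer(0), a = character(0),
                                     b = character(0), distance = numeric(0),
                                     retention = numeric(0),
                                     new_fp = integer(0),
                                     accepted = logical(0))))
  }
  check_simmat(S)
  if (!setequal(rownames(S), names(clusters))) {
    stop("similarity matrix labels must match cluster names", call. = FALSE)
  }
  S <- S[names(clusters), names(clusters), drop = FALSE]
  sizes <- stats::setNames(lengths(clusters), names(clusters))
  blocked <- character(0)
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  step <- 0L
  repeat {
    labs <- names(clusters)
    if (length(labs) < 2L) break
    D <- to_distance(S)
    best <- NULL
    for (a in seq_len(length(labs) - 1L)) {
      for (b in (a + 1L):length(labs)) {
        if (pair_key(labs[a], labs[b]) %in% blocked) next
        lab <- sort(c(labs[a], labs[b]))
        d <- D[a, b]
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(a = labs[a], b = labs[b], d = d, lab = lab)
        }
      }
    }
    if (is.null(best)) break
    step <- step + 1L
    merged_members <- c(clusters[[best$a]], clusters[[best$b]])
    verdict <- oracle(merged_members)
    if (!is.list(verdict) || is.null(verdict$retention) ||
        is.null(verdict$new_fp)) {
      stop("merge oracle failed at step ", step,
           "; partial log has ", length(log), " entries", call. = FALSE)
    }
    accepted <- verdict$retention > retention_min &&
      verdict$new_fp <= new_fp_max
    log[[step]] <- tibble::tibble(
      step = step, a = best$lab[1], b = best$lab[2], distance = best$d,
      retention = verdict$retention, new_fp = as.integer(verdict$new_fp),
      accepted = accepted
    )
    if (!accepted) {
      blocked <- c(blocked, pair_key(best$a, best$b))
      next
    }
    new_lab <- paste(sort(c(best$a, best$b)), collapse = "|")
    wa <- sizes[[best$a]]; wb <- sizes[[best$b]]
    new_row <- (wa * S[best$a, ] + wb * S[best$b, ]) / (wa + wb)
    keep <- setdiff(names(clusters), c(best$a, best$b))
    S2 <- matrix(0, length(keep) + 1L, length(keep) + 1L,
                 dimnames = list(c(keep, new_lab), c(keep, new_lab)))
    if (length(keep) > 0L) {
      S2[keep, keep] <- S[keep, keep]
      S2[new_lab, keep] <- new_row[keep]
      S2[keep, new_lab] <- new_row[keep]
    }
    S2[new_lab, new_lab] <- (wa * S[best$a, best$a] +
                               wb * S[best$b, best$b]) / (wa + wb)
    S <- S2
    clusters <- c(clusters[keep],
                  stats::setNames(list(merged_members), new_lab))
    sizes <- c(sizes[keep], stats::setNames(wa + wb, new_lab))
    # pairs blocked against the parents stay blocked only for the parents;
    # the merged cluster starts unblocked against everyone
  }
  list(clusters = clusters,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble::tibble(step = integer(0), a = character(0),
                        b = character(0), distance = numeric(0),
                        retention = numeric(0), new_fp = integer(0),
                        accepted = logical(0)))
}
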