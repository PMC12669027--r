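#' Tree-based genome weights
#'
#' Branch-proportional (Gerstein-Sonnhammer-Chothia style) apportionment:
#' every edge's length is divided equally among the leaves that descend
#' from it, a leaf's raw weight is the sum of its shares along the path to
#' the root, and weights are normalised to sum to 1. Densely sampled
#' clades, which share most of their path length among many leaves, are
#' thereby down-weighted relative to isolated deep branches. On a star
#' tree with equal branches the weights are uniform.
#'
#' @param tree Rooted `phylo` with non-negative branch lengths.
#' @return Named numeric vector of weights over the tip labels, summing
#'   to 1 (uniform when total branch length is zero).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' compute_weights(tr)  # A = B = 0.3, C = 0.4
#' @export
compute_weights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in genome tree", call. = FALSE)
  }
  if (n == 1L) {
    return(stats::setNames(1, tree$tip.label))
  }
  if (is.null(tree$edge.length)) {
    stop("genome tree lacks branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in genome tree", call. = FALSE)
  }
  # tips descending from each edge, then share out each edge length
  w <- stats::setNames(numeric(n), tree$tip.label)
  desc <- descendant_tips(tree)
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[tree$edge[e, 2]]]
    w[tips] <- w[tips] + tree$edge.length[e] / length(tips)
  }
  tot <- sum(w)
  if (tot <= 0) {
    return(stats::setNames(rep(1 / n, n), tree$tip.label))
  }
  w / tot
}

# tip labels descending from every node, by postorder accumulation
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  desc <- vector("list", n_nodes)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

check_weights <- function(weights, genome_ids, tol = 1e-9) {
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  miss <- setdiff(genome_ids, names(weights))
  if (length(miss) > 0L) {
    stop("weights missing for genome(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...", call. = FALSE)
  }
  invisible(weights)
}

#' Genome-level predicate: carries a (complete) system
#'
#' Returns a predicate over one genome's classified loci for use with
#' [weighted_prevalence()].
#'
#' @param cas_type Restrict to one type (e.g. `"III"`); `NULL` for any.
#' @param subtype Restrict to one subtype; `NULL` for any.
#' @param complete_only Count only complete systems (default `TRUE`).
#' @return Function taking a locus tibble and returning a logical scalar.
#' @export
has_system <- function(cas_type = NULL, subtype = NULL,
                       complete_only = TRUE) {
  force(cas_type); force(subtype); force(complete_only)
  function(loci) {
    if (nrow(loci) == 0L) return(FALSE)
    keep <- rep(TRUE, nrow(loci))
    if (complete_only) keep <- keep & loci$complete
    if (!is.null(cas_type)) keep <- keep & loci$cas_type %in% cas_type
    if (!is.null(subtype)) keep <- keep & loci$subtype %in% subtype
    any(keep)
  }
}

#' Phylogenetically weighted prevalence
#'
#' Per group, the sum of genome weights across genomes satisfying the
#' predicate divided by the total sum of genome weights within the group.
#' With uniform weights this reduces to the plain fraction of carrier
#' genomes. Groups with zero total weight are dropped (reported via
#' message).
#'
#' @param genomes Genome table with `genome_id` and the grouping column.
#' @param loci Classified locus tibble (see [classify_loci()]).
#' @param weights Named weights over the genomes (see
#'   [compute_weights()]).
#' @param group_by Name of the grouping column in `genomes` (e.g.
#'   `"taxon"`).
#' @param predicate Predicate over one genome's loci rows; see
#'   [has_system()].
#' @return Tibble with columns `group`, `prevalence`, `weight_total`.
#' @export
weighted_prevalence <- function(genomes, loci, weights,
                                group_by = "taxon",
                                predicate = has_system()) {
  stopifnot(group_by %in% names(genomes), "genome_id" %in% names(genomes))
  check_weights(weights, genomes$genome_id)
  loci_by_genome <- split(loci, factor(loci$genome_id,
                                       levels = genomes$genome_id))
  carrier <- vapply(genomes$genome_id, function(g) {
    sub <- loci_by_genome[[g]]
    if (is.null(sub)) sub <- loci[0, , drop = FALSE]
    isTRUE(predicate(sub))
  }, TRUE)
  df <- tibble::tibble(
    group = genomes[[group_by]],
    w = unname(weights[genomes$genome_id]),
    carrier = carrier
  )
  out <- dplyr::summarise(dplyr::group_by(df, .data$group),
                          weight_total = sum(.data$w),
                          prevalence = sum(.data$w[.data$carrier]) /
                            sum(.data$w),
                          .groups = "drop")
  empty <- out$weight_total <= 0
  if (any(empty)) {
    message("dropping group(s) with zero total weight: ",
            paste(out$group[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  dplyr::select(out, "group", "prevalence", "weight_total")
}

#' Weighted subtype-fraction matrix (taxon x subtype)
#'
#' Every complete locus is assigned a weight equal to the weight of its
#' genome (so two same-subtype loci in one genome both count), the weights
#' of the loci of each subtype are summed per taxon, and each taxon row is
#' normalised by the taxon's total over all complete loci. Rows of taxa
#' with at least one complete locus sum to 1.
#'
#' @inheritParams weighted_prevalence
#' @return Numeric matrix, taxa in rows, subtypes in columns, values in
#'   `[0, 1]`; taxa without complete loci are absent.
#' @export
subtype_fraction_matrix <- function(genomes, loci, weights) {
  check_weights(weights, genomes$genome_id)
  cl <- loci[loci$complete & loci$subtype != "unclassified", , drop = FALSE]
  if (nrow(cl) == 0L) {
    return(matrix(numeric(0), 0, 0))
  }
  cl$taxon <- genomes$taxon[match(cl$genome_id, genomes$genome_id)]
  cl$w <- unname(weights[cl$genome_id])
  agg <- dplyr::summarise(
    dplyr::group_by(cl, .data$taxon, .data$subtype),
    w = sum(.data$w), .groups = "drop"
  )
  taxa <- sort(unique(agg$taxon))
  subs <- sort(unique(agg$subtype))
  M <- matrix(0, length(taxa), length(subs), dimnames = list(taxa, subs))
  M[cbind(match(agg$taxon, taxa), match(agg$subtype, subs))] <- agg$w
  sweep(M, 1, rowSums(M), "/")
}

#' Default optimal-growth-temperature classes
#'
#' Psychrophile below 20 C, mesophile 20-45 C, thermophile 45-80 C,
#' hyperthermophile above 80 C.
#'
#' @param ogt Numeric vector of optimal growth temperatures (degrees C).
#' @return Factor with the four class labels.
#' @export
temperature_class <- function(ogt) {
  cut(ogt, breaks = c(-Inf, 20, 45, 80, Inf),
      labels = c("psychrophile", "mesophile", "thermophile",
                 "hyperthermophile"),
      right = FALSE)
}

#' Weighted prevalence by growth-temperature class
#'
#' Restricts the census to genomes with a known optimal growth temperature,
#' recomputes genome weights on the induced subtree, assigns temperature
#' classes and delegates to [weighted_prevalence()]. Genomes without an
#' OGT are excluded and counted.
#'
#' @param genomes Genome table with `genome_id` and `ogt` columns.
#' @param loci Classified locus tibble.
#' @param tree Genome phylogeny covering (at least) the analysed genomes.
#' @param classes Function mapping OGT to class labels (default
#'   [temperature_class()]).
#' @param predicate See [weighted_prevalence()].
#' @return List with `prevalence` (tibble as in [weighted_prevalence()])
#'   and `n_excluded` (genomes lacking OGT).
#' @export
prevalence_by_temperature <- function(genomes, loci, tree,
                                      classes = temperature_class,
                                      predicate = has_system()) {
  stopifnot("ogt" %in% names(genomes))
  known <- genomes[!is.na(genomes$ogt), , drop = FALSE]
  n_excluded <- nrow(genomes) - nrow(known)
  if (n_excluded > 0L) {
    message(n_excluded, " genome(s) without OGT excluded")
  }
  sub <- ape::keep.tip(tree, intersect(tree$tip.label, known$genome_id))
  weights <- compute_weights(sub)
  known <- known[known$genome_id %in% names(weights), , drop = FALSE]
  known$temp_class <- as.character(classes(known$ogt))
  prev <- weighted_prevalence(known, loci, weights,
                              group_by = "temp_class",
                              predicate = predicate)
  list(prevalence = prev, n_excluded = as.integer(n_excluded))
}
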