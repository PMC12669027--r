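# Synthetic-data generators. Every input format the toolkit consumes can
# be emulated with planted ground truth, so the full pipeline is testable
# without any external data. All generators are pure functions of their
# arguments and the seed.

DEFAULT_PLANT_SUBTYPES <- c("I-B", "I-E", "I-F", "II-A", "III-A", "III-B",
                            "III-E", "III-G", "IV-A", "V-A", "VI-B", "VII")

# Genes emitted for one planted locus of a subtype: the effector-module
# inventory, the adaptation module when the registry requires it (and
# always for type IV, whose loci would otherwise carry no core cas1-cas14
# anchor for the assembler), plus one alternative from each required_any
# set.
plant_gene_set <- function(s) {
  fams <- s$required_all
  for (alt in s$required_any) if (length(alt) > 0L) fams <- c(fams, alt[1])
  if (!s$adaptation_optional || s$cas_type == "IV") {
    fams <- c("cas1", "cas2", fams)
  }
  unique(fams)
}

# Remove one planted element to make the locus incomplete without losing
# the classification signal: a shared effector-core family if possible,
# else the adaptation module, else the array.
incompleteness_edit <- function(fams, s, has_array) {
  uniq_sig <- s$required_all[1]
  droppable <- setdiff(s$required_all, uniq_sig)
  if (length(droppable) > 0L) {
    return(list(fams = setdiff(fams, droppable[length(droppable)]),
                drop_array = FALSE))
  }
  if (!s$adaptation_optional && "cas2" %in% fams) {
    return(list(fams = setdiff(fams, "cas2"), drop_array = FALSE))
  }
  if (!s$array_optional && has_array) {
    return(list(fams = fams, drop_array = TRUE))
  }
  # nothing required beyond the signature itself: drop adaptation anyway
  list(fams = setdiff(fams, "cas2"), drop_array = FALSE)
}

#' Simulate genomes with planted CRISPR-cas loci
#'
#' Generates the gene, profile-hit and CRISPR-array tables for a cohort of
#' single-contig genomes, each carrying planted loci with known subtype
#' and completeness, surrounded by decoy genes. Planted genes emit hits
#' from subtype-tagged profiles (`family@subtype`); decoys emit hits from
#' non-cas profiles. Under `noise = "none"` true hits have fixed strong
#' e-values and no decoy hits are emitted; under `noise = "default"` true
#' hit e-values are log-uniform on `[1e-30, 1e-5]` with query coverage
#' Beta(8, 2), and decoy hits are log-uniform on `[1e-3, 1]` so they are
#' removed by the e-value filter. Gene coordinates use fixed 300 bp genes
#' with 50 bp gaps; gene order (rank), not distance, drives assembly.
#'
#' @param registry A `cas_registry`; planted subtypes must exist in it.
#' @param n_genomes Number of genomes (default 50).
#' @param subtypes Subtype ids to plant, cycled across carrier genomes.
#' @param seed Integer seed; the same seed yields identical output.
#' @param carrier_prob Probability that a genome carries a locus
#'   (default 1).
#' @param p_incomplete Probability that a planted locus is incomplete
#'   (default 0.2).
#' @param noise `"none"` or `"default"`.
#' @param n_taxa Genomes are assigned round-robin to this many taxa.
#' @param decoy_range Range of decoy genes on each side of a locus.
#' @return List of tibbles: `genes`, `hits`, `arrays`, `truth` (planted
#'   locus table: `genome_id`, `subtype`, `cas_type`, `complete`,
#'   `span_start`, `span_end`), and `genomes` (`genome_id`, `taxon`,
#'   `ogt`, `carrier`).
#' @export
simulate_genomes <- function(registry, n_genomes = 50L,
                             subtypes = DEFAULT_PLANT_SUBTYPES,
                             seed = 1L, carrier_prob = 1,
                             p_incomplete = 0.2,
                             noise = c("none", "default"),
                             n_taxa = 4L, decoy_range = c(4L, 10L)) {
  noise <- match.arg(noise)
  known <- vapply(registry$subtypes, function(s) s$id, "")
  bad <- setdiff(subtypes, known)
  if (length(bad) > 0L) {
    stop("subtype(s) unknown to registry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    genomes <- tibble::tibble(
      genome_id = sprintf("g%03d", seq_len(n_genomes)),
      taxon = paste0("taxon", (seq_len(n_genomes) - 1L) %% n_taxa + 1L),
      ogt = round(stats::runif(n_genomes, 5, 100), 1),
      carrier = stats::runif(n_genomes) < carrier_prob
    )
    planted <- ifelse(genomes$carrier,
                      subtypes[(cumsum(genomes$carrier) - 1L) %%
                                 length(subtypes) + 1L],
                      NA_character_)
    genes <- list(); hits <- list(); arrays <- list(); truth <- list()
    for (i in seq_len(n_genomes)) {
      sim <- simulate_one_genome(genomes$genome_id[i], planted[i],
                                 registry, p_incomplete, noise,
                                 decoy_range)
      genes[[i]] <- sim$genes; hits[[i]] <- sim$hits
      arrays[[i]] <- sim$arrays; truth[[i]] <- sim$truth
    }
    list(genes = dplyr::bind_rows(genes),
         hits = dplyr::bind_rows(hits),
         arrays = dplyr::bind_rows(arrays),
         truth = dplyr::bind_rows(truth),
         genomes = genomes)
  })
}

true_hit_evalue <- function(n, noise) {
  if (noise == "none") rep(1e-10, n) else 10^stats::runif(n, -30, -5)
}

simulate_one_genome <- function(genome_id, subtype, registry,
                                p_incomplete, noise, decoy_range) {
  gene_len <- 300L; gap <- 50L
  n_left <- sample(decoy_range[1]:decoy_range[2], 1L)
  n_right <- sample(decoy_range[1]:decoy_range[2], 1L)
  fams <- character(0); tags <- character(0)
  has_array <- FALSE; complete <- NA
  if (!is.na(subtype)) {
    s <- registry_subtype(registry, subtype)
    fams <- plant_gene_set(s)
    has_array <- !s$array_optional
    complete <- stats::runif(1) >= p_incomplete
    if (!complete) {
      edit <- incompleteness_edit(fams, s, has_array)
      fams <- edit$fams
      if (edit$drop_array) has_array <- FALSE
    }
    tags <- ifelse(fams %in% c(s$required_all, unlist(s$required_any)),
                   subtype, NA_character_)
  }
  n_locus <- length(fams)
  n_total <- n_left + n_locus + n_right
  starts <- (seq_len(n_total) - 1L) * (gene_len + gap) + 1L
  is_locus <- seq_len(n_total) > n_left & seq_len(n_total) <= n_left + n_locus
  strand <- ifelse(is_locus, "+", sample(c("+", "-"), n_total, TRUE))
  genes <- tibble::tibble(
    genome_id = genome_id, contig = "ctg1",
    protein_id = sprintf("%s_p%03d", genome_id, seq_len(n_total)),
    start = starts, end = starts + gene_len - 1L, strand = strand
  )
  locus_prot <- genes$protein_id[is_locus]
  hit_rows <- list()
  if (n_locus > 0L) {
    hit_rows$true <- tibble::tibble(
      protein_id = locus_prot,
      profile_id = ifelse(is.na(tags), fams, paste0(fams, "@", tags)),
      evalue = true_hit_evalue(n_locus, noise),
      score = round(stats::runif(n_locus, 80, 300), 1),
      q_cov = if (noise == "none") rep(0.9, n_locus) else
        round(stats::rbeta(n_locus, 8, 2), 3),
      p_from = 1L, p_to = 90L
    )
  }
  if (noise == "default") {
    decoy_prot <- genes$protein_id[!is_locus]
    pick <- stats::runif(length(decoy_prot)) < 0.5
    if (any(pick)) {
      nd <- sum(pick)
      hit_rows$decoy <- tibble::tibble(
        protein_id = decoy_prot[pick],
        profile_id = sprintf("pfam%04d", sample(9999L, nd, TRUE)),
        evalue = 10^stats::runif(nd, -3, 0),
        score = round(stats::runif(nd, 20, 60), 1),
        q_cov = round(stats::runif(nd, 0.1, 0.9), 3),
        p_from = 1L, p_to = 60L
      )
    }
  }
  arrays <- tibble::tibble(genome_id = character(0), contig = character(0),
                           start = integer(0), end = integer(0),
                           repeat_len = integer(0), n_spacers = integer(0))
  if (has_array) {
    last_end <- genes$end[n_left + n_locus]
    arrays <- tibble::tibble(genome_id = genome_id, contig = "ctg1",
                             start = last_end + 10L, end = last_end + 130L,
                             repeat_len = 30L, n_spacers = 5L)
  }
  truth <- if (is.na(subtype)) NULL else tibble::tibble(
    genome_id = genome_id, subtype = subtype,
    cas_type = subtype_id_type(subtype), complete = complete,
    span_start = min(genes$start[is_locus]),
    span_end = max(genes$end[is_locus], if (has_array) arrays$end)
  )
  list(genes = genes, hits = dplyr::bind_rows(hit_rows),
       arrays = arrays, truth = truth)
}

#' Simulate a genome phylogeny
#'
#' Star, caterpillar (pectinate, unit branch lengths) or random
#' coalescent tree shapes over leaves labelled to match
#' [simulate_genomes()].
#'
#' @param n Number of leaves (at least 1).
#' @param shape `"coalescent"`, `"star"` or `"caterpillar"`.
#' @param seed Integer seed (used by the coalescent shape).
#' @param labels Optional leaf labels (default `g001`..).
#' @return A rooted `phylo` with positive branch lengths.
#' @export
simulate_tree <- function(n, shape = c("coalescent", "star", "caterpillar"),
                          seed = 1L, labels = sprintf("g%03d", seq_len(n))) {
  shape <- match.arg(shape)
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  stopifnot(length(labels) == n)
  if (n == 1L) {
    tr <- ape::read.tree(text = paste0("(", labels[1], ":1);"))
    return(tr)
  }
  if (shape == "star") {
    tr <- ape::read.tree(text = paste0(
      "(", paste0(labels, ":1", collapse = ","), ");"))
    return(tr)
  }
  if (shape == "caterpillar") {
    nwk <- paste0("(", labels[1], ":1,", labels[2], ":1)")
    for (i in seq_len(n)[-(1:2)]) {
      nwk <- paste0("(", nwk, ":1,", labels[i], ":1)")
    }
    return(ape::read.tree(text = paste0(nwk, ";")))
  }
  withr::with_seed(seed, ape::rcoal(n, tip.label = labels))
}

#' Simulate a profile similarity matrix with planted blocks
#'
#' Cluster blocks have stochastically higher within-block than
#' between-block scores, and the diagonal self-scores are the row maxima,
#' so depth-cutting the UPGMA dendrogram of the derived distances recovers
#' the planted partition when the blocks are well separated.
#'
#' @param n_clusters Number of planted clusters.
#' @param cluster_size Profiles per cluster.
#' @param seed Integer seed.
#' @param within,between Mean within-/between-block scores.
#' @param jitter Uniform score jitter half-width.
#' @return List with `S` (labelled symmetric matrix) and `partition`
#'   (named integer vector of planted cluster ids).
#' @export
simulate_similarity <- function(n_clusters, cluster_size = 3L, seed = 1L,
                                within = 80, between = 15, jitter = 5) {
  n <- n_clusters * cluster_size
  labels <- sprintf("prof%02d", seq_len(n))
  block <- rep(seq_len(n_clusters), each = cluster_size)
  withr::with_seed(seed, {
    S <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      for (j in seq_len(n)[-seq_len(i)]) {
        mu <- if (block[i] == block[j]) within else between
        S[i, j] <- S[j, i] <- max(1, mu + stats::runif(1, -jitter, jitter))
      }
    }
    diag(S) <- 100 + stats::runif(n, 0, 10)
  })
  list(S = S, partition = stats::setNames(block, labels))
}
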