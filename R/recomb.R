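# Effector gene families entering the module-swap tally: cas8 (incl. the
# lettered large subunits and Cas10d), cas9, cas10 and cas12. cas13/cas14
# are excluded by default, mirroring the published tally; the fused
# cas7-11 effectors never match.
effector_gene_of <- function(family, include_extended = FALSE) {
  base <- dplyr::case_when(
    grepl("^cas8[a-z]?$", family) ~ "cas8",
    family == "cas10d" ~ "cas8",  # type I-D large subunit
    grepl("^cas9[a-z]?$", family) ~ "cas9",
    family == "cas10" ~ "cas10",
    grepl("^cas12[a-z]?$", family) ~ "cas12",
    .default = NA_character_
  )
  if (include_extended) {
    ext <- dplyr::case_when(
      grepl("^cas13[a-z]?$", family) ~ "cas13",
      family == "cas14" ~ "cas14",
      .default = NA_character_
    )
    base <- dplyr::coalesce(base, ext)
  }
  base
}

#' Greedy incremental protein clustering
#'
#' MMSEQS2-style greedy incremental clustering: proteins are processed
#' longest-first (ties broken lexicographically); each protein joins the
#' first existing cluster whose representative it matches at or above both
#' the identity and the coverage threshold (coverage measured on the
#' representative, mirroring coverage-on-target mode), otherwise it founds
#' a new cluster. The published levels are strict (0.9/0.9) and permissive
#' (0.5/0.33).
#'
#' @param pairs Pairwise table with columns `p1`, `p2`, `identity` and
#'   `cov1`, `cov2` (fraction of `p1` resp. `p2` covered by the
#'   alignment); one row per unordered pair is enough. Missing pairs are
#'   treated as no detectable similarity.
#' @param lengths Tibble with columns `protein_id`, `length`.
#' @param id_threshold,cov_threshold Clustering thresholds in `[0, 1]`.
#' @return Tibble with columns `protein_id`, `cluster_id` (the
#'   representative's id).
#' @export
greedy_cluster <- function(pairs, lengths, id_threshold, cov_threshold) {
  stopifnot(all(c("p1", "p2", "identity", "cov1", "cov2") %in% names(pairs)),
            all(c("protein_id", "length") %in% names(lengths)))
  if (nrow(pairs) > 0L &&
      any(pairs$identity < 0 | pairs$identity > 1, na.rm = TRUE)) {
    stop("identity outside [0, 1]", call. = FALSE)
  }
  if (nrow(lengths) == 0L) {
    return(tibble::tibble(protein_id = character(0),
                          cluster_id = character(0)))
  }
  # symmetric lookup: identity and coverage-on-the-second-protein
  key <- function(a, b) paste(a, b, sep = "\r")
  idn <- c(stats::setNames(pairs$identity, key(pairs$p1, pairs$p2)),
           stats::setNames(pairs$identity, key(pairs$p2, pairs$p1)))
  cov_on <- c(stats::setNames(pairs$cov2, key(pairs$p1, pairs$p2)),
              stats::setNames(pairs$cov1, key(pairs$p2, pairs$p1)))
  ord <- order(-lengths$length, lengths$protein_id)
  prots <- lengths$protein_id[ord]
  reps <- character(0)
  assign <- stats::setNames(character(length(prots)), prots)
  for (p in prots) {
    placed <- FALSE
    for (r in reps) {
      k <- key(p, r)
      if (!is.na(idn[k]) && !is.null(idn[k][[1]]) &&
          isTRUE(idn[[k]] >= id_threshold) &&
          isTRUE(cov_on[[k]] >= cov_threshold)) {
        assign[p] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, p)
      assign[p] <- p
    }
  }
  tibble::tibble(protein_id = prots, cluster_id = unname(assign[prots]))
}

#' Extract adaptation/effector module pairs from classified loci
#'
#' For every locus containing both a cas1 gene and an effector gene (cas8,
#' cas9, cas10 or cas12, including lettered large-subunit families), one
#' pair per distinct effector gene is emitted, linking the cas1 protein's
#' strict cluster to the effector protein's permissive cluster. Loci with
#' more than one effector gene (hybrids) yield one pair each and are
#' flagged. Loci lacking either side are skipped and counted.
#'
#' @param loci Classified locus tibble (needs `locus_id`, `hits` columns;
#'   [classify_loci()] output qualifies, with `locus_id` present from
#'   assembly).
#' @param strict Cluster table for cas1 proteins (columns `protein_id`,
#'   `cluster_id`), at the strict level.
#' @param permissive Cluster table for effector proteins at the permissive
#'   level.
#' @param include_extended Also pair cas13/cas14 effectors
#'   (default `FALSE`).
#' @return List with `pairs` (tibble: `locus_id`, `cas1_strict_cluster`,
#'   `effector_gene`, `effector_permissive_cluster`, `hybrid`) and
#'   `n_skipped`.
#' @export
extract_module_pairs <- function(loci, strict, permissive,
                                 include_extended = FALSE) {
  strict_of <- stats::setNames(strict$cluster_id, strict$protein_id)
  perm_of <- stats::setNames(permissive$cluster_id, permissive$protein_id)
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(loci))) {
    hits <- loci$hits[[i]]
    cas1_prot <- sort(unique(hits$protein_id[hits$family == "cas1"]))
    eff <- hits[!is.na(effector_gene_of(hits$family, include_extended)), ,
                drop = FALSE]
    if (length(cas1_prot) == 0L || nrow(eff) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    cas1_cluster <- strict_of[cas1_prot[1]]
    eff <- unique(tibble::tibble(
      protein_id = eff$protein_id,
      effector_gene = effector_gene_of(eff$family, include_extended)
    ))
    if (any(is.na(cas1_cluster)) || any(is.na(perm_of[eff$protein_id]))) {
      stop("unresolvable cluster id for locus ", loci$locus_id[i],
           call. = FALSE)
    }
    hybrid <- length(unique(eff$effector_gene)) > 1L
    out[[length(out) + 1L]] <- tibble::tibble(
      locus_id = loci$locus_id[i],
      cas1_strict_cluster = unname(cas1_cluster),
      effector_gene = eff$effector_gene,
      effector_permissive_cluster = unname(perm_of[eff$protein_id]),
      hybrid = hybrid
    )
  }
  pairs <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(locus_id = character(0),
                   cas1_strict_cluster = character(0),
                   effector_gene = character(0),
                   effector_permissive_cluster = character(0),
                   hybrid = logical(0))
  list(pairs = pairs, n_skipped = n_skipped)
}

#' Count adaptation/effector module swaps
#'
#' A strict cas1 cluster that co-occurs with `k` distinct permissive
#' effector clusters across loci evidences at least `k - 1` recombination
#' events between the adaptation and effector modules (a conservative,
#' spanning count). With `per_pair = TRUE`, every distinct
#' (strict, permissive) pair beyond the first per strict cluster is
#' counted instead, which here is the same spanning count applied per
#' effector gene.
#'
#' @param pairs Module-pair tibble from [extract_module_pairs()].
#' @param per_pair Count distinct co-occurring pairs per effector gene
#'   rather than per strict cluster (default `FALSE`).
#' @return List with `n_events` and `detail` (tibble: one row per strict
#'   cas1 cluster with its distinct effector clusters and event count).
#' @export
count_module_swaps <- function(pairs, per_pair = FALSE) {
  if (nrow(pairs) == 0L) {
    return(list(n_events = 0L,
                detail = tibble::tibble(cas1_strict_cluster = character(0),
                                        n_effector_clusters = integer(0),
                                        n_events = integer(0))))
  }
  if (per_pair) {
    detail <- dplyr::summarise(
      dplyr::group_by(pairs, .data$cas1_strict_cluster,
                      .data$effector_gene),
      n_effector_clusters =
        dplyr::n_distinct(.data$effector_permissive_cluster),
      .groups = "drop_last")
    detail <- dplyr::summarise(
      detail,
      n_events = sum(pmax(0L, .data$n_effector_clusters - 1L)),
      n_effector_clusters = sum(.data$n_effector_clusters),
      .groups = "drop")
  } else {
    detail <- dplyr::summarise(
      dplyr::group_by(pairs, .data$cas1_strict_cluster),
      n_effector_clusters =
        dplyr::n_distinct(.data$effector_permissive_cluster),
      .groups = "drop")
    detail$n_events <- pmax(0L, detail$n_effector_clusters - 1L)
  }
  list(n_events = as.integer(sum(detail$n_events)), detail = detail)
}
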