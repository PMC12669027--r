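check_genes <- function(genes) {
  need <- c("genome_id", "contig", "protein_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L) {
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene with start > end", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  invisible(genes)
}

# Gene order on each contig: 1-based rank by start coordinate.
rank_genes <- function(genes) {
  genes <- dplyr::arrange(genes, .data$genome_id, .data$contig, .data$start,
                          .data$end, .data$protein_id)
  dplyr::mutate(dplyr::group_by(genes, .data$genome_id, .data$contig),
                rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

# Merge rank windows that overlap or touch; returns matrix of from/to.
merge_windows <- function(from, to) {
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  mf <- from[1]; mt <- to[1]
  out <- NULL
  for (i in seq_along(from)[-1]) {
    if (from[i] <= mt + 1L) {
      mt <- max(mt, to[i])
    } else {
      out <- rbind(out, c(mf, mt)); mf <- from[i]; mt <- to[i]
    }
  }
  rbind(out, c(mf, mt))
}

# Count genes lying entirely between an array interval and a locus bp span.
genes_between <- function(cg, a_start, a_end, span_start, span_end) {
  if (a_end < span_start) {
    sum(cg$start > a_end & cg$end < span_start)
  } else if (a_start > span_end) {
    sum(cg$start > span_end & cg$end < a_start)
  } else 0L
}

#' Assemble CRISPR-cas genomic neighbourhoods
#'
#' For every gene carrying a core cas hit (cas1-cas14; see
#' [is_core_family()]), a neighbourhood of up to `flank` genes on each side
#' is taken (truncated at contig ends, never wrapped). Overlapping or
#' adjacent neighbourhoods on one contig are merged into a single locus.
#' CRISPR arrays within `flank` genes of a locus member are attached, and
#' the locus span extends over all members and attached arrays. Assembly is
#' a pure function of the input tables, so seed order cannot change the
#' result.
#'
#' @param genes Gene table (`genome_id`, `contig`, `protein_id`, `start`,
#'   `end`, `strand`), 1-based inclusive coordinates.
#' @param annot Assigned-hit table from [annotate_proteins()].
#' @param arrays Optional CRISPR-array table (`genome_id`, `contig`,
#'   `start`, `end`, `repeat_len`, `n_spacers`), already ingest-filtered
#'   (see [read_arrays()]).
#' @param flank Genes taken on each side of a seed (default 10).
#' @return Tibble with one row per locus: `locus_id`, `genome_id`,
#'   `contig`, `rank_from`, `rank_to`, `span_start`, `span_end`, list
#'   columns `members` (gene rows), `hits` (their assigned hits), `arrays`,
#'   and `seeds` (protein ids carrying core hits).
#' @export
assemble_neighborhoods <- function(genes, annot, arrays = NULL,
                                   flank = 10L) {
  check_genes(genes)
  if (!"family" %in% names(annot)) {
    stop("annot must be an assigned-hit table with a 'family' column ",
         "(see annotate_proteins())", call. = FALSE)
  }
  genes <- rank_genes(genes)
  seed_prot <- unique(annot$protein_id[is_core_family(annot$family)])
  missing_seed <- setdiff(seed_prot, genes$protein_id)
  if (length(missing_seed) > 0L) {
    stop("seed protein(s) absent from gene table: ",
         paste(missing_seed, collapse = ", "), call. = FALSE)
  }
  if (length(seed_prot) == 0L) {
    return(empty_loci())
  }
  loci <- list()
  for (key in unique(paste(genes$genome_id, genes$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    cg <- genes[genes$genome_id == parts[1] & genes$contig == parts[2], ,
                drop = FALSE]
    seeds_here <- cg$rank[cg$protein_id %in% seed_prot]
    if (length(seeds_here) == 0L) next
    n <- nrow(cg)
    win <- merge_windows(pmax(1L, seeds_here - flank),
                         pmin(n, seeds_here + flank))
    for (w in seq_len(nrow(win))) {
      members <- cg[cg$rank >= win[w, 1] & cg$rank <= win[w, 2], ,
                    drop = FALSE]
      loci[[length(loci) + 1L]] <- build_locus(
        parts[1], parts[2], members, annot, arrays, cg, flank
      )
    }
  }
  out <- dplyr::bind_rows(loci)
  out$locus_id <- sprintf("%s:%s:%d", out$genome_id, out$contig,
                          stats::ave(seq_len(nrow(out)),
                                     paste(out$genome_id, out$contig),
                                     FUN = seq_along))
  dplyr::relocate(out, "locus_id")
}

empty_loci <- function() {
  tibble::tibble(locus_id = character(0), genome_id = character(0),
                 contig = character(0), rank_from = integer(0),
                 rank_to = integer(0), span_start = integer(0),
                 span_end = integer(0), members = list(), hits = list(),
                 arrays = list(), seeds = list())
}

build_locus <- function(genome_id, contig, members, annot, arrays, cg,
                        flank) {
  hits <- annot[annot$protein_id %in% members$protein_id, , drop = FALSE]
  span_start <- min(members$start)
  span_end <- max(members$end)
  arr <- NULL
  if (!is.null(arrays) && nrow(arrays) > 0L) {
    arr <- arrays[arrays$genome_id == genome_id &
                    arrays$contig == contig, , drop = FALSE]
    if (nrow(arr) > 0L) {
      gap <- vapply(seq_len(nrow(arr)), function(i) {
        genes_between(cg, arr$start[i], arr$end[i], span_start, span_end)
      }, 0L)
      arr <- arr[gap <= flank, , drop = FALSE]
      if (nrow(arr) > 0L) {
        span_start <- min(span_start, arr$start)
        span_end <- max(span_end, arr$end)
      }
    }
  }
  if (is.null(arr)) {
    arr <- tibble::tibble(genome_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          repeat_len = integer(0), n_spacers = integer(0))
  }
  seeds <- intersect(members$protein_id,
                     annot$protein_id[is_core_family(annot$family)])
  tibble::tibble(
    genome_id = genome_id, contig = contig,
    rank_from = min(members$rank), rank_to = max(members$rank),
    span_start = span_start, span_end = span_end,
    members = list(tibble::as_tibble(members)),
    hits = list(tibble::as_tibble(hits)),
    arrays = list(tibble::as_tibble(arr)),
    seeds = list(seeds)
  )
}

# Directon bounds: the maximal run of consecutive co-oriented genes
# containing rank r, on one contig's gene table (sorted by rank).
directon_bounds <- function(strands, r) {
  lo <- r
  while (lo > 1L && strands[lo - 1L] == strands[r]) lo <- lo - 1L
  hi <- r
  while (hi < length(strands) && strands[hi + 1L] == strands[r]) hi <- hi + 1L
  c(lo, hi)
}

#' Trim locus boundaries to directon bounds
#'
#' Each locus margin is moved to the boundary of the directon (maximal run
#' of same-strand consecutive genes) containing the outermost cas-annotated
#' element, extending through co-oriented flanking genes and trimming
#' unannotated margin genes beyond the directon. Interior unannotated genes
#' are retained. A locus already directon-bounded is a fixpoint.
#'
#' @param loci Locus tibble from [assemble_neighborhoods()].
#' @param genes The full gene table the loci were assembled from.
#' @param registry Optional `cas_registry`; when given, only hits to
#'   registry gene families anchor the margins (decoy annotations are
#'   ignored).
#' @return The locus tibble with updated bounds, members and hits.
#' @export
trim_boundaries <- function(loci, genes, registry = NULL) {
  if (nrow(loci) == 0L) return(loci)
  check_genes(genes)
  genes <- rank_genes(genes)
  for (i in seq_len(nrow(loci))) {
    cg <- genes[genes$genome_id == loci$genome_id[i] &
                  genes$contig == loci$contig[i], , drop = FALSE]
    hits <- loci$hits[[i]]
    if (!is.null(registry)) {
      hits <- hits[hits$family %in% registry$families$name, , drop = FALSE]
    }
    anchor_prot <- unique(hits$protein_id)
    anchor_ranks <- cg$rank[cg$protein_id %in% anchor_prot]
    arr <- loci$arrays[[i]]
    if (nrow(arr) > 0L) {
      # the genes nearest each attached array anchor the margin too
      for (j in seq_len(nrow(arr))) {
        left <- cg$rank[cg$end < arr$start[j]]
        right <- cg$rank[cg$start > arr$end[j]]
        anchor_ranks <- c(anchor_ranks,
                          if (length(left)) max(left),
                          if (length(right)) min(right))
      }
    }
    anchor_ranks <- anchor_ranks[anchor_ranks >= loci$rank_from[i] &
                                   anchor_ranks <= loci$rank_to[i]]
    if (length(anchor_ranks) == 0L) next
    lo <- directon_bounds(cg$strand, min(anchor_ranks))[1]
    hi <- directon_bounds(cg$strand, max(anchor_ranks))[2]
    members <- cg[cg$rank >= lo & cg$rank <= hi, , drop = FALSE]
    loci$rank_from[i] <- lo
    loci$rank_to[i] <- hi
    loci$members[[i]] <- tibble::as_tibble(members)
    loci$hits[[i]] <- loci$hits[[i]][
      loci$hits[[i]]$protein_id %in% members$protein_id, , drop = FALSE]
    loci$span_start[i] <- min(members$start,
                              if (nrow(arr)) arr$start else integer(0))
    loci$span_end[i] <- max(members$end,
                            if (nrow(arr)) arr$end else integer(0))
  }
  loci
}

# Score all subtypes against the family evidence of one locus.
score_subtypes <- function(fam_present, tag_pairs, reg, uniq_map,
                           sig_weight, core_weight) {
  rows <- lapply(reg$subtypes, function(s) {
    if (length(s$forbidden) > 0L && any(s$forbidden %in% fam_present)) {
      return(tibble::tibble(subtype = s$id, cas_type = s$cas_type,
                            n_sig = 0L, n_req = 0L, score = -Inf,
                            disqualified = TRUE))
    }
    tag_fams <- tag_pairs$family[tag_pairs$subtype_tag == s$id]
    uniq_fams <- intersect(names(uniq_map)[uniq_map == s$id], fam_present)
    sig_fams <- unique(c(tag_fams, uniq_fams))
    n_req <- sum(s$required_all %in% fam_present)
    tibble::tibble(subtype = s$id, cas_type = s$cas_type,
                   n_sig = length(sig_fams), n_req = as.integer(n_req),
                   score = sig_weight * length(sig_fams) +
                     core_weight * n_req,
                   disqualified = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Classify a locus against the registry
#'
#' Each subtype is scored from the locus's gene-family evidence:
#' subtype-specific evidence (a hit whose profile is tagged with the
#' subtype, or a family that is the unique signature of that subtype)
#' counts `sig_weight`, and every required family present counts
#' `core_weight`; a forbidden family disqualifies the subtype. Subtypes
#' with no signature evidence are ineligible. The best score wins; ties
#' are broken by the number of required families matched and otherwise
#' recorded as conflicts, never silently resolved.
#'
#' @param loci Locus tibble (optionally trimmed).
#' @param registry A `cas_registry`.
#' @param sig_weight,core_weight Scoring weights (defaults 2 and 1).
#' @param min_signature Minimum count of subtype-specific evidence for a
#'   classification (default 1).
#' @return The locus tibble with columns `cas_type`, `subtype`, `variant`,
#'   `score`, `complete`, `incomplete_reason`, list columns `conflicts`
#'   (competing subtypes with scores) and `evidence` (family support).
#' @examples
#' # see vignette("crisprcensus-methods") for an end-to-end example
#' @export
classify_loci <- function(loci, registry, sig_weight = 2,
                          core_weight = 1, min_signature = 1L) {
  stopifnot(inherits(registry, "cas_registry"))
  uniq_map <- unique_signature_map(registry)
  n <- nrow(loci)
  loci$cas_type <- rep("unclassified", n)
  loci$subtype <- rep("unclassified", n)
  loci$variant <- rep(NA_character_, n)
  loci$score <- rep(NA_real_, n)
  loci$conflicts <- rep(list(tibble::tibble(subtype = character(0),
                                            score = numeric(0))), n)
  loci$evidence <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- loci$hits[[i]]
    fam_present <- intersect(unique(hits$family), registry$families$name)
    tag_pairs <- unique(hits[!is.na(hits$subtype_tag),
                             c("family", "subtype_tag"), drop = FALSE])
    loci$evidence[[i]] <- dplyr::count(
      hits[hits$family %in% fam_present, , drop = FALSE],
      .data$family, name = "n_hits")
    sc <- score_subtypes(fam_present, tag_pairs, registry, uniq_map,
                         sig_weight, core_weight)
    ok <- sc[!sc$disqualified & sc$n_sig >= min_signature, , drop = FALSE]
    if (nrow(ok) == 0L) next
    top <- ok[ok$score == max(ok$score), , drop = FALSE]
    best <- top[top$n_req == max(top$n_req), , drop = FALSE]
    best <- best[order(best$subtype), , drop = FALSE]
    loci$subtype[i] <- best$subtype[1]
    loci$cas_type[i] <- best$cas_type[1]
    loci$score[i] <- best$score[1]
    if (nrow(best) > 1L) {
      loci$conflicts[[i]] <- tibble::tibble(subtype = best$subtype,
                                            score = best$score)
    }
  }
  comp <- complete_status(loci, registry)
  loci$complete <- comp$complete
  loci$incomplete_reason <- comp$reason
  loci
}

complete_status <- function(loci, registry) {
  n <- nrow(loci)
  complete <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- completeness_one(
      fam_present = intersect(unique(loci$hits[[i]]$family),
                              registry$families$name),
      has_array = nrow(loci$arrays[[i]]) > 0L,
      subtype_id = loci$subtype[i], registry = registry
    )
    complete[i] <- res$complete
    reason[i] <- res$reason
  }
  list(complete = complete, reason = reason)
}

completeness_one <- function(fam_present, has_array, subtype_id, registry) {
  if (is.na(subtype_id) || subtype_id == "unclassified") {
    return(list(complete = FALSE, reason = "unclassified locus"))
  }
  s <- registry_subtype(registry, subtype_id)
  missing_req <- setdiff(s$required_all, fam_present)
  if (length(missing_req) > 0L) {
    return(list(complete = FALSE,
                reason = paste0("missing required famil",
                                if (length(missing_req) > 1) "ies: " else "y: ",
                                paste(missing_req, collapse = ", "))))
  }
  for (alt in s$required_any) {
    if (length(alt) > 0L && !any(alt %in% fam_present)) {
      return(list(complete = FALSE,
                  reason = paste0("no member of alternative set present: ",
                                  paste(alt, collapse = "|"))))
    }
  }
  if (!s$adaptation_optional &&
      !all(c("cas1", "cas2") %in% fam_present)) {
    return(list(complete = FALSE, reason = "adaptation module absent"))
  }
  if (!s$array_optional && !has_array) {
    return(list(complete = FALSE, reason = "no CRISPR array attached"))
  }
  list(complete = TRUE, reason = NA_character_)
}

#' Is a classified locus complete?
#'
#' A locus is complete iff it contains all core and subtype-specific
#' signature genes of its subtype's effector module; the adaptation module
#' (cas1 + cas2) and an attached CRISPR array are additionally required
#' only when the subtype definition marks them non-optional (type VII, for
#' instance, lacks adaptation modules, and III-G loci carry no array). An
#' unclassified locus is never complete; the reason is attached as an
#' attribute.
#'
#' @param locus One locus row (from a classified or unclassified locus
#'   tibble).
#' @param classification A list or row with at least `$subtype`; defaults
#'   to the locus's own `subtype` column when present.
#' @param registry A `cas_registry`.
#' @return Logical scalar with attribute `"reason"` (`NA` when complete).
#' @export
is_complete <- function(locus, classification = NULL, registry) {
  if (is.null(classification)) classification <- locus
  subtype_id <- if (is.list(classification) && !is.null(classification$subtype))
    classification$subtype[[1]] else as.character(classification)[1]
  res <- completeness_one(
    fam_present = intersect(unique(locus$hits[[1]]$family),
                            registry$families$name),
    has_array = nrow(locus$arrays[[1]]) > 0L,
    subtype_id = subtype_id, registry = registry
  )
  structure(res$complete, reason = res$reason)
}
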