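#' Split profile ids into gene family and subtype tag
#'
#' Profile ids follow the convention `family` or `family@subtype`
#' (`"cas8a@I-A"`): the family names the gene family the profile models and
#' the optional tag records the subtype provenance of the profile, mirroring
#' subtype-specific PSSM sets.
#'
#' @param profile_id Character vector of profile ids.
#' @return Tibble with columns `profile_id`, `family`, `subtype_tag`
#'   (`NA` when untagged).
#' @export
split_profile <- function(profile_id) {
  tagged <- grepl("@", profile_id, fixed = TRUE)
  tibble::tibble(
    profile_id = profile_id,
    family = sub("@.*$", "", profile_id),
    subtype_tag = ifelse(tagged, sub("^.*@", "", profile_id), NA_character_)
  )
}

check_hits <- function(hits) {
  need <- c("protein_id", "profile_id", "evalue", "score",
            "q_cov", "p_from", "p_to")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L) {
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stop("negative e-value in hit table", call. = FALSE)
  }
  if (any(hits$p_from > hits$p_to, na.rm = TRUE)) {
    stop("hit with p_from > p_to", call. = FALSE)
  }
  if (any(hits$q_cov < 0 | hits$q_cov > 1, na.rm = TRUE)) {
    stop("q_cov outside [0, 1]", call. = FALSE)
  }
  invisible(hits)
}

#' Filter profile hits by e-value
#'
#' Retains hits at or below the e-value threshold (the published cutoff is
#' 1e-4), preserving input order.
#'
#' @param hits Hit tibble (columns `protein_id`, `profile_id`, `evalue`,
#'   `score`, `q_cov`, `p_from`, `p_to`).
#' @param evalue_max Inclusive e-value ceiling.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, evalue_max = 1e-4) {
  check_hits(hits)
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

#' Filter profile hits by query coverage
#'
#' Retains hits covering at least `min_cov` of the query profile length
#' (inclusive; the abundance-estimation cutoff is 0.75).
#'
#' @inheritParams filter_hits
#' @param min_cov Inclusive coverage floor in `[0, 1]`.
#' @return The filtered hit tibble.
#' @export
coverage_filter <- function(hits, min_cov = 0.75) {
  check_hits(hits)
  hits[hits$q_cov >= min_cov, , drop = FALSE]
}

hit_overlap <- function(f1, t1, f2, t2) {
  pmax(0L, pmin(t1, t2) - pmax(f1, f2) + 1L)
}

#' Select the best-scoring non-overlapping hits on one protein
#'
#' Greedy culling by descending bit score: a hit is accepted iff its
#' interval overlaps every already-accepted hit by at most
#' `overlap_tolerance` residues. Score ties are broken by lower e-value,
#' then longer interval, then lexicographic profile id, so the result is
#' deterministic. Every rejected hit overlaps some accepted hit of equal or
#' greater score.
#'
#' @param hits Hit tibble for a single protein.
#' @param overlap_tolerance Residues of tolerated overlap (default 0).
#' @return Accepted hits, sorted by `p_from`.
#' @examples
#' h <- tibble::tibble(protein_id = "p1",
#'   profile_id = c("A", "B", "C"), evalue = 1e-10, score = c(50, 60, 40),
#'   q_cov = 0.9, p_from = c(1, 50, 140), p_to = c(100, 150, 200))
#' select_nonoverlapping(h)$profile_id  # "B"
#' @export
select_nonoverlapping <- function(hits, overlap_tolerance = 0L) {
  check_hits(hits)
  if (nrow(hits) == 0L) return(hits)
  if (length(unique(hits$protein_id)) != 1L) {
    stop("select_nonoverlapping() expects hits for a single protein",
         call. = FALSE)
  }
  len <- hits$p_to - hits$p_from + 1L
  ord <- order(-hits$score, hits$evalue, -len, hits$profile_id)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) { keep <- i; next }
    ov <- hit_overlap(hits$p_from[i], hits$p_to[i],
                      hits$p_from[keep], hits$p_to[keep])
    if (all(ov <= overlap_tolerance)) keep <- c(keep, i)
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$p_from, out$p_to, out$profile_id), , drop = FALSE]
}

#' Annotate proteins with a non-overlapping set of best-scoring hits
#'
#' Applies the e-value filter, then greedy non-overlap selection per
#' protein, and annotates each assigned hit with its gene family and
#' subtype tag.
#'
#' @param hits Hit tibble covering any number of proteins.
#' @param config A [pipeline_config()].
#' @return Tibble of assigned hits with added `family` and `subtype_tag`
#'   columns.
#' @export
annotate_proteins <- function(hits, config = pipeline_config()) {
  check_hits(hits)
  kept <- filter_hits(hits, config$evalue_max)
  if (nrow(kept) == 0L) {
    out <- kept
  } else {
    parts <- split(kept, kept$protein_id)
    out <- dplyr::bind_rows(lapply(parts, select_nonoverlapping,
                                   overlap_tolerance =
                                     config$overlap_tolerance))
  }
  prof <- split_profile(out$profile_id)
  out$family <- prof$family
  out$subtype_tag <- prof$subtype_tag
  tibble::as_tibble(out)
}

#' Count clustered-database abundance per type and subtype
#'
#' Implements the abundance-counting mode: hits of subtype-provenance
#' profiles against a clustered protein database are de-overlapped per
#' target and counted once per best non-overlapping assignment, keyed by
#' the subtype of the query profile. Hits whose profile carries no subtype
#' tag are counted under `"unassigned"` and reported.
#'
#' @param hits Hit tibble; `protein_id` identifies the *target* protein and
#'   `profile_id` the query profile (tagged `family@subtype`). Hits are
#'   expected to be e-value- and coverage-filtered already (pass them
#'   through [filter_hits()] and [coverage_filter()] first).
#' @param registry Optional `cas_registry`; when given, subtype tags absent
#'   from the registry are folded into `"unassigned"`.
#' @param overlap_tolerance Residues of tolerated overlap per target.
#' @return List with tibbles `by_subtype` (`subtype`, `n`) and `by_type`
#'   (`cas_type`, `n`), and the integer `n_unassigned`.
#' @export
count_abundance <- function(hits, registry = NULL, overlap_tolerance = 0L) {
  check_hits(hits)
  if (nrow(hits) == 0L) {
    return(list(by_subtype = tibble::tibble(subtype = character(0),
                                            n = integer(0)),
                by_type = tibble::tibble(cas_type = character(0),
                                         n = integer(0)),
                n_unassigned = 0L))
  }
  parts <- split(hits, hits$protein_id)
  assigned <- dplyr::bind_rows(lapply(parts, select_nonoverlapping,
                                      overlap_tolerance = overlap_tolerance))
  prof <- split_profile(assigned$profile_id)
  subtype <- prof$subtype_tag
  if (!is.null(registry)) {
    known <- vapply(registry$subtypes, function(s) s$id, "")
    subtype[!is.na(subtype) & !(subtype %in% known)] <- NA_character_
  }
  n_unassigned <- sum(is.na(subtype))
  subtype[is.na(subtype)] <- "unassigned"
  by_subtype <- dplyr::count(tibble::tibble(subtype = subtype),
                             .data$subtype, name = "n")
  typed <- by_subtype[by_subtype$subtype != "unassigned", , drop = FALSE]
  by_type <- dplyr::count(
    tibble::tibble(cas_type = subtype_id_type(typed$subtype),
                   n = typed$n),
    .data$cas_type, wt = .data$n, name = "n"
  )
  list(by_subtype = by_subtype, by_type = by_type,
       n_unassigned = as.integer(n_unassigned))
}
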