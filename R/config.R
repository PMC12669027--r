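#' Pipeline configuration
#'
#' Collects every numeric threshold used across the toolkit in one object.
#' The defaults are the operating points of the published pipeline this
#' package implements: the PSI-BLAST e-value cutoff for profile hits, the
#' query-coverage floor for abundance counting, the strict (0.9/0.9) and
#' permissive (0.5/0.33) protein-clustering thresholds, the footprint
#' clustering identity, the dendrogram depth cut, the profile-merge
#' acceptance rule (>98 percent retention, at most ten new false positives),
#' the ten-gene neighbourhood flank, and the 20 bp minimum direct-repeat
#' length for CRISPR-array ingestion.
#'
#' @param evalue_max Maximum profile-hit e-value retained (default 1e-4).
#' @param abundance_min_cov Minimum fraction of the query profile length a
#'   hit must cover to be counted in abundance estimation (default 0.75).
#' @param strict_id,strict_cov Identity and coverage thresholds of the
#'   strict protein clustering level (defaults 0.9, 0.9).
#' @param permissive_id,permissive_cov Identity and coverage thresholds of
#'   the permissive clustering level (defaults 0.5, 0.33).
#' @param footprint_cluster_id Identity threshold used when clustering
#'   profile footprints (default 0.7).
#' @param tree_depth_cut Node-height cutoff for depth-cutting profile
#'   similarity dendrograms (default 0.8, log-distance units).
#' @param merge_retention_min Profile-merge acceptance: fraction of original
#'   member sequences that the merged profile must retain, strict lower
#'   bound (default 0.98).
#' @param merge_new_fp_max Profile-merge acceptance: maximum number of new
#'   false positives, inclusive (default 10).
#' @param flank_genes Number of genes taken on each side of a core cas gene
#'   when assembling neighbourhoods (default 10).
#' @param min_repeat_len_bp Minimum direct-repeat length of ingested CRISPR
#'   arrays, in base pairs (default 20).
#' @param overlap_tolerance Residues of overlap tolerated between accepted
#'   profile hits on one protein (default 0).
#' @param rng_seed Seed used by stochastic helpers (default 1).
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config()
#' cfg$evalue_max
#' @export
pipeline_config <- function(evalue_max = 1e-4,
                            abundance_min_cov = 0.75,
                            strict_id = 0.9, strict_cov = 0.9,
                            permissive_id = 0.5, permissive_cov = 0.33,
                            footprint_cluster_id = 0.7,
                            tree_depth_cut = 0.8,
                            merge_retention_min = 0.98,
                            merge_new_fp_max = 10L,
                            flank_genes = 10L,
                            min_repeat_len_bp = 20L,
                            overlap_tolerance = 0L,
                            rng_seed = 1L) {
  cfg <- list(
    evalue_max = evalue_max,
    abundance_min_cov = abundance_min_cov,
    strict_id = strict_id, strict_cov = strict_cov,
    permissive_id = permissive_id, permissive_cov = permissive_cov,
    footprint_cluster_id = footprint_cluster_id,
    tree_depth_cut = tree_depth_cut,
    merge_retention_min = merge_retention_min,
    merge_new_fp_max = as.integer(merge_new_fp_max),
    flank_genes = as.integer(flank_genes),
    min_repeat_len_bp = as.integer(min_repeat_len_bp),
    overlap_tolerance = as.integer(overlap_tolerance),
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("abundance_min_cov", "strict_id", "strict_cov",
             "permissive_id", "permissive_cov", "footprint_cluster_id",
             "merge_retention_min")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("config field '", f, "' must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$evalue_max) || cfg$evalue_max < 0) {
    stop("evalue_max must be non-negative", call. = FALSE)
  }
  if (cfg$tree_depth_cut < 0) stop("tree_depth_cut must be non-negative",
                                   call. = FALSE)
  ints <- c("merge_new_fp_max", "flank_genes", "min_repeat_len_bp",
            "overlap_tolerance")
  for (f in ints) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop("config field '", f, "' must be a non-negative integer",
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("CRISPR-Cas pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
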