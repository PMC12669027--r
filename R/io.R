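# File dialects: GFF3 subset for genes, headered TSV for hits / arrays /
# cluster tables / matrices, Newick for trees. All coordinates on disk are
# 1-based inclusive (GFF3 convention); conversion, if ever needed, happens
# in one place only. All writers are atomic (temp file, then rename), so a
# failed write never leaves a partial output.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to move temporary output to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read a gene table from a GFF3 subset
#'
#' Accepts the CDS rows of a GFF3 file: columns seqid, source, type,
#' start, end, score, strand, phase, attributes; the attributes field must
#' carry `ID=` and may carry `genome=` (falling back to the source
#' column). Rows of other types are ignored. Malformed rows are rejected
#' with their line number.
#'
#' @param path GFF3 file path.
#' @return Gene tibble (`genome_id`, `contig`, `protein_id`, `start`,
#'   `end`, `strand`).
#' @export
read_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no feature rows in ", path, call. = FALSE)
  rows <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- list()
  for (k in seq_along(rows)) {
    f <- rows[[k]]
    ln <- idx[k]
    if (length(f) != 9L) {
      stop("line ", ln, ": expected 9 tab-separated fields, got ",
           length(f), call. = FALSE)
    }
    if (f[3] != "CDS") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("line ", ln, ": non-numeric coordinates", call. = FALSE)
    }
    if (start > end) {
      stop("line ", ln, ": start > end", call. = FALSE)
    }
    if (!f[7] %in% c("+", "-")) {
      stop("line ", ln, ": strand must be '+' or '-'", call. = FALSE)
    }
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    get_attr <- function(key) {
      hit <- grep(paste0("^", key, "="), attrs, value = TRUE)
      if (length(hit) == 0L) NA_character_ else sub("^[^=]+=", "", hit[1])
    }
    id <- get_attr("ID")
    if (is.na(id)) stop("line ", ln, ": missing ID attribute",
                        call. = FALSE)
    genome <- get_attr("genome")
    if (is.na(genome)) genome <- f[2]
    out[[length(out) + 1L]] <- tibble::tibble(
      genome_id = genome, contig = f[1], protein_id = id,
      start = start, end = end, strand = f[7]
    )
  }
  if (length(out) == 0L) stop("no CDS rows in ", path, call. = FALSE)
  check_genes(dplyr::bind_rows(out))
}

#' Write a gene table as GFF3
#' @param genes Gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  check_genes(genes)
  atomic_write(path, function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;genome=%s",
                       genes$contig, genes$genome_id, genes$start,
                       genes$end, genes$strand, genes$protein_id,
                       genes$genome_id), con)
  })
}

read_tsv_checked <- function(path, required, col_types) {
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(path, ": missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop(path, ": malformed row(s) at line(s) ",
         paste(utils::head(probs$row, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a profile-hit table
#'
#' Headered TSV with columns protein_id, profile_id, evalue, bitscore,
#' qcov, pstart, pend (a superset of BLAST outfmt-6 semantics; 1-based
#' inclusive hit coordinates).
#'
#' @param path TSV path.
#' @return Hit tibble with internal column names (`score`, `q_cov`,
#'   `p_from`, `p_to`).
#' @export
read_hits <- function(path) {
  df <- read_tsv_checked(path,
                         c("protein_id", "profile_id", "evalue",
                           "bitscore", "qcov", "pstart", "pend"),
                         readr::cols(protein_id = "c", profile_id = "c",
                                     evalue = "d", bitscore = "d",
                                     qcov = "d", pstart = "i", pend = "i"))
  hits <- tibble::tibble(protein_id = df$protein_id,
                         profile_id = df$profile_id, evalue = df$evalue,
                         score = df$bitscore, q_cov = df$qcov,
                         p_from = df$pstart, p_to = df$pend)
  check_hits(hits)
}

#' Write a profile-hit table
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  check_hits(hits)
  out <- tibble::tibble(protein_id = hits$protein_id,
                        profile_id = hits$profile_id,
                        evalue = hits$evalue, bitscore = hits$score,
                        qcov = hits$q_cov, pstart = hits$p_from,
                        pend = hits$p_to)
  atomic_write(path, function(tmp) readr::write_tsv(out, tmp))
}

#' Read a CRISPR-array table
#'
#' Headered TSV (genome_id, contig, start, end, repeat_len, n_spacers)
#' with detector-style array calls. Arrays with a direct repeat shorter
#' than `min_repeat_len` are dropped at ingest (the published minimum is
#' 20 bp).
#'
#' @param path TSV path.
#' @param min_repeat_len Minimum direct-repeat length in bp.
#' @return Array tibble.
#' @export
read_arrays <- function(path, min_repeat_len = 20L) {
  df <- read_tsv_checked(path,
                         c("genome_id", "contig", "start", "end",
                           "repeat_len", "n_spacers"),
                         readr::cols(genome_id = "c", contig = "c",
                                     start = "i", end = "i",
                                     repeat_len = "i", n_spacers = "i"))
  if (any(df$start > df$end)) stop(path, ": array with start > end",
                                   call. = FALSE)
  if (any(df$n_spacers < 1L)) stop(path, ": array with no spacers",
                                   call. = FALSE)
  df[df$repeat_len >= min_repeat_len, , drop = FALSE]
}

#' Write a CRISPR-array table
#' @param arrays Array tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays <- function(arrays, path) {
  atomic_write(path, function(tmp) readr::write_tsv(arrays, tmp))
}

#' Read a Newick genome tree
#' @param path Newick file.
#' @return A `phylo`.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("unparseable Newick in ", path, call. = FALSE)
  tr
}

#' Write a tree (or dendrogram) as Newick
#' @param tree A `phylo` or `cas_dendrogram` (converted with
#'   [dendro_to_phylo()], heights encoded as branch lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "cas_dendrogram")) tree <- dendro_to_phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  atomic_write(path, function(tmp) ape::write.tree(tree, file = tmp))
}

#' Read a labelled square score matrix
#' @param path TSV with row labels in the first column and matching column
#'   labels in the header.
#' @return Labelled numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M))) {
    stop(path, ": matrix must be square with matching labels",
         call. = FALSE)
  }
  storage.mode(M) <- "double"
  M
}

#' Write a labelled square matrix
#' @param M Labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(M, path) {
  atomic_write(path, function(tmp) {
    df <- data.frame(label = rownames(M), M, check.names = FALSE)
    readr::write_tsv(df, tmp)
  })
}

#' Write a locus report
#'
#' One row per locus: genome, contig, span, classification, completeness,
#' and the comma-joined gene-family content.
#'
#' @param loci Classified locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  flat <- tibble::tibble(
    locus_id = loci$locus_id, genome_id = loci$genome_id,
    contig = loci$contig, span_start = loci$span_start,
    span_end = loci$span_end,
    cas_type = if ("cas_type" %in% names(loci)) loci$cas_type else NA,
    subtype = if ("subtype" %in% names(loci)) loci$subtype else NA,
    variant = if ("variant" %in% names(loci)) loci$variant else NA,
    complete = if ("complete" %in% names(loci)) loci$complete else NA,
    n_genes = vapply(loci$members, nrow, 0L),
    n_arrays = vapply(loci$arrays, nrow, 0L),
    families = vapply(loci$hits, function(h)
      paste(sort(unique(h$family)), collapse = ","), "")
  )
  atomic_write(path, function(tmp) readr::write_tsv(flat, tmp))
}

#' Read a flattened locus report
#' @param path TSV written by [write_loci()].
#' @return Tibble of the flattened locus rows.
#' @export
read_loci <- function(path) {
  read_tsv_checked(path,
                   c("locus_id", "genome_id", "contig", "span_start",
                     "span_end", "cas_type", "subtype", "complete"),
                   readr::cols(.default = "c", span_start = "i",
                               span_end = "i", complete = "l",
                               n_genes = "i", n_arrays = "i"))
}

#' Write a census table (prevalence or fraction matrix)
#' @param x Tibble (written as TSV) or matrix (written with a `label`
#'   column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(x, path) {
  if (is.matrix(x)) return(write_matrix(x, path))
  atomic_write(path, function(tmp) readr::write_tsv(x, tmp))
}
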