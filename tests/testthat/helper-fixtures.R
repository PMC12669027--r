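# Fixture builders shared across test files.

# A single-contig gene table with `n` genes of 300 bp and 50 bp gaps.
make_genes <- function(n, strands = rep("+", n), genome = "gA",
                       contig = "c1") {
  starts <- (seq_len(n) - 1L) * 350L + 1L
  tibble::tibble(
    genome_id = genome, contig = contig,
    protein_id = sprintf("%s_p%02d", genome, seq_len(n)),
    start = starts, end = starts + 299L, strand = strands
  )
}

# Strong hits for the given proteins, one per (protein, profile) pair.
make_hits <- function(protein_id, profile_id) {
  n <- length(protein_id)
  tibble::tibble(
    protein_id = protein_id, profile_id = profile_id,
    evalue = 1e-10, score = 200, q_cov = 0.9,
    p_from = 1L, p_to = 90L
  )
}

# Assemble + classify a locus whose genes carry the given profiles
# (optionally with an attached array); returns the classified locus row.
make_classified_locus <- function(profiles, registry, array = TRUE,
                                  n_left = 2L, n_right = 2L,
                                  reverse = FALSE) {
  n <- n_left + length(profiles) + n_right
  genes <- make_genes(n)
  if (reverse) {
    # mirror the contig: reverse gene order and flip strands
    total <- max(genes$end) + 1L
    new_start <- total - genes$end
    genes$end <- total - genes$start
    genes$start <- new_start
    genes$strand <- ifelse(genes$strand == "+", "-", "+")
  }
  locus_prot <- sprintf("gA_p%02d", n_left + seq_along(profiles))
  hits <- make_hits(locus_prot, profiles)
  arrays <- if (array) {
    anchor <- genes[genes$protein_id == locus_prot[length(locus_prot)], ]
    tibble::tibble(genome_id = "gA", contig = "c1",
                   start = anchor$end + 10L, end = anchor$end + 130L,
                   repeat_len = 30L, n_spacers = 4L)
  }
  annot <- annotate_proteins(hits)
  loci <- assemble_neighborhoods(genes, annot, arrays)
  classify_loci(loci, registry)
}

registry_2025 <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_registry("2025")
    reg
  }
})
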