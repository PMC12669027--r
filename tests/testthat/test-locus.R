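test_that("a mid-contig seed yields a 21-gene neighbourhood", {
  genes <- make_genes(30)
  annot <- annotate_proteins(make_hits("gA_p15", "cas1"))
  loci <- assemble_neighborhoods(genes, annot)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$rank_from, 5L)
  expect_equal(loci$rank_to, 25L)
  expect_equal(nrow(loci$members[[1]]), 21L)
})

test_that("neighbourhoods truncate at contig ends and never wrap", {
  genes <- make_genes(12)
  annot <- annotate_proteins(make_hits("gA_p03", "cas2"))
  loci <- assemble_neighborhoods(genes, annot)
  expect_equal(loci$rank_from, 1L)
  expect_equal(loci$rank_to, 12L)
})

test_that("nearby seeds merge into one locus, independent of order", {
  genes <- make_genes(40)
  annot1 <- annotate_proteins(make_hits(c("gA_p10", "gA_p15"),
                                        c("cas1", "cas9")))
  loci <- assemble_neighborhoods(genes, annot1)
  expect_equal(nrow(loci), 1L)
  expect_equal(c(loci$rank_from, loci$rank_to), c(1L, 25L))
  # permuting input rows (seed discovery order) changes nothing
  annot2 <- annot1[rev(seq_len(nrow(annot1))), ]
  loci2 <- assemble_neighborhoods(genes[sample(40), ], annot2)
  expect_equal(loci2[, c("rank_from", "rank_to")],
               loci[, c("rank_from", "rank_to")])
})

test_that("loci on one contig never overlap after merging", {
  genes <- make_genes(80)
  for (seed in 1:10) {
    prot <- withr::with_seed(seed,
                             sample(genes$protein_id, sample(2:6, 1)))
    annot <- annotate_proteins(make_hits(prot, rep("cas1", length(prot))))
    loci <- assemble_neighborhoods(genes, annot)
    if (nrow(loci) > 1L) {
      o <- order(loci$rank_from)
      expect_true(all(loci$rank_from[o][-1] >
                        utils::head(loci$rank_to[o], -1) + 1L))
    }
  }
})

test_that("a seed protein absent from the gene table is an error", {
  genes <- make_genes(5)
  annot <- annotate_proteins(make_hits("ghost_p1", "cas1"))
  expect_error(assemble_neighborhoods(genes, annot), "ghost_p1")
})

test_that("margins extend to the directon boundary and trim beyond it", {
  # strands: + + cas(+) + | - -  : the cas directon runs ranks 1..4
  genes <- make_genes(6, strands = c("+", "+", "+", "+", "-", "-"))
  annot <- annotate_proteins(make_hits("gA_p03", "cas1"))
  loci <- assemble_neighborhoods(genes, annot, flank = 1L)
  expect_equal(c(loci$rank_from, loci$rank_to), c(2L, 4L))
  trimmed <- trim_boundaries(loci, genes)
  expect_equal(c(trimmed$rank_from, trimmed$rank_to), c(1L, 4L))
  # a directon-bounded locus is a fixpoint
  again <- trim_boundaries(trimmed, genes)
  expect_equal(again[, c("rank_from", "rank_to")],
               trimmed[, c("rank_from", "rank_to")])
})

test_that("a single-gene locus is unchanged by trimming", {
  genes <- make_genes(1)
  annot <- annotate_proteins(make_hits("gA_p01", "cas1"))
  loci <- assemble_neighborhoods(genes, annot)
  trimmed <- trim_boundaries(loci, genes)
  expect_equal(trimmed[, c("rank_from", "rank_to")],
               loci[, c("rank_from", "rank_to")])
})

test_that("signature-driven classification recovers the new lineages", {
  reg <- registry_2025()
  vii <- make_classified_locus(c("cas14", "cas7", "cas5", "cas6"), reg)
  expect_equal(vii$subtype, "VII")
  expect_equal(vii$cas_type, "VII")
  iiie <- make_classified_locus("cas7-11e", reg)
  expect_equal(iiie$subtype, "III-E")
  plain <- make_classified_locus(c("cas1", "cas2"), reg)
  expect_equal(plain$subtype, "unclassified")
  expect_false(plain$complete)
})

test_that("classification is invariant under gene-order reversal", {
  reg <- registry_2025()
  for (profs in list(c("cas14", "cas7", "cas5"),
                     c("cas8e@I-E", "cas7@I-E", "cas5@I-E", "cas3@I-E",
                       "cas1", "cas2"))) {
    fwd <- make_classified_locus(profs, reg)
    rev <- make_classified_locus(profs, reg, reverse = TRUE)
    expect_equal(rev$subtype, fwd$subtype)
    expect_equal(rev$complete, fwd$complete)
  }
})

test_that("completeness honours optional adaptation modules and arrays", {
  reg <- registry_2025()
  # type VII loci lack adaptation modules yet count as complete
  vii <- make_classified_locus(c("cas14", "cas7", "cas5"), reg)
  expect_true(vii$complete)
  # III-G has no array, and none is required
  iiig <- make_classified_locus(
    c("cas10@III-G", "cas7@III-G", "cas5@III-G", "csx26"), reg,
    array = FALSE)
  expect_equal(iiig$subtype, "III-G")
  expect_true(iiig$complete)
  # a required effector-core family missing means incomplete
  ie <- make_classified_locus(c("cas8e", "cas5@I-E", "cas3@I-E",
                                "cas1", "cas2"), reg)
  expect_equal(ie$subtype, "I-E")
  expect_false(ie$complete)
  expect_match(ie$incomplete_reason, "cas7")
  res <- is_complete(ie[1, ], registry = reg)
  expect_false(as.logical(res))
  expect_match(attr(res, "reason"), "cas7")
})

test_that("tied subtype evidence is surfaced as a conflict", {
  reg <- registry_2025()
  # III-C and III-H share the same inventory; tag both equally
  locus <- make_classified_locus(
    c("cas10@III-C", "cas7@III-H", "cas5", "cas11"), reg)
  expect_true(locus$subtype %in% c("III-C", "III-H"))
  expect_equal(sort(locus$conflicts[[1]]$subtype), c("III-C", "III-H"))
})
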