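test_that("expression tables round-trip with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tadj_p",
               "Mt_Medtr5g099060\t7.42\t0.000",
               "Mt_Medtr5g030920\t0.60\t0.002",
               "Mt_Medtr1g006690\t-0.19\t0.665"), path)
  rec <- read_expression_table(path, "Mt")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$log2fc[rec$gene_id == "Mt_Medtr5g099060"], 7.42)
  expect_equal(rec$adj_p[rec$gene_id == "Mt_Medtr5g099060"], 0)
  expect_true(all(rec$species_id == "Mt"))
})

test_that("malformed expression tables are rejected or reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tadj_p", "Mt_a\t1.0\t1.5"), path)
  expect_error(read_expression_table(path, "Mt"), "Mt_a")

  writeLines(c("gene_id\tlog2fc\tadj_p", "Mt_a\t1.0\t0.1", "Mt_a\t2.0\t0.2"),
             path)
  expect_error(read_expression_table(path, "Mt"), "duplicate")

  writeLines(c("gene_id\tlog2fc\tadj_p", "Mt_a\tbroken\t0.1", "Mt_b\t2.0\t0.2"),
             path)
  expect_warning(rec <- read_expression_table(path, "Mt"), "skipped")
  expect_equal(rec$gene_id, "Mt_b")

  expect_error(read_expression_table(file.path(tempdir(), "nope.tsv"), "Mt"),
               "not found")
})

test_that("tissue-specific normalization follows the genome-wide convention", {
  rec <- expression_records(c("Mt_full", "Mt_nodspec_p"), "Mt",
                            c(2.5, NA), c(0.01, 0.03))
  status <- data.frame(
    gene_id = c("Mt_unexp", "Mt_nodspec", "Mt_rootspec", "Mt_nodspec_p"),
    status = c("unexpressed", "nodule_specific", "root_specific",
               "nodule_specific"))
  out <- normalize_tissue_specific(rec, status)
  get <- function(g) unlist(out[out$gene_id == g, c("log2fc", "adj_p")])
  expect_equal(unname(get("Mt_unexp")), c(0, 1))
  expect_equal(unname(get("Mt_nodspec")), c(15, 1))
  expect_equal(unname(get("Mt_rootspec")), c(-15, 1))
  # already-provided values are kept: fold change imputed, p respected
  expect_equal(unname(get("Mt_nodspec_p")), c(15, 0.03))
  # fully specified records come back unchanged
  expect_equal(unname(get("Mt_full")), c(2.5, 0.01))
})

test_that("conflicting tissue-specific flags are fatal", {
  rec <- expression_records(character(), character(), numeric(), numeric())
  status <- data.frame(gene_id = c("Mt_x", "Mt_x"),
                       status = c("nodule_specific", "root_specific"))
  expect_error(normalize_tissue_specific(rec, status),
               "both nodule- and root-specific")
})

test_that("codon alignments are parsed, validated, and round-tripped", {
  aln <- codon_alignment(c(A = "ATGGCTAAA", B = "ATGGCTAAA"))
  expect_equal(aln$n_codons, 3L)
  expect_false(anyNA(aln$states))
  expect_equal(aln$states["A", ], aln$states["B", ])

  expect_error(codon_alignment(c(A = "ATGTAAGCT", B = "ATGGCTGCT")),
               "stop codon TAA in taxon A at codon 2")
  expect_error(codon_alignment(c(A = "ATGGCT", B = "ATG")), "ragged")
  expect_error(codon_alignment(c(A = "ATGG", B = "ATGG")), "divisible by 3")
  expect_error(codon_alignment(c(A = "ATG", A = "ATG")), "duplicate")

  miss <- codon_alignment(c(A = "ATGNNNGCT", B = "ATG---GCT"))
  expect_true(is.na(miss$states["A", 2]))
  expect_true(is.na(miss$states["B", 2]))
  expect_false(anyNA(miss$states[, c(1, 3)]))

  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_fasta(miss, path)
  back <- read_codon_fasta(path)
  expect_identical(back$states, miss$states)
})

test_that("newick trees are read, validated, and round-tripped", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_newick(path)
  expect_equal(ape::Ntip(tree), 3L)

  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, out)
  back <- read_newick(out)
  expect_true(ape::all.equal.phylo(tree, back, use.edge.length = TRUE))
  expect_equal(sort(back$edge.length), sort(tree$edge.length), tolerance = 1e-12)

  writeLines("((A:1,A:1):1,C:2);", path)
  expect_error(read_newick(path), "duplicate tip")

  writeLines("((A,B),C);", path)
  expect_warning(t2 <- read_newick(path), "branch lengths")
  expect_true(all(t2$edge.length == 0.1))

  writeLines("((A:1,B:1:1,C:2);", path)
  expect_error(read_newick(path))
})

test_that("configuration rejects invalid thresholds", {
  expect_error(rns_config(sh_alpha = 1.5))
  expect_error(rns_config(n_perm = 0))
  expect_error(rns_config(fc_cutoff = -1))
  cfg <- rns_config()
  expect_equal(unname(cfg$p_cutoffs[c("Ct", "Dg", "Mt")]),
               c(0.005, 0.001, 0.001))
})
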