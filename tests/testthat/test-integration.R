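# Target filtering, inverse-direction attribution, mRNA-concordance
# elimination and the multi-target summary.

test_that("filter_targets applies probability, region and validation rules", {
  tab <- data.frame(
    mirna_id = "hsa-miR-x", gene_symbol = c("A", "B", "C", "D"),
    binding_probability = c(0.97, 0.94, 0.99, 0.99),
    region = c("3UTR", "3UTR", "5UTR", "3UTR"),
    validated = c(TRUE, TRUE, TRUE, FALSE),
    source = NA_character_, stringsAsFactors = FALSE)
  out <- filter_targets(tab)
  expect_identical(out$gene_symbol, "A")
  # threshold is inclusive
  tab$binding_probability <- 0.95
  expect_identical(nrow(filter_targets(tab[1, ])), 1L)
  # validated_only can be relaxed
  expect_setequal(filter_targets(tab, validated_only = FALSE)$gene_symbol,
                  c("A", "B", "D"))
})

test_that("inverse_hits emits strict sign-opposition hits per fraction", {
  priority <- data.frame(
    mirna_id = c("hsa-miR-509-5p", "hsa-miR-21-5p"),
    comparison = "TvN", fold_change = c(-1.85, 6.89),
    p_value = c(1.3e-3, 1.58e-2), stringsAsFactors = FALSE)
  targets <- data.frame(
    mirna_id = c("hsa-miR-509-5p", "hsa-miR-21-5p"),
    gene_symbol = c("COTL1", "DDAH1"), binding_probability = 0.99,
    region = "3UTR", validated = TRUE, source = NA_character_,
    stringsAsFactors = FALSE)
  protein_de <- data.frame(
    gene_symbol = c("COTL1", "DDAH1", "DDAH1"),
    comparison = c("TvN", "TvN", "F1vT"),
    fraction = c("membrane", "membrane", "cytosolic"),
    fold_change = c(2.23, -2.13, 4.16),
    p_value = c(3.83e-2, 1.92e-3, 3.84e-4), stringsAsFactors = FALSE)
  hits <- inverse_hits(priority, targets, protein_de)
  expect_identical(nrow(hits), 2L)
  expect_true(all(sign(hits$mirna_fc) * sign(hits$protein_fc) < 0))
  cotl1 <- hits[hits$gene_symbol == "COTL1", ]
  expect_identical(cotl1$comparison, "TvN")
  expect_identical(cotl1$fraction, "membrane")
  # miRNA up and protein up in the same comparison: no hit (the F1vT
  # DDAH1 +4.16 entry is judged against the borrowed +6.89 and rejected)
  expect_false(any(hits$gene_symbol == "DDAH1" & hits$comparison == "F1vT"))
  # strict same-comparison mode drops cross-comparison candidates entirely
  same <- inverse_hits(priority, targets, protein_de,
                       comparison_match = "same")
  expect_identical(same[, 1:6], hits[, 1:6])
})

test_that("cross-comparison borrowing only applies when the miRNA is not DE there", {
  priority <- data.frame(
    mirna_id = c("hsa-miR-222-3p", "hsa-miR-222-3p", "hsa-miR-206"),
    comparison = c("TvN", "F1vT", "F1vT"),
    fold_change = c(1.99, 2.27, 26.01),
    p_value = c(7.1e-3, 2.41e-2, 8.59e-5), stringsAsFactors = FALSE)
  targets <- data.frame(
    mirna_id = c("hsa-miR-222-3p", "hsa-miR-206"),
    gene_symbol = c("SOD2", "SLC25A22"), binding_probability = 0.99,
    region = "3UTR", validated = TRUE, source = NA_character_,
    stringsAsFactors = FALSE)
  protein_de <- data.frame(
    gene_symbol = c("SOD2", "SOD2", "SLC25A22"),
    comparison = c("TvN", "F1vT", "TvN"),
    fraction = "membrane", fold_change = c(2.29, -4.84, -2.77),
    p_value = c(5.88e-3, 5.06e-6, 1.19e-2), stringsAsFactors = FALSE)
  hits <- inverse_hits(priority, targets, protein_de)
  # SOD2 TvN (+2.29) is judged against the TvN FC (+1.99): same sign, no hit
  expect_false(any(hits$gene_symbol == "SOD2" & hits$comparison == "TvN"))
  expect_true(any(hits$gene_symbol == "SOD2" & hits$comparison == "F1vT"))
  # miR-206 is DE only in F1vT; its TvN protein entry borrows the F1vT FC
  slc <- hits[hits$gene_symbol == "SLC25A22", ]
  expect_identical(slc$comparison, "TvN")
  expect_equal(slc$mirna_fc, 26.01)
  # strict mode refuses the borrowed match
  same <- inverse_hits(priority, targets, protein_de,
                       comparison_match = "same")
  expect_false(any(same$gene_symbol == "SLC25A22"))
})

test_that("inverse_hits equals the brute-force triple-loop oracle", {
  for (seed in 1:12) {
    inp <- random_integration_inputs(seed)
    for (mode in c("either", "same")) {
      got <- inverse_hits(inp$priority, inp$targets, inp$protein_de,
                          comparison_match = mode)
      oracle <- inverse_hits_oracle(inp$priority, inp$targets,
                                    inp$protein_de, comparison_match = mode)
      expect_equal(nrow(got), nrow(oracle))
      if (nrow(got) > 0) {
        expect_identical(got$mirna_id, oracle$mirna_id)
        expect_identical(got$gene_symbol, oracle$gene_symbol)
        expect_identical(got$comparison, oracle$comparison)
        expect_identical(got$fraction, oracle$fraction)
        expect_equal(got$mirna_fc, oracle$mirna_fc)
        expect_equal(got$protein_fc, oracle$protein_fc)
      }
    }
  }
})

test_that("mRNA concordance keeps absent/discordant and removes concordant", {
  hits <- data.frame(
    mirna_id = "hsa-miR-x", gene_symbol = c("A", "B", "C"),
    comparison = "TvN", fraction = "membrane",
    mirna_fc = -2, protein_fc = c(2.0, 2.0, 2.0), protein_p = 0.01,
    mrna_status = "absent", stringsAsFactors = FALSE)
  mrna <- data.frame(gene_symbol = c("A", "C", "B"),
                     comparison = c("TvN", "TvN", "F1vT"),
                     fold_change = c(1.8, -1.6, 1.8),
                     p_value = 0.01, stringsAsFactors = FALSE)
  out <- mrna_concordance_filter(hits, mrna)
  # A concordant (removed); B has no TvN entry (absent); C discordant
  expect_setequal(out$gene_symbol, c("B", "C"))
  expect_identical(out$mrna_status[out$gene_symbol == "B"], "absent")
  expect_identical(out$mrna_status[out$gene_symbol == "C"], "discordant")
  eliminated <- attr(out, "eliminated")
  expect_identical(eliminated$gene_symbol, "A")
  expect_identical(eliminated$mrna_status, "concordant")
  expect_false(any(out$mrna_status == "concordant"))
})

test_that("multi_target_summary counts distinct genes across fractions", {
  hits <- data.frame(
    mirna_id = c("hsa-miR-a", "hsa-miR-a", "hsa-miR-b", "hsa-miR-b"),
    gene_symbol = c("G1", "G1", "G1", "G2"),
    comparison = "TvN", fraction = c("membrane", "cytosolic",
                                     "membrane", "membrane"),
    mirna_fc = 2, protein_fc = -2, protein_p = 0.01,
    mrna_status = "absent", stringsAsFactors = FALSE)
  out <- multi_target_summary(hits)
  # miR-a hits the same gene in two fractions: one distinct protein only
  expect_identical(out$mirna_id, "hsa-miR-b")
  expect_identical(out$n_distinct_proteins, 2L)
  low <- multi_target_summary(hits, min_proteins = 1)
  expect_identical(low$n_distinct_proteins[low$mirna_id == "hsa-miR-a"], 1L)
  empty <- multi_target_summary(hits[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("the published-cohort fixtures yield the seven multi-target miRNAs", {
  priority <- read_priority_table(fixture_path("pdac_priority_mirna.tsv"))
  targets <- filter_targets(
    read_target_table(fixture_path("pdac_target_predictions.tsv")))
  protein_de <- read_protein_de_table(fixture_path("pdac_protein_de.tsv"))
  hits <- inverse_hits(priority, targets, protein_de)
  summary <- multi_target_summary(hits)
  expected <- c("hsa-miR-2467-3p" = 6L, "hsa-miR-222-3p" = 4L,
                "hsa-miR-4534" = 3L, "hsa-miR-4742-5p" = 3L,
                "hsa-miR-509-5p" = 3L, "hsa-miR-206" = 2L,
                "hsa-miR-615-3p" = 2L)
  expect_identical(nrow(summary), 7L)
  expect_identical(
    setNames(summary$n_distinct_proteins, summary$mirna_id)[names(expected)],
    expected)
})
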