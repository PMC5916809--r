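maf_fix <- function() {
  data.frame(
    Tumor_Sample_Barcode = c("S1", "S1", "S2", "S3", "S3", "S4", "S5"),
    Hugo_Symbol = c("DRV1", "OTHER", "DRV1", "DRV2", "MSH2", "DRV1", "OTHER"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Silent", "Missense_Mutation",
                               "Nonsense_Mutation", "Missense_Mutation",
                               "3'UTR"),
    is_driver = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("alteration profiles honour variant classes and driver flags", {
  fus <- data.frame(sample_id = c("S4", "S6"), gene5 = c("X", "DRV2"),
                    gene3 = c("DRV1", "Y"), stringsAsFactors = FALSE)
  prof <- build_alteration_profiles(maf_fix(), fus, c("DRV1", "DRV2"),
                                    samples = paste0("S", 1:6))
  p <- function(s) prof[prof$sample_id == s, ]
  # S1: curated missense driver mutation, no fusion
  expect_true(p("S1")$has_driver_mutation)
  expect_true(p("S1")$has_driver_gene_mutation)
  expect_false(p("S1")$has_driver_fusion)
  # S2: only a silent mutation in a driver gene (class not counted)
  expect_false(p("S2")$has_driver_gene_mutation)
  # S3: non-curated driver-gene missense; MSH2 nonsense marks MMR
  expect_true(p("S3")$has_driver_gene_mutation)
  expect_false(p("S3")$has_driver_mutation)
  expect_true(p("S3")$mmr_mutated)
  # n_mutations counts every MAF row
  expect_equal(p("S1")$n_mutations, 2)
  expect_equal(p("S6")$n_mutations, 0)
  # invariant: curated driver mutation implies driver-gene mutation
  expect_true(all(!prof$has_driver_mutation | prof$has_driver_gene_mutation))
  expect_error(build_alteration_profiles(maf_fix()[, -3], fus, "DRV1"),
               "Variant_Classification")
})

test_that("driver groups partition the cohort", {
  prof <- data.frame(
    sample_id = paste0("S", 1:6),
    has_driver_mutation = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    has_driver_gene_mutation = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    has_driver_fusion = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    n_mutations = 1:6, mmr_mutated = FALSE, stringsAsFactors = FALSE)
  grp <- classify_driver_group(prof)
  expect_equal(grp, c("DRIVER_MUT_ONLY", "MUT_ONLY", "DRIVER_MUT_AND_FUSION",
                      "MUT_AND_FUSION", "FUSION_ONLY", "NONE"))
  # partition property on the generator cohort
  rep <- shared_report()
  expect_equal(length(rep$driver_groups), nrow(rep$profiles))
  expect_equal(sum(table(rep$driver_groups)), nrow(rep$profiles))
})

test_that("burden comparison matches the exact U distribution for small groups", {
  prof <- data.frame(
    sample_id = paste0("S", 1:6),
    has_driver_mutation = FALSE, has_driver_gene_mutation = FALSE,
    has_driver_fusion = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    n_mutations = c(1, 2, 3, 10, 11, 12),
    mmr_mutated = FALSE, stringsAsFactors = FALSE)
  res <- burden_comparison(prof, "FUSION_ONLY", "NONE")
  # fully separated groups of 3: exact two-sided p = 2 / choose(6, 3)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_mw_p(c(1, 2, 3), c(10, 11, 12)))

  # random small groups, distinct values: exact match with brute force
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- sample(1:1000, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    p2 <- data.frame(sample_id = seq_along(v),
                     has_driver_mutation = FALSE,
                     has_driver_gene_mutation = FALSE,
                     has_driver_fusion = c(rep(TRUE, n1), rep(FALSE, n2)),
                     n_mutations = v, mmr_mutated = FALSE)
    expect_equal(burden_comparison(p2, "FUSION_ONLY", "NONE")$p_value,
                 oracle_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("MMR-mutated hypermutators are excluded before the burden test", {
  prof <- data.frame(
    sample_id = paste0("S", 1:7),
    has_driver_mutation = FALSE, has_driver_gene_mutation = FALSE,
    has_driver_fusion = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    n_mutations = c(1, 2, 3, 10, 11, 12, 5000),
    mmr_mutated = c(rep(FALSE, 6), TRUE), stringsAsFactors = FALSE)
  res <- burden_comparison(prof, "FUSION_ONLY", "NONE")
  expect_equal(res$n_b, 3)  # the hypermutator is gone
  expect_error(burden_comparison(prof[7, , drop = FALSE], "FUSION_ONLY",
                                 "NONE"), "empty group")
})

test_that("exclusivity matrix distinguishes fusion, mutation, both", {
  fus <- data.frame(sample_id = c("S1", "S2"), gene5 = c("ESR1x", "G2"),
                    gene3 = c("G9", "ESR1x"), stringsAsFactors = FALSE)
  maf <- data.frame(Tumor_Sample_Barcode = c("S2", "S3"),
                    Hugo_Symbol = c("ESR1x", "ESR1x"),
                    Variant_Classification = "Missense_Mutation",
                    is_driver = FALSE, stringsAsFactors = FALSE)
  m <- exclusivity_matrix(fus, maf, c("ESR1x", "G9"))
  expect_equal(m["ESR1x", "S1"], "FUSION")
  expect_equal(m["ESR1x", "S2"], "BOTH")
  expect_equal(m["ESR1x", "S3"], "MUTATION")
  expect_equal(m["G9", "S3"], "NONE")
  expect_equal(dim(exclusivity_matrix(fus, maf, character(0))), c(0, 0))
})

test_that("druggability matching respects partners and label status", {
  drugs <- data.frame(
    gene = c("TMPRSS2x", "PMLx", "RETx"),
    partner = c(NA, "RARAx", NA),
    cancer_type = "*",
    drug = c("d1", "d2", "d3"),
    label = c("ON_LABEL", "ON_LABEL", "OFF_LABEL"), stringsAsFactors = FALSE)
  fus <- data.frame(
    sample_id = c("P1", "P2", "P3", "P4"),
    gene5 = c("TMPRSS2x", "PMLx", "PMLx", "X"),
    gene3 = c("ERGx", "RARAx", "OTHER", "RETx"),
    call_id = paste0("C", 1:4), stringsAsFactors = FALSE)
  res <- annotate_druggable(fus, drugs)
  expect_setequal(res$matches$sample_id, c("P1", "P2", "P4"))
  expect_true(res$sample_druggable$druggable[
    res$sample_druggable$sample_id == "P1"])
  # pair-restricted entry does not match PML--OTHER
  expect_false("P3" %in% res$matches$sample_id)
  # off-label excluded on demand, and on-label-only is a subset
  on <- annotate_druggable(fus, drugs, allow_off_label = FALSE)
  expect_false("P4" %in% on$matches$sample_id)
  expect_true(all(on$matches$sample_id %in% res$matches$sample_id))
})

test_that("smoking chi-square reproduces the printed contingency result", {
  # 15 druggable of 75 never-smokers vs 9 of 425 smokers
  tab <- matrix(c(15, 60, 9, 416), nrow = 2, byrow = TRUE,
                dimnames = list(smoking = c("never", "ever"),
                                druggable = c("yes", "no")))
  res <- smoking_association(tab)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$statistic, 0)

  # identical proportions: statistic 0, p = 1
  flat <- matrix(c(10, 90, 20, 180), nrow = 2, byrow = TRUE)
  res2 <- smoking_association(flat)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)

  # zero margin: NA with a warning
  degen <- matrix(c(0, 100, 0, 50), nrow = 2, byrow = TRUE)
  expect_warning(res3 <- smoking_association(degen), "zero margin")
  expect_true(is.na(res3$p_value))

  # vector interface
  dr <- c(rep(TRUE, 5), rep(FALSE, 45), rep(TRUE, 2), rep(FALSE, 48))
  sm <- c(rep("never", 50), rep("ever", 50))
  expect_true(is.finite(smoking_association(dr, sm)$p_value))
})
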