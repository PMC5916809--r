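locus <- function(region, off = NA_integer_, aa = NA_integer_) {
  structure(list(region = region, cds_offset = as.integer(off),
                 aa_pos = as.integer(aa),
                 codon_phase = if (is.na(off)) NA_integer_ else
                   as.integer(off %% 3)),
            class = "transcript_locus")
}

dom_fix <- data.frame(gene = c("KIN", "KIN2", "MULTI", "MULTI"),
                      domain = c("kd", "kd", "kd1", "kd2"),
                      aa_start = c(50, 40, 50, 200),
                      aa_end = c(120, 100, 120, 260),
                      stringsAsFactors = FALSE)
kin_fix <- data.frame(gene = c("KIN", "KIN2", "MULTI"),
                      group = c("TK", "AGC", "CMGC"),
                      stringsAsFactors = FALSE)

test_that("breakpoint pairs classify into the category taxonomy", {
  expect_equal(classify_breakpoint_pair(locus("CDS", 9, 4), locus("CDS", 0, 1)),
               c("CDS", "CDS"))
  expect_equal(classify_breakpoint_pair(locus("FIVE_UTR"), locus("FIVE_UTR")),
               c("FIVE_UTR", "FIVE_UTR"))
  expect_equal(classify_breakpoint_pair(locus("CDS", 3, 2), locus("INTRON")),
               c("CDS", "NONCODING"))
  expect_equal(classify_breakpoint_pair(locus("NONCODING"), locus("THREE_UTR")),
               c("NONCODING", "THREE_UTR"))
})

test_that("frame prediction follows the mod-3 offset rule", {
  expect_equal(predict_frame(locus("CDS", 6), locus("CDS", 0)), "INFRAME")
  expect_equal(predict_frame(locus("CDS", 7), locus("CDS", 4)), "INFRAME")
  expect_equal(predict_frame(locus("CDS", 7), locus("CDS", 3)), "FRAMESHIFT")
  expect_equal(predict_frame(locus("CDS", 5), locus("FIVE_UTR")), "NO_FRAME")
  expect_equal(predict_frame(locus("INTRON"), locus("CDS", 3)), "NO_FRAME")
})

test_that("frame prediction matches translation of a concatenated toy CDS", {
  set.seed(7)
  sense <- names(oracle_codons)[oracle_codons != "*"]
  cds5 <- paste0("ATG", paste(sample(sense, 30, replace = TRUE),
                              collapse = ""), "TAA")
  cds3 <- paste0("ATG", paste(sample(sense, 30, replace = TRUE),
                              collapse = ""), "TAA")
  wt3 <- oracle_translate(cds3)
  tail8 <- substr(wt3, nchar(wt3) - 7, nchar(wt3))
  for (case in list(c(7, 4), c(7, 3), c(9, 6), c(10, 5))) {
    r <- case[1]; d <- case[2]
    fused <- paste0(substr(cds5, 1, r), substr(cds3, d + 1, nchar(cds3)))
    frame <- predict_frame(locus("CDS", r), locus("CDS", d))
    expect_equal(endsWith(oracle_translate(fused), tail8),
                 frame == "INFRAME", info = paste(r, d))
  }
})

test_that("kinase domain retention follows the positional rules", {
  # 5'-kinase: retained through the domain end, or breakpoint in 3' UTR
  expect_equal(assess_domain_retention("KIN", "five",
                                       locus("CDS", 360, 120), locus("CDS", 0, 1),
                                       "INFRAME", dom_fix), "INTACT")
  expect_equal(assess_domain_retention("KIN", "five",
                                       locus("THREE_UTR"), locus("CDS", 0, 1),
                                       "NO_FRAME", dom_fix), "INTACT")
  # inside the domain: disrupted
  expect_equal(assess_domain_retention("KIN", "five",
                                       locus("CDS", 240, 80), locus("CDS", 0, 1),
                                       "INFRAME", dom_fix), "DISRUPTED")
  # 5'-kinase retention ignores the 3' partner's frame
  expect_equal(assess_domain_retention("KIN", "five",
                                       locus("CDS", 361, 121), locus("CDS", 0, 1),
                                       "FRAMESHIFT", dom_fix), "INTACT")

  # 3'-kinase: promoter swap keeps the whole ORF
  expect_equal(assess_domain_retention("KIN", "three",
                                       locus("FIVE_UTR"), locus("FIVE_UTR"),
                                       "NO_FRAME", dom_fix), "INTACT")
  # upstream of the domain and in frame: intact; frameshift: disrupted
  expect_equal(assess_domain_retention("KIN", "three",
                                       locus("CDS", 9, 4), locus("CDS", 30, 11),
                                       "INFRAME", dom_fix), "INTACT")
  expect_equal(assess_domain_retention("KIN", "three",
                                       locus("CDS", 9, 4), locus("CDS", 31, 11),
                                       "FRAMESHIFT", dom_fix), "DISRUPTED")
  # boundary-inclusive: residue exactly at aa_start / aa_end retains
  expect_equal(assess_domain_retention("KIN", "three",
                                       locus("CDS", 9, 4),
                                       locus("CDS", 147, 50),
                                       "INFRAME", dom_fix), "INTACT")
  expect_equal(assess_domain_retention("KIN", "five",
                                       locus("CDS", 360, 120),
                                       locus("CDS", 0, 1),
                                       "INFRAME", dom_fix), "INTACT")
  # any of several domains intact suffices
  expect_equal(assess_domain_retention("MULTI", "five",
                                       locus("CDS", 450, 150),
                                       locus("CDS", 0, 1),
                                       "INFRAME", dom_fix), "INTACT")
  expect_error(assess_domain_retention("ABSENT", "five", locus("CDS", 3, 1),
                                       locus("CDS", 0, 1), "INFRAME", dom_fix),
               "missing from the domain table")
})

test_that("kinase role classification resolves both-kinase fusions", {
  none <- classify_kinase_role("A", "B", locus("CDS", 9, 4), locus("CDS", 0, 1),
                               "INFRAME", kin_fix, dom_fix)
  expect_equal(none$role, "NONE")
  expect_equal(none$domain_status, "NA")

  three <- classify_kinase_role("A", "KIN", locus("CDS", 9, 4),
                                locus("CDS", 30, 11), "INFRAME",
                                kin_fix, dom_fix)
  expect_equal(three$role, "THREE_KINASE")
  expect_equal(three$group, "TK")
  expect_equal(three$domain_status, "INTACT")

  # both partners kinases, only the 3' domain intact -> reassigned 3'
  both3 <- classify_kinase_role("KIN2", "KIN",
                                locus("CDS", 150, 50),   # inside KIN2 domain
                                locus("CDS", 30, 11), "INFRAME",
                                kin_fix, dom_fix)
  expect_equal(both3$role, "THREE_KINASE")
  # only the 5' domain intact -> reassigned 5'
  both5 <- classify_kinase_role("KIN2", "KIN",
                                locus("CDS", 330, 110),  # past KIN2 domain end
                                locus("CDS", 400, 134),  # inside KIN domain
                                "INFRAME", kin_fix, dom_fix)
  expect_equal(both5$role, "FIVE_KINASE")
  # neither intact -> stays BOTH
  both0 <- classify_kinase_role("KIN2", "KIN",
                                locus("CDS", 150, 50), locus("CDS", 400, 134),
                                "INFRAME", kin_fix, dom_fix)
  expect_equal(both0$role, "BOTH_KINASE")
})

test_that("3'-kinase retention is monotone as the breakpoint moves 5'", {
  state <- vapply(seq(60, 1, by = -1), function(aa)
    assess_domain_retention("KIN", "three", locus("CDS", 9, 4),
                            locus("CDS", (aa - 1) * 3, aa), "INFRAME",
                            dom_fix), character(1))
  # once intact (aa <= 50), never flips back while moving further 5'
  flips <- which(diff(state == "INTACT") < 0)
  expect_length(flips, 0)
  expect_true(any(state == "INTACT"))
  expect_true(any(state == "DISRUPTED"))
})

test_that("annotated generator fusions recover every truth label", {
  st <- shared_study()
  rep <- shared_report()
  tr <- st$truth$records
  a <- rep$annotated
  idx <- truth_index(a, tr)
  squash <- function(x) ifelse(x %in% c("INTRON", "NONCODING"), "NONCODING", x)
  expect_identical(a$frame, tr$frame_truth[idx])
  expect_identical(a$region5, squash(tr$region5[idx]))
  expect_identical(a$region3, squash(tr$region3[idx]))
  expect_identical(a$kinase_role, tr$kinase_role_truth[idx])
  expect_identical(a$domain_status, tr$domain_truth[idx])
})

test_that("normalized kinase-group percentages behave as defined", {
  # equal pan-cancer shares: normalization cancels
  m <- rbind(TCA = c(A = 4, B = 6), TCB = c(A = 6, B = 4))
  res <- normalized_group_percentages(rbind(TCA = c(A = 5, B = 5),
                                            TCB = c(A = 5, B = 5)))
  expect_equal(unname(res$percentages["TCA", ]), c(50, 50))
  raw <- normalized_group_percentages(m)
  expect_equal(unname(raw$percentages["TCA", ]), c(40, 60))

  # hand-computed example: pan-cancer 30 vs 10 => p = .75/.25;
  # one cancer type with 3 and 1 normalizes to 4 and 4 => 50/50
  m2 <- rbind(C1 = c(G1 = 3, G2 = 1), C2 = c(G1 = 27, G2 = 9))
  res2 <- normalized_group_percentages(m2)
  expect_equal(unname(res2$p_g), c(0.75, 0.25))
  expect_equal(unname(res2$percentages["C1", ]), c(50, 50))

  # absent group dropped, remainder renormalizes to 100
  m3 <- rbind(C1 = c(G1 = 3, G2 = 0, G3 = 1), C2 = c(G1 = 9, G2 = 0, G3 = 3))
  res3 <- normalized_group_percentages(m3)
  expect_false("G2" %in% colnames(res3$percentages))
  expect_equal(unname(rowSums(res3$percentages)), c(100, 100))

  # zero-fusion cancer type omitted with a warning
  m4 <- rbind(C1 = c(G1 = 2, G2 = 2), C2 = c(G1 = 0, G2 = 0))
  expect_warning(res4 <- normalized_group_percentages(m4), "omitted")
  expect_equal(rownames(res4$percentages), "C1")
  expect_error(normalized_group_percentages(m4 * 0), "positive")
})
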