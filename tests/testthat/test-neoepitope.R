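# Two single-exon toy genes with known sequences for translation tests.
toy_pair <- function(seed = 13, n_codons5 = 40, n_codons3 = 40) {
  set.seed(seed)
  sense <- names(oracle_codons)[oracle_codons != "*"]
  mk <- function(sym, chrom, n_codons, offset) {
    utr5 <- 12; utr3 <- 9
    cds <- paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                               collapse = ""), "TAA")
    len <- utr5 + nchar(cds) + utr3
    model <- gene_model(sym, sym, chrom, "+",
                        exons = rbind(c(offset, offset + len)),
                        cds_start = offset + utr5,
                        cds_end = offset + utr5 + nchar(cds))
    seq <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                        collapse = ""), cds,
                  paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
                        collapse = ""))
    list(model = model, seq = seq, cds = cds, utr5 = utr5, offset = offset)
  }
  g5 <- mk("FX5", "chr1", n_codons5, 1000)
  g3 <- mk("FX3", "chr2", n_codons3, 5000)
  list(models = list(FX5 = g5$model, FX3 = g3$model),
       seqs = c(FX5 = g5$seq, FX3 = g3$seq), g5 = g5, g3 = g3)
}

# 1-based genomic position of the r-th retained coding base of the 5' gene /
# the (d+1)-th coding base of the 3' gene (single-exon plus-strand toys).
pos5_for <- function(g, r) g$offset + g$utr5 + r
pos3_for <- function(g, d) g$offset + g$utr5 + d + 1

test_that("inframe fusion translation matches the codon-table oracle", {
  tp <- toy_pair()
  r <- 21; d <- 9  # both on codon boundaries
  fus <- list(gene5 = "FX5", gene3 = "FX3",
              pos5 = pos5_for(tp$g5, r), pos3 = pos3_for(tp$g3, d))
  fp <- translate_fusion(fus, tp$models, tp$seqs)
  expect_equal(fp$frame, "INFRAME")
  expect_false(fp$novel_tail)
  oracle <- oracle_translate(paste0(substr(tp$g5$cds, 1, r),
                                    substr(tp$g3$cds, d + 1,
                                           nchar(tp$g3$cds))))
  expect_equal(fp$sequence, oracle)
  expect_equal(fp$junction_index, 7)
  # suffix equals the wild-type 3' protein suffix
  wt3 <- oracle_translate(tp$g3$cds)
  expect_equal(substr(fp$sequence, 8, nchar(fp$sequence)),
               substr(wt3, 4, nchar(wt3)))
})

test_that("frameshift products diverge from wild type at every tail position", {
  tp <- toy_pair()
  r <- 21; d <- 13  # offsets differ by 2 mod 3
  fus <- list(gene5 = "FX5", gene3 = "FX3",
              pos5 = pos5_for(tp$g5, r), pos3 = pos3_for(tp$g3, d))
  fp <- translate_fusion(fus, tp$models, tp$seqs)
  expect_equal(fp$frame, "FRAMESHIFT")
  expect_true(fp$novel_tail)
  oracle <- oracle_translate(paste0(substr(tp$g5$cds, 1, r),
                                    substr(tp$g3$cds, d + 1,
                                           nchar(tp$g3$cds))))
  expect_equal(fp$sequence, oracle)
  wt3 <- oracle_translate(tp$g3$cds)
  tail_fus <- substr(fp$sequence, fp$junction_index + 1, nchar(fp$sequence))
  tail_wt <- substr(wt3, d %/% 3 + 2, nchar(wt3))
  k <- min(nchar(tail_fus), nchar(tail_wt))
  expect_gte(k, 3)
  same <- strsplit(substr(tail_fus, 1, k), "")[[1]] ==
    strsplit(substr(tail_wt, 1, k), "")[[1]]
  expect_lt(mean(same), 0.3)  # random codon coincidences only
})

test_that("a 5'UTR swap yields the intact wild-type 3' protein", {
  tp <- toy_pair()
  fus <- list(gene5 = "FX5", gene3 = "FX3",
              pos5 = tp$g5$offset + 5,  # inside 5' UTR of FX5
              pos3 = tp$g3$offset + 5)  # inside 5' UTR of FX3
  fp <- translate_fusion(fus, tp$models, tp$seqs)
  expect_equal(fp$sequence, oracle_translate(tp$g3$cds))
  expect_equal(fp$junction_index, 0L)
  expect_false(fp$novel_tail)
  # any other no-frame configuration has no start codon
  bad <- list(gene5 = "FX5", gene3 = "FX3",
              pos5 = pos5_for(tp$g5, 9),
              pos3 = tp$g3$offset + tp$g3$utr5 + nchar(tp$g3$cds) + 3)
  expect_error(translate_fusion(bad, tp$models, tp$seqs), "no ATG context")
})

test_that("junction peptide enumeration matches the exhaustive scan", {
  prot <- function(seq, j, tail = FALSE)
    structure(list(sequence = seq, junction_index = j, novel_tail = tail,
                   frame = if (tail) "FRAMESHIFT" else "INFRAME"),
              class = "fusion_protein")
  long <- paste(rep(LETTERS[1:20], 5), collapse = "")
  # central junction: (L-1) windows per length, 7+8+9+10 = 34
  p <- prot(long, 50)
  expect_length(enumerate_junction_peptides(p), 34)
  expect_identical(enumerate_junction_peptides(p),
                   oracle_junction_peptides(long, 50, FALSE))
  # junction 3 residues from the N-terminus: flank-limited counts
  p3 <- prot(long, 3)
  expect_identical(enumerate_junction_peptides(p3),
                   oracle_junction_peptides(long, 3, FALSE))
  expect_length(enumerate_junction_peptides(p3), 12)
  # novel tail adds all tail windows
  pt <- prot(long, 50, tail = TRUE)
  expect_identical(enumerate_junction_peptides(pt),
                   oracle_junction_peptides(long, 50, TRUE))
  # truncation near the C terminus
  pe <- prot(substr(long, 1, 12), 10)
  expect_identical(enumerate_junction_peptides(pe),
                   oracle_junction_peptides(substr(long, 1, 12), 10, FALSE))
  # promoter swap: no junction residues, no peptides
  expect_length(enumerate_junction_peptides(prot(long, 0)), 0)
  # junction at the last residue: nothing spans it
  expect_length(enumerate_junction_peptides(prot(long, 100)), 0)
})

test_that("neoantigen calling filters wild type, affinity, and read support", {
  peps <- c("AAAAWWWW", "CCCCWWWW", "DDDDWWWW")
  wt <- c(paste0("MM", "AAAAWWWW", "KK"), "MKKKKKKK")
  pred <- function(peptide, allele) {
    if (peptide == "CCCCWWWW") return(100)
    if (peptide == "DDDDWWWW") return(600)
    stop("unexpected")
  }
  out <- call_neoantigens(peps, wt, pred, alleles = "HLA-A*02:01",
                          junction_reads = 10)
  expect_equal(nrow(out), 2)  # wild-type peptide excluded before prediction
  expect_false("AAAAWWWW" %in% out$peptide)
  expect_true(out$is_neoantigen[out$peptide == "CCCCWWWW"])
  expect_false(out$is_neoantigen[out$peptide == "DDDDWWWW"])
  # junction support below the threshold: no calls at all
  none <- call_neoantigens(peps, wt, pred, "HLA-A*02:01", junction_reads = 4)
  expect_equal(nrow(none), 0)
  # predictor failure degrades to NA, not an error
  bad <- function(peptide, allele) stop("model offline")
  res <- call_neoantigens("CCCCWWWW", wt, bad, "HLA-A*02:01",
                          junction_reads = 10)
  expect_true(is.na(res$affinity_nM))
  expect_false(res$is_neoantigen)
})

test_that("toy-predictor affinities give frameshift fusions more neoantigens", {
  rep <- shared_report()
  m <- rep$summary$mean_neoantigens_by_frame
  expect_true(all(c("FRAMESHIFT", "INFRAME") %in% names(m)))
  expect_gt(m[["FRAMESHIFT"]], m[["INFRAME"]])
})
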