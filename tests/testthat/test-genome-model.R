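test_that("GTF round trip transcribes plus- and minus-strand models", {
  gtf <- tempfile(fileext = ".gtf")
  attr_a <- 'gene_id "gA"; transcript_id "tA"; gene_name "A"; gene_biotype "protein_coding";'
  attr_b <- 'gene_id "gB"; transcript_id "tB"; gene_name "B"; gene_biotype "protein_coding";'
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", attr_a, sep = "\t"),
    paste("chr1", "src", "exon", 301, 400, ".", "+", ".", attr_a, sep = "\t"),
    paste("chr1", "src", "CDS", 151, 200, ".", "+", ".", attr_a, sep = "\t"),
    paste("chr1", "src", "CDS", 301, 350, ".", "+", ".", attr_a, sep = "\t"),
    paste("chr1", "src", "exon", 501, 600, ".", "-", ".", attr_b, sep = "\t"),
    paste("chr1", "src", "exon", 701, 800, ".", "-", ".", attr_b, sep = "\t")
  ), gtf)
  models <- read_gtf(gtf)
  a <- models$A
  expect_equal(nrow(a$exons), 2)
  expect_equal(a$exons, matrix(c(100, 300, 200, 400), ncol = 2))
  expect_equal(a$cds_start, 150)
  expect_equal(a$cds_end, 350)
  expect_true(a$is_coding)
  # minus strand: exons in transcript order are genomically descending
  b <- models$B
  expect_equal(b$exons[, 1], c(700, 500))
  expect_false(b$is_coding)

  # full structural round trip through the writer
  gtf2 <- tempfile(fileext = ".gtf")
  write_gtf(models, gtf2)
  again <- read_gtf(gtf2)
  expect_equal(again$A$exons, a$exons)
  expect_equal(again$B$exons, b$exons)
  expect_equal(again$A$cds_start, a$cds_start)
})

test_that("malformed GTF lines are rejected with a line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 1, 10, ".", "+", ".", sep = "\t")  # 8 fields
  ), gtf)
  expect_error(read_gtf(gtf), "line 1.*9 tab-separated")
})

test_that("canonical transcript selection prefers the longest CDS", {
  gtf <- tempfile(fileext = ".gtf")
  at1 <- 'gene_id "g"; transcript_id "t2"; gene_name "G";'
  at2 <- 'gene_id "g"; transcript_id "t1"; gene_name "G";'
  writeLines(c(
    paste("chr1", "s", "exon", 101, 400, ".", "+", ".", at1, sep = "\t"),
    paste("chr1", "s", "CDS", 101, 160, ".", "+", ".", at1, sep = "\t"),
    paste("chr1", "s", "exon", 101, 400, ".", "+", ".", at2, sep = "\t"),
    paste("chr1", "s", "CDS", 101, 220, ".", "+", ".", at2, sep = "\t")
  ), gtf)
  expect_equal(read_gtf(gtf)$G$transcript_id, "t1")
})

test_that("locate_breakpoint assigns regions and coding offsets", {
  m <- gene_model("g", "G", "chr1", "+",
                  exons = rbind(c(0, 100), c(200, 300)),
                  cds_start = 10, cds_end = 250)
  expect_equal(locate_breakpoint(m, 5)$region, "FIVE_UTR")
  l <- locate_breakpoint(m, 11)  # first CDS base
  expect_equal(l$region, "CDS")
  expect_equal(l$cds_offset, 0L)
  expect_equal(l$aa_pos, 1L)
  expect_equal(locate_breakpoint(m, 150)$region, "INTRON")
  expect_equal(locate_breakpoint(m, 260)$region, "THREE_UTR")
  expect_error(locate_breakpoint(m, 1000), "outside the span")
  # the 5' side convention counts the breakpoint base as retained
  expect_equal(locate_breakpoint(m, 11, side = "5prime")$cds_offset, 1L)
})

test_that("minus-strand coding offsets walk the exon chain 5' to 3'", {
  m <- gene_model("g", "G", "chr1", "-",
                  exons = rbind(c(200, 300), c(0, 100)),
                  cds_start = 50, cds_end = 280)
  # 5 coding bases into the CDS along the transcript: tx cds starts at
  # genomic 279 (0-based), so the 6th coding base is genomic 274 -> 1-based 275
  l <- locate_breakpoint(m, 275)
  expect_equal(l$region, "CDS")
  expect_equal(l$cds_offset, 5L)
  expect_equal(l$aa_pos, 2L)
})

test_that("non-coding models map everywhere to NONCODING", {
  m <- gene_model("g", "G", "chr1", "+", exons = rbind(c(0, 100), c(200, 300)),
                  is_coding = FALSE)
  expect_equal(locate_breakpoint(m, 50)$region, "NONCODING")
  expect_equal(locate_breakpoint(m, 150)$region, "NONCODING")
})

test_that("locate_breakpoint agrees with a brute-force exon walk", {
  ann <- shared_annotation()
  for (sym in c("KTK1", "GEN001", "PRM1")) {
    m <- ann$models[[sym]]
    # brute force: walk exons in transcript order, counting coding bases
    cb_start <- if (m$strand == "+") m$cds_start else m$cds_end - 1
    seen <- 0; coding_started <- FALSE; checked <- 0; mismatches <- 0
    for (i in seq_len(nrow(m$exons))) {
      gpos <- if (m$strand == "+") seq(m$exons[i, 1], m$exons[i, 2] - 1)
              else seq(m$exons[i, 2] - 1, m$exons[i, 1])
      for (p0 in gpos) {
        if (p0 == cb_start) coding_started <- TRUE
        l <- locate_breakpoint(m, p0 + 1)
        if (coding_started && seen < (m$cds_end - m$cds_start)) {
          if (l$region == "CDS") {
            if (l$cds_offset != seen || l$aa_pos != seen %/% 3 + 1)
              mismatches <- mismatches + 1
            checked <- checked + 1
          }
          seen <- seen + 1
        }
      }
    }
    expect_equal(mismatches, 0)
    expect_gt(checked, 100)
  }
})

test_that("mirrored (reverse-complemented) models give identical loci", {
  ann <- shared_annotation()
  m <- ann$models$KTK2
  L <- 1e7
  mirror <- gene_model(
    m$gene_id, m$symbol, m$chromosome,
    strand = if (m$strand == "+") "-" else "+",
    exons = cbind(L - m$exons[, 2], L - m$exons[, 1]),
    cds_start = L - m$cds_end, cds_end = L - m$cds_start,
    transcript_id = m$transcript_id)
  sp <- c(min(m$exons[, 1]), max(m$exons[, 2]))
  same <- vapply(seq(sp[1] + 1, sp[2], by = 37), function(pos)
    identical(unclass(locate_breakpoint(m, pos)),
              unclass(locate_breakpoint(mirror, L - pos + 1))), logical(1))
  expect_true(all(same))
})

test_that("transcript_protein translates the CDS and stops at stops", {
  m <- gene_model("g", "G", "chr1", "+", exons = rbind(c(0, 9)),
                  cds_start = 0, cds_end = 9)
  expect_equal(transcript_protein(m, "ATGAAATAG"), "MK")
  expect_equal(transcript_protein(m, "ATGTAAAAA"), "M")  # internal stop
  expect_error(transcript_protein(m, "ATGNAATAG"), "ambiguous")
  expect_error(transcript_protein(m, "ATG"), "length")

  # random 60-codon CDS equals the codon-table oracle
  set.seed(42)
  sense <- names(oracle_codons)[oracle_codons != "*"]
  cds <- paste0("ATG", paste(sample(sense, 58, replace = TRUE), collapse = ""),
                "TAA")
  m2 <- gene_model("g", "G", "chr1", "+", exons = rbind(c(0, 180)),
                   cds_start = 0, cds_end = 180)
  expect_equal(transcript_protein(m2, cds), oracle_translate(cds))
})

test_that("synthetic transcript sequences translate cleanly", {
  ann <- shared_annotation()
  for (sym in c("KAGC1", "GEN002")) {
    m <- ann$models[[sym]]
    p <- transcript_protein(m, ann$tx_seqs[[sym]])
    expect_match(p, "^M")
    cds <- transcript_cds(m, ann$tx_seqs[[sym]])
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(nchar(p), nchar(cds) / 3 - 1)  # stop codon excluded
    expect_equal(p, oracle_translate(cds))
  }
})
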