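# Independent oracles and shared fixtures. The codon table and window scans
# here are written from scratch so they never share code with the package
# paths they check.

oracle_codons <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Codon-by-codon translation, stopping at the first stop codon.
oracle_translate <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- oracle_codons[[substr(nt, 3 * i - 2, 3 * i)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# Exhaustive k-mer scan oracle for junction peptide enumeration.
oracle_junction_peptides <- function(seq, j, novel_tail, lengths = 8:11) {
  n <- nchar(seq)
  out <- character(0)
  for (L in lengths) {
    if (n < L) next
    for (s in 1:(n - L + 1)) {
      e <- s + L - 1
      spans <- j >= 1 && s <= j && e >= j + 1
      in_tail <- novel_tail && s >= j + 1
      if (spans || in_tail) out <- c(out, substr(seq, s, e))
    }
  }
  sort(unique(out))
}

# Exact Mann-Whitney two-sided p by full enumeration of group assignments,
# mirroring R's doubling rule for the two-sided p-value.
oracle_mw_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  u_obs <- u_stat(x, y)
  mu <- n1 * length(y) / 2
  p <- if (u_obs < mu) 2 * mean(us <= u_obs)
       else if (u_obs > mu) 2 * mean(us >= u_obs)
       else 1
  min(1, p)
}

# Type-7 quantile by hand (sorted-order interpolation).
oracle_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (if (lo < n) x[lo + 1] - x[lo] else 0)
}

make_sam_pair_lines <- function(qname, c1, p1, c2, p2, mapq1 = 60,
                                mapq2 = 60, flag1 = 97, flag2 = 145) {
  c(paste(qname, flag1, c1, p1, mapq1, "100M", c2, p2, 0, "*", "*",
          sep = "\t"),
    paste(qname, flag2, c2, p2, mapq2, "100M", c1, p1, 0, "*", "*",
          sep = "\t"))
}

sam_header_lines <- function(chroms = paste0("chr", 1:4), len = 5e6) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(len)))
}

# ---- shared fixtures (built once per test run) -----------------------------

.fixture_env <- new.env(parent = emptyenv())

shared_config <- function() {
  cohort_config(seed = 101L, n_samples = c(TCA = 40L, TCB = 40L),
                n_genes = 25L, carrier_fraction = 0.08)
}

shared_annotation <- function() {
  if (is.null(.fixture_env$ann))
    .fixture_env$ann <- generate_annotation(shared_config())
  .fixture_env$ann
}

shared_study <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "fusionscape-shared-study")
    .fixture_env$study <- simulate_study(shared_config(), dir)
  }
  .fixture_env$study
}

shared_report <- function() {
  if (is.null(.fixture_env$report)) {
    st <- shared_study()
    .fixture_env$report <- run_pipeline(st$paths,
                                        pipeline_config(seed = 101L))
  }
  .fixture_env$report
}

# Truth record matching a merged/kept call row.
truth_index <- function(calls, truth_records) {
  match(paste(calls$sample_id, calls$gene5, calls$gene3),
        paste(truth_records$sample_id, truth_records$gene5,
              truth_records$gene3))
}

# Canonical one-row call for filter/window tests.
make_call <- function(sample_id = "S1", gene5 = "A", gene3 = "B",
                      chrom5 = "chr1", pos5 = 1000, strand5 = "+",
                      chrom3 = "chr2", pos3 = 2000, strand3 = "+",
                      junction_reads = 10, spanning_frags = 5,
                      total_frags = 4e7, ffpm = 1,
                      callers = "STARFUSION_LIKE", cancer_type = "TCA") {
  data.frame(sample_id = sample_id, gene5 = gene5, gene3 = gene3,
             chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
             chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
             junction_reads = junction_reads,
             spanning_frags = spanning_frags, total_frags = total_frags,
             ffpm = ffpm, callers = callers, cancer_type = cancer_type,
             stringsAsFactors = FALSE)
}
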