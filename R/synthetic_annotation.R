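#' Configuration for a synthetic fusion study
#'
#' Bundles every tunable of the synthetic-data generator. Identical seed and
#' configuration give byte-identical outputs from all `simulate_*` functions.
#'
#' @param seed Integer master seed (< 2^31).
#' @param n_samples Named integer vector: samples per cancer-type label.
#' @param n_genes Number of *regular* (non-kinase, non-special) genes; kinase,
#'   promoter, decoy, and non-coding genes are added on top. Must be >= 10.
#' @param n_kinase_per_group Kinase genes emitted per kinase group.
#' @param kinase_groups Kinase group labels; defaults to the eight standard
#'   phylogenetic families.
#' @param carrier_fraction Fraction of a cancer type's samples carrying each
#'   standard truth fusion.
#' @param outlier_effect Expression shift for fusion carriers of outlier
#'   genes, in units of the gene's cohort standard deviation (log2 scale).
#' @param promoter_coupling Coupling coefficient for promoter-capture events:
#'   a carrier's kinase expression (log2 scale, in kinase-SD units) is shifted
#'   by `promoter_coupling` times the partner's z-score in that sample, so
#'   fusions with a more active partner promoter drive the kinase higher.
#' @param mut_rate Mean background mutation count per sample (Poisson).
#' @param msi_hypermut_factor Burden multiplier for MSI samples.
#' @param driver_mut_fraction Fraction of samples given a curated driver
#'   mutation.
#' @param msi_fraction Fraction of samples that are microsatellite-unstable.
#' @param never_smoker_fraction Fraction of samples labelled never-smokers.
#' @param wgs_fraction Fraction of samples with WGS available.
#' @param total_frags RNA-seq library size (total fragments) per sample, used
#'   for FFPM.
#' @param ffpm_min,recurrence_max Filter thresholds echoed into resources.
#' @param bp_jitter Max per-caller breakpoint jitter (bases) for non-primary
#'   callers when the primary caller also reports the event.
#' @param domain_window Relative protein interval (start, end fractions) where
#'   kinase domains are placed.
#' @param extra_domains Optional data frame (gene, domain, aa_start, aa_end)
#'   of additional domain rows; validated against protein lengths.
#' @param genome_gap Genomic spacing between consecutive genes (bases); keeps
#'   WGS windows of unrelated genes disjoint.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_samples = c(BRCA = 60L, LUAD = 60L),
                          n_genes = 30L,
                          n_kinase_per_group = 2L,
                          kinase_groups = c("AGC", "CAMK", "CK1", "CMGC",
                                            "STE", "TK", "TKL", "OTHER"),
                          carrier_fraction = 0.05,
                          outlier_effect = 5,
                          promoter_coupling = 0.8,
                          mut_rate = 30,
                          msi_hypermut_factor = 15,
                          driver_mut_fraction = 0.35,
                          msi_fraction = 0.1,
                          never_smoker_fraction = 0.15,
                          wgs_fraction = 0.7,
                          total_frags = 4e7,
                          ffpm_min = 0.1,
                          recurrence_max = 10L,
                          bp_jitter = 2L,
                          domain_window = c(0.35, 0.75),
                          extra_domains = NULL,
                          genome_gap = 3e5) {
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  if (is.null(names(n_samples)) || any(!nzchar(names(n_samples))))
    stop("n_samples must be a named vector of cancer-type labels")
  if (n_genes < 10) stop("n_genes must be >= 10")
  fr <- c(carrier_fraction, driver_mut_fraction, msi_fraction,
          never_smoker_fraction, wgs_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (length(domain_window) != 2 || domain_window[1] <= 0 ||
      domain_window[2] >= 1 || domain_window[1] >= domain_window[2])
    stop("domain_window must be increasing fractions inside (0, 1)")
  structure(list(
    seed = seed, n_samples = n_samples, n_genes = as.integer(n_genes),
    n_kinase_per_group = as.integer(n_kinase_per_group),
    kinase_groups = kinase_groups, carrier_fraction = carrier_fraction,
    outlier_effect = outlier_effect, promoter_coupling = promoter_coupling,
    mut_rate = mut_rate, msi_hypermut_factor = msi_hypermut_factor,
    driver_mut_fraction = driver_mut_fraction,
    msi_fraction = msi_fraction,
    never_smoker_fraction = never_smoker_fraction,
    wgs_fraction = wgs_fraction, total_frags = total_frags,
    ffpm_min = ffpm_min, recurrence_max = as.integer(recurrence_max),
    bp_jitter = as.integer(bp_jitter), domain_window = domain_window,
    extra_domains = extra_domains, genome_gap = genome_gap
  ), class = "cohort_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All 61 sense codons (standard code).
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

.rand_cds <- function(n_codons) {
  # ATG + sense codons + stop; no internal stop codons.
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(.sense_codons(), n_codons - 2, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate synthetic gene annotation and filter resources
#'
#' Builds a deterministic toy genome: multi-exon gene models on both strands
#' across four chromosomes, transcript sequences whose CDS is a positive
#' multiple of three, a kinase table covering every configured kinase group, a
#' protein-domain table, paralog pairs, a gene exclusion list, a panel of
#' normal-tissue fusion pairs, a recurrence allowlist, a driver-gene list, and
#' a druggability table. Also fixes per-gene expression location/scale used by
#' [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @return An object of class `fusion_annotation`: list with elements
#'   `models`, `tx_seqs`, `domains`, `kinases`, `paralogs`, `exclusion_genes`,
#'   `normals_panel`, `allowlist`, `driver_genes`, `drugs`, `expr_params`,
#'   `genome`, `roster`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_genes < 10) stop("n_genes must be >= 10")
  with_seed(config$seed * 7 + 1, {
    roster <- data.frame(
      symbol = c(
        as.vector(t(outer(config$kinase_groups,
                          seq_len(config$n_kinase_per_group),
                          function(g, i) paste0("K", g, i)))),
        paste0("PRM", 1:8),
        "EXCL1", "EXCL2", "PARA1", "PARA2", "ADJ5P", "ADJ3P",
        "LNC1", "LNC2",
        sprintf("GEN%03d", seq_len(config$n_genes))),
      stringsAsFactors = FALSE)
    roster$role <- c(
      rep("kinase", length(config$kinase_groups) * config$n_kinase_per_group),
      rep("promoter", 8), rep("excluded", 2), rep("paralog", 2),
      rep("adjacent", 2), rep("noncoding", 2),
      rep("regular", config$n_genes))
    roster$group <- NA_character_
    roster$group[roster$role == "kinase"] <-
      rep(config$kinase_groups, each = config$n_kinase_per_group)

    chroms <- paste0("chr", 1:4)
    cursor <- stats::setNames(rep(1e5, 4), chroms)
    models <- list(); tx_seqs <- character(0)
    for (i in seq_len(nrow(roster))) {
      sym <- roster$symbol[i]
      chrom <- if (sym == "ADJ3P") roster$chrom[i - 1] else
        chroms[(i - 1) %% 4 + 1]
      strand <- if (i %% 2 == 0) "-" else "+"
      n_ex <- sample(3:5, 1)
      ex_len <- sample(180:500, n_ex, replace = TRUE)
      introns <- sample(200:1500, n_ex - 1, replace = TRUE)
      start <- if (sym == "ADJ3P") cursor[[chrom]] else cursor[[chrom]]
      starts <- start + c(0, cumsum(ex_len[-n_ex] + introns))
      exons0 <- cbind(starts, starts + ex_len)  # genomic ascending
      gene_end <- max(exons0[, 2])
      cursor[[chrom]] <- gene_end +
        if (sym == "ADJ5P") 5e4 else config$genome_gap
      ex_tx <- if (strand == "-") exons0[rev(seq_len(n_ex)), , drop = FALSE]
               else exons0
      tx_len <- sum(ex_len)
      coding <- roster$role[i] != "noncoding"
      if (coding) {
        utr5 <- sample(40:110, 1)
        utr3 <- sample(40:140, 1)
        cds_len <- tx_len - utr5 - utr3
        cds_len <- cds_len - cds_len %% 3
        stopifnot(cds_len >= 240)
        g1 <- .tx_to_genomic(structure(list(exons = ex_tx, strand = strand,
                                            symbol = sym),
                                       class = "gene_model"), utr5)
        g2 <- .tx_to_genomic(structure(list(exons = ex_tx, strand = strand,
                                            symbol = sym),
                                       class = "gene_model"),
                             utr5 + cds_len - 1)
        cds_start <- min(g1, g2); cds_end <- max(g1, g2) + 1
        seq <- paste0(.rand_dna(utr5), .rand_cds(cds_len / 3),
                      .rand_dna(tx_len - utr5 - cds_len))
      } else {
        cds_start <- NA; cds_end <- NA
        seq <- .rand_dna(tx_len)
      }
      models[[sym]] <- gene_model(
        gene_id = sprintf("SYNG%05d", i), symbol = sym, chromosome = chrom,
        strand = strand, exons = ex_tx, cds_start = cds_start,
        cds_end = cds_end, transcript_id = sprintf("SYNT%05d", i),
        is_coding = coding)
      tx_seqs[[sym]] <- seq
      roster$chrom[i] <- chrom
    }

    kin <- roster[roster$role == "kinase", ]
    domains <- do.call(rbind, lapply(seq_len(nrow(kin)), function(j) {
      m <- models[[kin$symbol[j]]]
      L <- .cds_length(m) / 3 - 1  # residues, excluding stop
      data.frame(gene = kin$symbol[j], domain = "Protein kinase domain",
                 aa_start = max(2, floor(config$domain_window[1] * L)),
                 aa_end = floor(config$domain_window[2] * L),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(config$extra_domains)) {
      xd <- config$extra_domains
      for (j in seq_len(nrow(xd))) {
        m <- models[[xd$gene[j]]]
        if (is.null(m)) stop("extra domain for unknown gene ", xd$gene[j])
        L <- .cds_length(m) / 3 - 1
        if (xd$aa_end[j] > L || xd$aa_start[j] < 1)
          stop(sprintf("domain [%d, %d] exceeds protein length %d for gene %s",
                       xd$aa_start[j], xd$aa_end[j], L, xd$gene[j]))
      }
      domains <- rbind(domains, xd[, c("gene", "domain", "aa_start", "aa_end")])
    }

    mu <- ifelse(roster$role == "promoter", stats::runif(nrow(roster), 9, 11),
                 stats::runif(nrow(roster), 3, 8))
    expr_params <- data.frame(symbol = roster$symbol, mu = mu,
                              sd = stats::runif(nrow(roster), 0.8, 1.2),
                              stringsAsFactors = FALSE)

    drugs <- data.frame(
      gene = c("KTK1", "KCMGC1", "KTKL1", "GEN009"),
      partner = c(NA, NA, "PRM2", NA),
      cancer_type = c("*", "*", "*", "*"),
      drug = c("toytinib", "mocktinib", "swaponib", "synthetanib"),
      label = c("ON_LABEL", "OFF_LABEL", "OFF_LABEL", "ON_LABEL"),
      stringsAsFactors = FALSE)

    driver_genes <- c(kin$symbol, "PRM1", "PRM2",
                      sprintf("GEN%03d", 9:12))

    structure(list(
      models = models, tx_seqs = tx_seqs, domains = domains,
      kinases = data.frame(gene = kin$symbol, group = kin$group,
                           stringsAsFactors = FALSE),
      paralogs = data.frame(gene1 = "PARA1", gene2 = "PARA2",
                            stringsAsFactors = FALSE),
      exclusion_genes = c("EXCL1", "EXCL2"),
      normals_panel = data.frame(gene1 = c("GEN013", "GEN021"),
                                 gene2 = c("GEN014", "GEN022"),
                                 stringsAsFactors = FALSE),
      allowlist = data.frame(gene1 = "GEN019", gene2 = "GEN020",
                             stringsAsFactors = FALSE),
      driver_genes = driver_genes, drugs = drugs,
      expr_params = expr_params,
      genome = data.frame(chrom = chroms,
                          length = unname(cursor) + 2e5,
                          stringsAsFactors = FALSE),
      roster = roster
    ), class = "fusion_annotation")
  })
}

#' Write transcript sequences as FASTA
#'
#' @param tx_seqs Named character vector of transcript sequences (by symbol).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_transcript_fasta <- function(tx_seqs, path) {
  set <- Biostrings::DNAStringSet(tx_seqs[order(names(tx_seqs))])
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector keyed by sequence name.
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
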