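# Sampling helper immune to the length-1 behaviour of sample().
.pick <- function(x, n, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

# Choose breakpoints for a designed fusion event. r = retained 5' coding
# bases, d = discarded 3' coding bases; the INFRAME condition is r == d mod 3.
.design_breakpoints <- function(m5, m3, region5, region3, frame,
                                mode5 = "mid", mode3 = "mid",
                                domains = NULL) {
  dom_of <- function(sym) {
    rows <- domains[domains$gene == sym, , drop = FALSE]
    if (nrow(rows) == 0) NULL else rows[1, ]
  }
  r <- NA; d <- NA
  t5 <- switch(region5,
    CDS = {
      cb <- .cds_tx_bounds(m5); len <- cb[2] - cb[1]
      dm <- dom_of(m5$symbol)
      r <- switch(mode5,
        after_domain = 3 * (dm$aa_end + 2),
        in_domain = 3 * ((dm$aa_start + dm$aa_end) %/% 2),
        mid = 3 * ((len / 3) %/% 2))
      stopifnot(r >= 1, r <= len - 3)
      cb[1] + r - 1
    },
    FIVE_UTR = .cds_tx_bounds(m5)[1] %/% 2,
    THREE_UTR = {
      cb <- .cds_tx_bounds(m5)
      cb[2] + (.tx_length(m5) - cb[2]) %/% 2
    },
    NONCODING = NA)
  t3 <- switch(region3,
    CDS = {
      cb <- .cds_tx_bounds(m3); len <- cb[2] - cb[1]
      dm <- dom_of(m3$symbol)
      d <- switch(mode3,
        before_domain = 9,
        in_domain = 3 * ((dm$aa_start + dm$aa_end) %/% 2),
        mid = 3 * ((len / 3) %/% 2))
      if (identical(frame, "INFRAME")) d <- d + (r - d) %% 3
      if (identical(frame, "FRAMESHIFT")) d <- d + (r - d + 1) %% 3
      stopifnot(d >= 0, d <= len - 6)
      cb[1] + d
    },
    FIVE_UTR = .cds_tx_bounds(m3)[1] %/% 2,
    INTRON = NA,
    NONCODING = NA)

  g5 <- if (region5 == "NONCODING") {
    ex <- m5$exons[1, ]; (ex[1] + ex[2]) %/% 2 + 1
  } else .tx_to_genomic(m5, t5) + 1
  g3 <- if (region3 == "INTRON") {
    ex <- m3$exons
    lo <- min(ex[1, 2], ex[2, 2]); hi <- max(ex[1, 1], ex[2, 1])
    lo + (hi - lo) %/% 2 + 1
  } else if (region3 == "NONCODING") {
    ex <- m3$exons[1, ]; (ex[1] + ex[2]) %/% 2 + 1
  } else .tx_to_genomic(m3, t3) + 1
  list(pos5 = as.numeric(g5), pos3 = as.numeric(g3), r = r, d = d)
}

#' Design the ground-truth fusion events of a synthetic study
#'
#' Lays out a fixed plan of fusion events over the configured cohort: kinase
#' fusions covering inframe/frameshift/no-frame labels, intact and disrupted
#' kinase domains, 5'-, 3'-, and both-kinase orientations, a promoter-swap
#' event, expression-outlier events, and one decoy violating each of the five
#' filter rules (plus an allowlisted recurrent event when the cohort has two
#' or more cancer types). Every caller record emitted downstream maps to
#' exactly one truth record.
#'
#' @param annotation A [generate_annotation()] result.
#' @param config The matching [cohort_config()].
#' @return An object of class `fusion_truth`: list with `records` (one row per
#'   fusion-carrying sample) and `samples` (cohort roster with WGS
#'   availability).
#' @export
generate_truth <- function(annotation, config) {
  stopifnot(inherits(annotation, "fusion_annotation"),
            inherits(config, "cohort_config"))
  needed <- c("KTK1", "KTK2", "KCAMK1", "KCMGC1", "KCK11", "KTKL1", "KSTE1",
              "KAGC1", "PRM1", "PRM2", "PRM3", sprintf("GEN%03d", 1:20),
              "EXCL1", "PARA1", "PARA2", "ADJ5P", "ADJ3P", "LNC1")
  missing <- setdiff(needed, names(annotation$models))
  if (length(missing))
    stop("annotation lacks genes required by the default truth plan: ",
         paste(missing, collapse = ", "),
         " (need default kinase groups and n_genes >= 20)")

  with_seed(config$seed * 7 + 2, {
    types <- names(config$n_samples)
    samples <- do.call(rbind, lapply(types, function(ct) {
      data.frame(sample_id = sprintf("%s_S%03d", ct,
                                     seq_len(config$n_samples[[ct]])),
                 cancer_type = ct, stringsAsFactors = FALSE)
    }))
    samples$has_wgs <- stats::runif(nrow(samples)) < config$wgs_fraction

    t1 <- types[1]
    t2 <- if (length(types) >= 2) types[2] else types[1]
    nc <- function(ct) max(1L, round(config$carrier_fraction *
                                       config$n_samples[[ct]]))
    mods <- annotation$models
    dom <- annotation$domains

    plan <- list(
      list(id = "E01", g5 = "PRM1", g3 = "KTK1", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "before_domain",
           role = "THREE_KINASE", domain = "INTACT",
           effect = 0, egene = NA, coupled = TRUE,
           type = t1, n = nc(t1),
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE;BREAKFAST_LIKE",
           fate = "KEPT", support = 4),
      list(id = "E02", g5 = "GEN001", g3 = "KTK2", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "before_domain",
           role = "THREE_KINASE", domain = "INTACT", effect = 0, egene = NA,
           type = t1, n = nc(t1),
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "KEPT", support = 3),
      list(id = "E03", g5 = "GEN002", g3 = "KCAMK1", r5 = "CDS", r3 = "CDS",
           frame = "FRAMESHIFT", m5 = "mid", m3 = "before_domain",
           role = "THREE_KINASE", domain = "DISRUPTED", effect = 0,
           egene = NA, type = t2, n = nc(t2),
           callers = "STARFUSION_LIKE;BREAKFAST_LIKE",
           fate = "KEPT", support = 2),
      list(id = "E04", g5 = "KCMGC1", g3 = "GEN003", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "after_domain", m3 = "mid",
           role = "FIVE_KINASE", domain = "INTACT", effect = 0, egene = NA,
           type = t2, n = nc(t2), callers = "STARFUSION_LIKE",
           fate = "KEPT", support = 5),
      list(id = "E05", g5 = "KCK11", g3 = "GEN004", r5 = "CDS", r3 = "CDS",
           frame = "FRAMESHIFT", m5 = "in_domain", m3 = "mid",
           role = "FIVE_KINASE", domain = "DISRUPTED", effect = 0,
           egene = NA, type = t1, n = 2L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "KEPT", support = 0),
      list(id = "E06", g5 = "PRM2", g3 = "KTKL1", r5 = "FIVE_UTR",
           r3 = "FIVE_UTR", frame = "NO_FRAME", m5 = "mid", m3 = "mid",
           role = "THREE_KINASE", domain = "INTACT",
           effect = config$outlier_effect, egene = "KTKL1",
           type = t1, n = nc(t1),
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE;BREAKFAST_LIKE",
           fate = "KEPT", support = 3),
      list(id = "E07", g5 = "KSTE1", g3 = "KAGC1", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "in_domain", m3 = "before_domain",
           role = "THREE_KINASE", domain = "INTACT", effect = 0, egene = NA,
           type = t2, n = 2L, callers = "STARFUSION_LIKE",
           fate = "KEPT", support = 3),
      list(id = "E08", g5 = "GEN005", g3 = "GEN006", r5 = "CDS",
           r3 = "INTRON", frame = "NO_FRAME", m5 = "mid", m3 = "mid",
           role = "NONE", domain = NA, effect = 0, egene = NA,
           type = t2, n = 2L, callers = "ERICSCRIPT_LIKE;BREAKFAST_LIKE",
           fate = "KEPT", support = 0),
      list(id = "E09", g5 = "GEN009", g3 = "GEN010", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = config$outlier_effect, egene = "GEN010",
           type = t2, n = nc(t2) + 1L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "KEPT", support = 4),
      list(id = "E10", g5 = "GEN011", g3 = "GEN012", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = -config$outlier_effect, egene = "GEN012",
           type = t1, n = nc(t1),
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "KEPT", support = 3),
      list(id = "E11", g5 = "GEN007", g3 = "LNC1", r5 = "CDS",
           r3 = "NONCODING", frame = "NO_FRAME", m5 = "mid", m3 = "mid",
           role = "NONE", domain = NA, effect = 0, egene = NA,
           type = t1, n = 1L, callers = "STARFUSION_LIKE;BREAKFAST_LIKE",
           fate = "KEPT", support = 0),
      list(id = "E12", g5 = "PRM3", g3 = "KTK1", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "before_domain",
           role = "THREE_KINASE", domain = "INTACT", effect = 0, egene = NA,
           coupled = TRUE, type = t2, n = 1L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "KEPT", support = 3, junction_reads = 4L),
      list(id = "E13", g5 = "ADJ5P", g3 = "ADJ3P", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = 0, egene = NA, type = t1, n = 2L,
           callers = "STARFUSION_LIKE", fate = "KEPT", support = 3,
           ambiguous = TRUE),
      list(id = "D01", g5 = "EXCL1", g3 = "GEN013", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = 0, egene = NA, type = t1, n = 1L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "R1_EXCLUDED_GENE", support = 0),
      list(id = "D02", g5 = "PARA1", g3 = "PARA2", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = 0, egene = NA, type = t1, n = 1L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "R2_SELF_OR_PARALOG", support = 0),
      list(id = "D03", g5 = "GEN013", g3 = "GEN014", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = 0, egene = NA, type = t2, n = 1L,
           callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
           fate = "R3_NORMALS_PANEL", support = 0),
      list(id = "D04", g5 = "GEN015", g3 = "GEN016", r5 = "CDS", r3 = "CDS",
           frame = "INFRAME", m5 = "mid", m3 = "mid", role = "NONE",
           domain = NA, effect = 0, egene = NA, type = t2, n = 1L,
           callers = "STARFUSION_LIKE", fate = "R4_FFPM", support = 0,
           junction_reads = 1L, spanning_frags = 1L)
    )
    if (length(types) >= 2 && nrow(samples) >= 24) {
      half <- config$recurrence_max %/% 2
      plan <- c(plan, list(
        list(id = "D05", g5 = "GEN017", g3 = "GEN018", r5 = "CDS",
             r3 = "CDS", frame = "INFRAME", m5 = "mid", m3 = "mid",
             role = "NONE", domain = NA, effect = 0, egene = NA,
             type = "SPLIT", n = config$recurrence_max, n1 = half,
             callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
             fate = "R5_RECURRENT_ARTIFACT", support = 0),
        list(id = "A05", g5 = "GEN019", g3 = "GEN020", r5 = "CDS",
             r3 = "CDS", frame = "INFRAME", m5 = "mid", m3 = "mid",
             role = "NONE", domain = NA, effect = 0, egene = NA,
             type = "SPLIT", n = config$recurrence_max, n1 = half,
             callers = "STARFUSION_LIKE;ERICSCRIPT_LIKE",
             fate = "KEPT", support = 0)))
    }

    recs <- lapply(plan, function(ev) {
      m5 <- mods[[ev$g5]]; m3 <- mods[[ev$g3]]
      bp <- .design_breakpoints(m5, m3, ev$r5, ev$r3, ev$frame,
                                ev$m5, ev$m3, dom)
      carriers <- if (identical(ev$type, "SPLIT")) {
        c(.pick(samples$sample_id[samples$cancer_type == t1], ev$n1),
          .pick(samples$sample_id[samples$cancer_type == t2],
                ev$n - ev$n1))
      } else {
        .pick(samples$sample_id[samples$cancer_type == ev$type], ev$n)
      }
      n <- length(carriers)
      jr <- if (!is.null(ev$junction_reads)) rep(ev$junction_reads, n)
            else .pick(8:40, n, replace = TRUE)
      sp <- if (!is.null(ev$spanning_frags)) rep(ev$spanning_frags, n)
            else .pick(2:20, n, replace = TRUE)
      data.frame(
        record_id = paste0(ev$id, "_", carriers), event = ev$id,
        sample_id = carriers,
        cancer_type = samples$cancer_type[match(carriers, samples$sample_id)],
        gene5 = ev$g5, gene3 = ev$g3,
        chrom5 = m5$chromosome, pos5 = bp$pos5, strand5 = m5$strand,
        chrom3 = m3$chromosome, pos3 = bp$pos3, strand3 = m3$strand,
        frame_truth = ev$frame, region5 = ev$r5, region3 = ev$r3,
        kinase_role_truth = ev$role,
        domain_truth = if (is.na(ev$domain)) "NA" else ev$domain,
        effect_gene = if (is.na(ev$egene)) NA_character_ else ev$egene,
        expression_effect = ev$effect, filter_fate = ev$fate,
        callers = ev$callers, junction_reads = jr, spanning_frags = sp,
        total_frags = config$total_frags,
        wgs_support = ev$support,
        wgs_ambiguous = isTRUE(ev$ambiguous),
        coupled = isTRUE(ev$coupled),
        stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, recs)
    records$expected_discordant <- ifelse(records$wgs_ambiguous, 0L,
                                          records$wgs_support)
    has_wgs <- samples$has_wgs[match(records$sample_id, samples$sample_id)]
    records$validation_truth <- ifelse(!has_wgs, "NOT_EVALUABLE",
      ifelse(records$expected_discordant >= 3, "VALIDATED", "NOT_VALIDATED"))
    rownames(records) <- NULL
    structure(list(records = records, samples = samples),
              class = "fusion_truth")
  })
}

#' Emit per-caller fusion TSV tables from truth records
#'
#' Each truth record is written into the native table of every caller listed
#' in its `callers` set. When the primary caller also reports an event, the
#' other callers' breakpoints are jittered by up to `config$bp_jitter` bases
#' to emulate coordinate disagreement between tools.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [cohort_config()].
#' @return Named list of data frames: `STARFUSION_LIKE`, `ERICSCRIPT_LIKE`,
#'   `BREAKFAST_LIKE`, each in that dialect's native columns.
#' @export
simulate_fusion_calls <- function(truth, config) {
  stopifnot(inherits(truth, "fusion_truth"), inherits(config, "cohort_config"))
  with_seed(config$seed * 7 + 3, {
    r <- truth$records
    rows <- list(STARFUSION_LIKE = list(), ERICSCRIPT_LIKE = list(),
                 BREAKFAST_LIKE = list())
    for (i in seq_len(nrow(r))) {
      callers <- strsplit(r$callers[i], ";", fixed = TRUE)[[1]]
      has_sf <- "STARFUSION_LIKE" %in% callers
      for (cl in callers) {
        j5 <- 0L; j3 <- 0L
        if (cl != "STARFUSION_LIKE" && has_sf && config$bp_jitter > 0) {
          j5 <- .pick(-config$bp_jitter:config$bp_jitter, 1)
          j3 <- .pick(-config$bp_jitter:config$bp_jitter, 1)
        }
        p5 <- r$pos5[i] + j5; p3 <- r$pos3[i] + j3
        rows[[cl]][[length(rows[[cl]]) + 1L]] <- switch(cl,
          STARFUSION_LIKE = data.frame(
            sample_id = r$sample_id[i],
            fusion_name = paste0(r$gene5[i], "--", r$gene3[i]),
            junction_read_count = r$junction_reads[i],
            spanning_frag_count = r$spanning_frags[i],
            left_breakpoint = paste(r$chrom5[i], p5, r$strand5[i], sep = ":"),
            right_breakpoint = paste(r$chrom3[i], p3, r$strand3[i], sep = ":"),
            ffpm = (r$junction_reads[i] + r$spanning_frags[i]) /
              r$total_frags[i] * 1e6,
            total_frags = r$total_frags[i], stringsAsFactors = FALSE),
          ERICSCRIPT_LIKE = data.frame(
            sample_id = r$sample_id[i],
            gene_5prime = r$gene5[i], gene_3prime = r$gene3[i],
            chr_5prime = r$chrom5[i], breakpoint_5prime = p5,
            strand_5prime = r$strand5[i],
            chr_3prime = r$chrom3[i], breakpoint_3prime = p3,
            strand_3prime = r$strand3[i],
            crossing_reads = r$junction_reads[i],
            spanning_reads = r$spanning_frags[i],
            total_frags = r$total_frags[i], stringsAsFactors = FALSE),
          BREAKFAST_LIKE = data.frame(
            sample_id = r$sample_id[i],
            chrom_5p = r$chrom5[i], pos_5p = p5, strand_5p = r$strand5[i],
            gene_5p = r$gene5[i],
            chrom_3p = r$chrom3[i], pos_3p = p3, strand_3p = r$strand3[i],
            gene_3p = r$gene3[i],
            num_reads = r$junction_reads[i],
            total_frags = r$total_frags[i], stringsAsFactors = FALSE))
      }
    }
    lapply(rows, function(x) if (length(x)) do.call(rbind, x) else NULL)
  })
}

#' Simulate expression, copy number, mutations, and sample metadata
#'
#' Expression is log-normal per gene (location/scale fixed by the annotation),
#' with the configured outlier shifts injected into fusion carriers on the
#' log2 scale. MSI samples get a hypermutator burden and a guaranteed
#' mismatch-repair gene mutation. A configured fraction of samples carries a
#' curated driver mutation (flagged in the MAF `is_driver` column).
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [cohort_config()].
#' @param annotation The matching [generate_annotation()] result.
#' @param seed RNG seed for the cohort draw (defaults to the config seed, so
#'   replicate cohorts can be drawn over the same annotation and truth).
#' @return An object of class `fusion_cohort`: list with `expression` (genes x
#'   samples matrix), `copy_number`, `maf`, `metadata`.
#' @export
simulate_cohort <- function(truth, config, annotation, seed = config$seed) {
  stopifnot(inherits(truth, "fusion_truth"),
            inherits(annotation, "fusion_annotation"))
  with_seed(seed * 7 + 4, {
    sm <- truth$samples
    genes <- annotation$expr_params$symbol
    n_g <- length(genes); n_s <- nrow(sm)
    mu <- annotation$expr_params$mu
    sdv <- annotation$expr_params$sd
    lg <- matrix(stats::rnorm(n_g * n_s, mean = mu, sd = sdv),
                 nrow = n_g, ncol = n_s,
                 dimnames = list(genes, sm$sample_id))
    r <- truth$records
    inj <- r[!is.na(r$effect_gene) & r$expression_effect != 0, , drop = FALSE]
    for (i in seq_len(nrow(inj))) {
      g <- inj$effect_gene[i]
      lg[g, inj$sample_id[i]] <- lg[g, inj$sample_id[i]] +
        inj$expression_effect[i] * sdv[match(g, genes)]
    }
    # Promoter capture: a detected capture fusion implies an active partner
    # locus, so the carrier's partner expression is elevated and the kinase
    # tracks the partner's (activated) z-score with the configured coupling.
    activation <- 1.5  # partner locus activation, in partner-SD units
    cpl <- r[r$coupled, , drop = FALSE]
    for (i in seq_len(nrow(cpl))) {
      p <- cpl$gene5[i]; k <- cpl$gene3[i]; s <- cpl$sample_id[i]
      lg[p, s] <- lg[p, s] + activation * sdv[match(p, genes)]
      z_p <- (lg[p, s] - mu[match(p, genes)]) / sdv[match(p, genes)]
      lg[k, s] <- lg[k, s] +
        config$promoter_coupling * z_p * sdv[match(k, genes)]
    }
    expression <- round(2^lg, 4)

    copy_number <- matrix(
      sample(c(0L, 1L, 2L, 3L, 4L, 5L), n_g * n_s, replace = TRUE,
             prob = c(0.01, 0.08, 0.80, 0.08, 0.02, 0.01)),
      nrow = n_g, dimnames = list(genes, sm$sample_id))

    n_msi <- round(config$msi_fraction * n_s)
    msi_samples <- .pick(sm$sample_id, n_msi)
    driver_samples <- .pick(sm$sample_id,
                            round(config$driver_mut_fraction * n_s))
    mmr <- c("POLE", "MLH1", "MLH3", "MGMT", "MSH6", "MSH3", "MSH2",
             "PMS1", "PMS2")
    classes <- c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                 "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
                 "Frame_Shift_Del", "Frame_Shift_Ins", "Nonstop_Mutation",
                 "Translation_Start_Site", "3'UTR")
    cls_prob <- c(0.45, 0.22, 0.05, 0.05, 0.03, 0.02, 0.05, 0.03, 0.01,
                  0.01, 0.08)
    gene_pool <- c(genes, mmr)
    # Background mutations rarely hit driver or MMR genes (a 299-gene driver
    # list is a tiny slice of a real exome), so weight them down.
    pool_w <- ifelse(gene_pool %in% annotation$driver_genes, 0.05,
                     ifelse(gene_pool %in% mmr, 0.02, 1))
    maf_rows <- lapply(sm$sample_id, function(s) {
      lam <- config$mut_rate *
        if (s %in% msi_samples) config$msi_hypermut_factor else 1
      n_mut <- stats::rpois(1, lam)
      out <- data.frame(
        Tumor_Sample_Barcode = rep(s, n_mut),
        Hugo_Symbol = sample(gene_pool, n_mut, replace = TRUE,
                             prob = pool_w),
        Variant_Classification = sample(classes, n_mut, replace = TRUE,
                                        prob = cls_prob),
        is_driver = rep(FALSE, n_mut), stringsAsFactors = FALSE)
      if (s %in% msi_samples)
        out <- rbind(out, data.frame(
          Tumor_Sample_Barcode = s, Hugo_Symbol = .pick(mmr, 1),
          Variant_Classification = "Missense_Mutation", is_driver = FALSE,
          stringsAsFactors = FALSE))
      if (s %in% driver_samples)
        out <- rbind(out, data.frame(
          Tumor_Sample_Barcode = s,
          Hugo_Symbol = .pick(annotation$driver_genes, 1),
          Variant_Classification = "Missense_Mutation", is_driver = TRUE,
          stringsAsFactors = FALSE))
      out
    })
    maf <- do.call(rbind, maf_rows)

    hla_pool <- c("HLA-A*02:01", "HLA-A*01:01", "HLA-B*07:02",
                  "HLA-B*08:01", "HLA-C*07:01", "HLA-C*04:01")
    metadata <- data.frame(
      sample_id = sm$sample_id, cancer_type = sm$cancer_type,
      smoking_status = ifelse(
        stats::runif(n_s) < config$never_smoker_fraction, "never", "ever"),
      msi = sm$sample_id %in% msi_samples,
      has_wgs = sm$has_wgs,
      hla_alleles = vapply(seq_len(n_s), function(i)
        paste(.pick(hla_pool, 2), collapse = ";"), character(1)),
      stringsAsFactors = FALSE)

    structure(list(expression = expression, copy_number = copy_number,
                   maf = maf, metadata = metadata),
              class = "fusion_cohort")
  })
}

.sam_header <- function(genome) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, as.integer(genome$length)))
}

.sam_pair <- function(qname, c1, p1, c2, p2, mapq1, mapq2) {
  c(paste(qname, 97, c1, p1, mapq1, "100M", c2, p2, 0, "*", "*", sep = "\t"),
    paste(qname, 145, c2, p2, mapq2, "100M", c1, p1, 0, "*", "*", sep = "\t"))
}

#' Simulate WGS read support as SAM records
#'
#' For every truth fusion in a WGS-covered sample, emits the intended number
#' of qualifying discordant read pairs (one high-MAPQ mate inside each partner
#' gene), one additional low-MAPQ pair that must not pass the quality filter,
#' and per-sample concordant decoy pairs with both mates in a single gene.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [cohort_config()].
#' @param annotation The matching [generate_annotation()] result.
#' @param seed RNG seed (defaults to the config seed).
#' @param include_header Must be `TRUE`; SAM output without a header is
#'   refused.
#' @return Named list: `sam` (character-vector SAM lines per WGS sample) and
#'   `has_wgs` (named logical over all samples).
#' @export
simulate_wgs_support <- function(truth, config, annotation,
                                 seed = config$seed, include_header = TRUE) {
  if (!isTRUE(include_header))
    stop("SAM output requires a header (include_header = TRUE)")
  stopifnot(inherits(truth, "fusion_truth"),
            inherits(annotation, "fusion_annotation"))
  with_seed(seed * 7 + 5, {
    header <- .sam_header(annotation$genome)
    mods <- annotation$models
    pos_in <- function(sym, n) {
      sp <- .gene_span(mods[[sym]])
      .pick(seq(sp[1] + 1, sp[2] - 100), n, replace = TRUE)
    }
    sm <- truth$samples
    wgs_samples <- sm$sample_id[sm$has_wgs]
    r <- truth$records
    sam <- lapply(wgs_samples, function(s) {
      lines <- header
      rr <- r[r$sample_id == s, , drop = FALSE]
      for (i in seq_len(nrow(rr))) {
        k <- rr$wgs_support[i]
        if (k > 0) {
          for (p in seq_len(k))
            lines <- c(lines, .sam_pair(
              sprintf("%s_DP%02d", rr$record_id[i], p),
              rr$chrom5[i], pos_in(rr$gene5[i], 1),
              rr$chrom3[i], pos_in(rr$gene3[i], 1), 60, 60))
          lines <- c(lines, .sam_pair(
            sprintf("%s_LQ01", rr$record_id[i]),
            rr$chrom5[i], pos_in(rr$gene5[i], 1),
            rr$chrom3[i], pos_in(rr$gene3[i], 1), .pick(0:19, 1), 60))
        }
      }
      g <- .pick(names(mods), 1)
      for (p in 1:2)
        lines <- c(lines, .sam_pair(
          sprintf("CONC_%s_%02d", s, p),
          mods[[g]]$chromosome, pos_in(g, 1),
          mods[[g]]$chromosome, pos_in(g, 1), 60, 60))
      lines
    })
    names(sam) <- wgs_samples
    list(sam = sam,
         has_wgs = stats::setNames(sm$has_wgs, sm$sample_id))
  })
}

#' Deterministic toy peptide-MHC affinity predictor
#'
#' Stands in for a trained binding model behind the pipeline's pluggable
#' predictor contract: a deterministic map from (peptide, allele) to an
#' affinity in nM within (0, 50000]. Peptides containing a configured
#' strong-binder motif are guaranteed an affinity of at most 500 nM.
#'
#' @param seed Integer seed fixing the mapping.
#' @param strong_motifs Character vector of subsequences forcing strong
#'   binding.
#' @return A function `(peptide, allele) -> nM` of class
#'   `affinity_predictor`; errors on peptides outside length 8-11.
#' @export
toy_affinity_model <- function(seed = 1L, strong_motifs = character()) {
  seed <- as.integer(seed)
  hash1 <- function(s) {
    h <- (abs(seed) %% 2147483646) + 7
    for (x in utf8ToInt(s)) h <- (h * 131 + x) %% 2147483647
    h
  }
  f <- function(peptide, allele) {
    vapply(peptide, function(p) {
      n <- nchar(p)
      if (n < 8 || n > 11)
        stop("peptide length must be 8-11 residues, got ", n, " (", p, ")")
      u <- (hash1(paste0(p, "|", allele)) + 1) / 2147483648
      if (length(strong_motifs) &&
          any(vapply(strong_motifs, function(m) grepl(m, p, fixed = TRUE),
                     logical(1))))
        50 + 450 * u
      else
        50000 * u^3
    }, numeric(1), USE.NAMES = FALSE)
  }
  structure(f, class = c("affinity_predictor", "function"),
            seed = seed, strong_motifs = strong_motifs)
}
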