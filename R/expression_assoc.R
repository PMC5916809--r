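#' Cohort expression percentile of a sample
#'
#' Average-rank percentile of `sample_value` among `cohort_values` (which
#' include the sample itself), rescaled so the cohort minimum maps to 0 and
#' the maximum to 100; ties receive their average rank.
#'
#' @param cohort_values Expression values of the cancer-type cohort at one
#'   gene (the sample included).
#' @param sample_value The sample's value at that gene.
#' @return Percentile in `[0, 100]`.
#' @export
expression_percentile <- function(cohort_values, sample_value) {
  n <- length(cohort_values)
  if (n == 0) stop("empty cohort")
  if (n == 1) return(50)
  r <- sum(cohort_values < sample_value) +
    (1 + sum(cohort_values == sample_value)) / 2
  (r - 1) / (n - 1) * 100
}

#' Tukey outlier fences and flags
#'
#' Quartiles by linear interpolation between order statistics (quantile
#' type 7); values above `q3 + 1.5 * IQR` are over-expression outliers, below
#' `q1 - 1.5 * IQR` under-expression outliers.
#'
#' @param values Numeric vector, length >= 4.
#' @return Object of class `outlier_fences`: `q1`, `q3`, `iqr`, `lower`,
#'   `upper`, and logical flags `over`, `under`.
#' @export
tukey_fences <- function(values) {
  if (length(values) < 4) stop("need at least 4 values for stable quartiles")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  upper <- q[2] + 1.5 * iqr
  lower <- q[1] - 1.5 * iqr
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr, lower = lower,
                 upper = upper, over = values > upper, under = values < lower),
            class = "outlier_fences")
}

#' Test fusion-expression associations per gene and cancer type
#'
#' Within each cancer type, every fused gene is tested two ways on the
#' log2(x+1) scale: a Welch t test of fusion vs non-fusion samples, and
#' Fisher's exact test of Tukey outlier status (over- and under-expression
#' separately) against fusion status. All p-value families are
#' Benjamini-Hochberg corrected across the full set of (gene, cancer type)
#' tests. A gene is flagged for review when any corrected q-value passes
#' `fdr`, at least `min_fusions` fusion samples carry it, and the fusion
#' samples' median expression percentile falls in the top or bottom decile.
#'
#' @param expression Genes x samples numeric matrix (linear scale).
#' @param fusions Data frame with `sample_id` and `gene` (one row per fused
#'   gene per sample).
#' @param metadata Data frame with `sample_id`, `cancer_type`.
#' @param genes Optional restriction to a gene set (e.g. kinases, oncogenes).
#' @param fdr BH q-value threshold.
#' @param min_fusions Minimum fusion samples for review flagging.
#' @return Data frame: `gene`, `cancer_type`, `n_fusion_samples`, `t_p`,
#'   `fisher_over_p`, `fisher_under_p`, matching `*_q` columns,
#'   `median_fusion_percentile`, `flagged_for_review`.
#' @export
fusion_expression_association <- function(expression, fusions, metadata,
                                          genes = NULL, fdr = 0.05,
                                          min_fusions = 3) {
  lg <- log2(expression + 1)
  rows <- list()
  for (ct in sort(unique(metadata$cancer_type))) {
    ct_samples <- metadata$sample_id[metadata$cancer_type == ct]
    ct_samples <- intersect(ct_samples, colnames(lg))
    if (length(ct_samples) < 4) next
    fus_ct <- fusions[fusions$sample_id %in% ct_samples, , drop = FALSE]
    test_genes <- intersect(unique(fus_ct$gene), rownames(lg))
    if (!is.null(genes)) test_genes <- intersect(test_genes, genes)
    for (g in test_genes) {
      x <- lg[g, ct_samples]
      carrier <- ct_samples %in% fus_ct$sample_id[fus_ct$gene == g]
      nf <- sum(carrier)
      if (nf == 0) next
      t_p <- if (nf >= 2 && sum(!carrier) >= 2)
        tryCatch(stats::t.test(x[carrier], x[!carrier])$p.value,
                 error = function(e) NA_real_) else NA_real_
      fen <- tukey_fences(x)
      fp <- function(flag) {
        tab <- table(factor(flag, c(FALSE, TRUE)),
                     factor(carrier, c(FALSE, TRUE)))
        tryCatch(stats::fisher.test(tab)$p.value,
                 error = function(e) NA_real_)
      }
      pct <- vapply(which(carrier), function(j)
        expression_percentile(x, x[j]), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, cancer_type = ct, n_fusion_samples = nf, t_p = t_p,
        fisher_over_p = fp(fen$over), fisher_under_p = fp(fen$under),
        median_fusion_percentile = stats::median(pct),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(0), cancer_type = character(0),
                      n_fusion_samples = integer(0), t_p = numeric(0),
                      fisher_over_p = numeric(0), fisher_under_p = numeric(0),
                      t_q = numeric(0), fisher_over_q = numeric(0),
                      fisher_under_q = numeric(0),
                      median_fusion_percentile = numeric(0),
                      flagged_for_review = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$t_q <- stats::p.adjust(res$t_p, "BH")
  res$fisher_over_q <- stats::p.adjust(res$fisher_over_p, "BH")
  res$fisher_under_q <- stats::p.adjust(res$fisher_under_p, "BH")
  min_q <- suppressWarnings(pmin(res$t_q, res$fisher_over_q,
                                 res$fisher_under_q, na.rm = TRUE))
  min_q[!is.finite(min_q)] <- NA
  res$flagged_for_review <- !is.na(min_q) & min_q < fdr &
    res$n_fusion_samples >= min_fusions &
    (res$median_fusion_percentile >= 90 | res$median_fusion_percentile <= 10)
  res
}

#' Restrict fusions to copy-number-quiet kinase loci
#'
#' Keeps fusions whose kinase gene has `low <= copies <= high` (inclusive) in
#' the fusion-bearing sample, controlling for amplification-driven expression.
#' Fusions with no copy value are excluded with a warning.
#'
#' @param fusions Data frame with `sample_id` and a `kinase_gene` column (or
#'   `gene` as fallback).
#' @param copy_table Genes x samples copy-number matrix.
#' @param low,high Inclusive copy bounds.
#' @return The kept subset of `fusions` with an added `copy_number` column.
#' @export
copy_number_filter <- function(fusions, copy_table, low = 1, high = 3) {
  gcol <- if ("kinase_gene" %in% names(fusions)) "kinase_gene" else "gene"
  cn <- rep(NA_real_, nrow(fusions))
  for (i in seq_len(nrow(fusions))) {
    g <- fusions[[gcol]][i]; s <- fusions$sample_id[i]
    if (!is.na(g) && g %in% rownames(copy_table) &&
        s %in% colnames(copy_table))
      cn[i] <- copy_table[g, s]
  }
  if (any(is.na(cn)))
    warning(sum(is.na(cn)), " fusion(s) without copy-number values excluded")
  out <- fusions[!is.na(cn) & cn >= low & cn <= high, , drop = FALSE]
  out$copy_number <- cn[!is.na(cn) & cn >= low & cn <= high]
  out
}

#' Categorize copy-number values for display
#'
#' Deterministic mapping of a log2-ratio-like value to the five display
#' categories used for copy-number annotation.
#'
#' @param values Numeric copy values on a log2-ratio-like scale.
#' @param cuts Four increasing cut points.
#' @return Character vector of categories.
#' @export
copy_number_category <- function(values, cuts = c(-2, -1, 1, 2)) {
  stopifnot(length(cuts) == 4, !is.unsorted(cuts))
  as.character(cut(values, c(-Inf, cuts, Inf),
                   labels = c("DEEP_DELETION", "LOSS", "NEUTRAL", "GAIN",
                              "HIGH_AMPLIFICATION"),
                   right = FALSE))
}

#' Compare kinase vs partner expression in fusion-bearing samples
#'
#' For each (filtered, intact-domain) kinase fusion, compares the cohort
#' expression percentiles of the kinase gene and its partner in the
#' fusion-bearing sample: absolute difference within `equal_band` percentile
#' points is `EQUAL`, otherwise `PARTNER_HIGHER` / `PARTNER_LOWER`. Also
#' reports the kinase expression quantile (percentile / 100).
#'
#' @param expression Genes x samples matrix.
#' @param fusions Data frame with `sample_id`, `cancer_type`, `kinase_gene`,
#'   and partner via `gene5`/`gene3` plus `kinase_role`.
#' @param metadata Data frame with `sample_id`, `cancer_type`.
#' @param equal_band Percentile half-width treated as equal expression.
#' @return `fusions` with added `partner_gene`, `kinase_quantile`,
#'   `partner_percentile`, `category` (`NA` when the partner is missing from
#'   the matrix).
#' @export
kinase_partner_comparison <- function(expression, fusions, metadata,
                                      equal_band = 5) {
  lg <- log2(expression + 1)
  n <- nrow(fusions)
  partner <- ifelse(fusions$kinase_role == "THREE_KINASE", fusions$gene5,
                    fusions$gene3)
  kq <- rep(NA_real_, n); pp <- rep(NA_real_, n)
  cat <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- fusions$sample_id[i]
    ct <- fusions$cancer_type[i]
    cohort <- intersect(metadata$sample_id[metadata$cancer_type == ct],
                        colnames(lg))
    kg <- fusions$kinase_gene[i]
    if (is.na(kg) || !kg %in% rownames(lg) || !s %in% cohort) next
    pk <- expression_percentile(lg[kg, cohort], lg[kg, s])
    kq[i] <- pk / 100
    if (!partner[i] %in% rownames(lg)) next
    pp[i] <- expression_percentile(lg[partner[i], cohort], lg[partner[i], s])
    d <- pp[i] - pk
    cat[i] <- if (abs(d) <= equal_band) "EQUAL"
              else if (d > 0) "PARTNER_HIGHER" else "PARTNER_LOWER"
  }
  fusions$partner_gene <- partner
  fusions$kinase_quantile <- kq
  fusions$partner_percentile <- pp
  fusions$category <- cat
  fusions
}
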