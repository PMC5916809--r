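#' Mismatch-repair and proofreading genes whose mutation marks hypermutators
#' @export
mmr_genes <- c("POLE", "MLH1", "MLH3", "MGMT", "MSH6", "MSH3", "MSH2",
               "PMS1", "PMS2")

#' MAF variant classes counted as driver-gene alteration events
#' @export
driver_variant_classes <- c("In_Frame_Del", "In_Frame_Ins",
                            "Missense_Mutation", "Nonsense_Mutation",
                            "Nonstop_Mutation", "Splice_Site",
                            "Translation_Start_Site")

#' Per-sample genomic alteration profiles
#'
#' Summarizes, per sample: whether it carries a curated driver mutation
#' (`is_driver`-flagged MAF row in a driver gene with a qualifying variant
#' class), any qualifying mutation in a driver gene, a fusion involving a
#' driver gene, its total mutation burden (all MAF rows), and whether any
#' mismatch-repair/proofreading gene is mutated.
#'
#' @param maf MAF-like data frame: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#'   `Variant_Classification`, and a logical driver-mutation flag column.
#' @param fusions Kept fusion calls (`sample_id`, `gene5`, `gene3`).
#' @param driver_genes Character vector of driver gene symbols.
#' @param samples Sample universe; defaults to samples seen in `maf` or
#'   `fusions`.
#' @param driver_flag_col Name of the curated driver-mutation flag column.
#' @return Data frame of class `alteration_profiles`: `sample_id`,
#'   `has_driver_mutation`, `has_driver_gene_mutation`, `has_driver_fusion`,
#'   `n_mutations`, `mmr_mutated`.
#' @export
build_alteration_profiles <- function(maf, fusions, driver_genes,
                                      samples = NULL,
                                      driver_flag_col = "is_driver") {
  if (!"Variant_Classification" %in% names(maf))
    stop("MAF is missing the Variant_Classification column")
  if (!driver_flag_col %in% names(maf))
    stop("MAF is missing the driver-mutation flag column '",
         driver_flag_col, "'")
  samples <- samples %||% sort(unique(c(maf$Tumor_Sample_Barcode,
                                        fusions$sample_id)))
  qual <- maf$Variant_Classification %in% driver_variant_classes
  in_driver <- maf$Hugo_Symbol %in% driver_genes
  is_drv <- as.logical(maf[[driver_flag_col]])
  fus_driver <- fusions$sample_id[fusions$gene5 %in% driver_genes |
                                    fusions$gene3 %in% driver_genes]
  prof <- data.frame(
    sample_id = samples,
    has_driver_mutation = vapply(samples, function(s)
      any(maf$Tumor_Sample_Barcode == s & qual & in_driver & is_drv),
      logical(1)),
    has_driver_gene_mutation = vapply(samples, function(s)
      any(maf$Tumor_Sample_Barcode == s & qual & in_driver), logical(1)),
    has_driver_fusion = samples %in% fus_driver,
    n_mutations = vapply(samples, function(s)
      sum(maf$Tumor_Sample_Barcode == s), integer(1)),
    mmr_mutated = vapply(samples, function(s)
      any(maf$Tumor_Sample_Barcode == s & maf$Hugo_Symbol %in% mmr_genes),
      logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(prof) <- c("alteration_profiles", class(prof))
  prof
}

#' Assign each sample to a driver-alteration group
#'
#' The six groups partition the cohort: known driver mutation and/or driver
#' fusion, driver-gene mutation without a known driver mutation (with or
#' without fusion), fusion only, or no driver alteration.
#'
#' @param profiles Output of [build_alteration_profiles()].
#' @return Character vector: one of `DRIVER_MUT_ONLY`, `MUT_ONLY`,
#'   `DRIVER_MUT_AND_FUSION`, `MUT_AND_FUSION`, `FUSION_ONLY`, `NONE`.
#' @export
classify_driver_group <- function(profiles) {
  dm <- profiles$has_driver_mutation
  m <- profiles$has_driver_gene_mutation
  f <- profiles$has_driver_fusion
  ifelse(dm & f, "DRIVER_MUT_AND_FUSION",
  ifelse(m & f, "MUT_AND_FUSION",
  ifelse(dm, "DRIVER_MUT_ONLY",
  ifelse(m, "MUT_ONLY",
  ifelse(f, "FUSION_ONLY", "NONE")))))
}

#' Compare mutation burden between driver groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of total mutation counts
#' between two driver groups. Samples with mutations in mismatch-repair or
#' proofreading genes are removed first to exclude the microsatellite
#' instability confounder.
#'
#' @param profiles Output of [build_alteration_profiles()].
#' @param group_a,group_b Driver-group labels (each may be a vector of labels
#'   to pool).
#' @param exclude_mmr Remove `mmr_mutated` samples before testing.
#' @return List: `p_value`, `statistic` (the U statistic), `n_a`, `n_b`.
#' @export
burden_comparison <- function(profiles, group_a, group_b,
                              exclude_mmr = TRUE) {
  grp <- classify_driver_group(profiles)
  keep <- if (exclude_mmr) !profiles$mmr_mutated else rep(TRUE, nrow(profiles))
  x <- profiles$n_mutations[keep & grp %in% group_a]
  y <- profiles$n_mutations[keep & grp %in% group_b]
  if (length(x) == 0 || length(y) == 0)
    stop("empty group after MMR exclusion")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_a = length(x), n_b = length(y))
}

#' Gene x sample alteration-type matrix
#'
#' For mutual-exclusivity inspection: each cell records whether the sample
#' carries a fusion, a qualifying mutation, both, or neither in that gene.
#'
#' @param fusions Kept fusion calls (`sample_id`, `gene5`, `gene3`).
#' @param maf MAF-like data frame.
#' @param genes Genes of interest (rows).
#' @param samples Sample universe; defaults to samples with at least one
#'   alteration in `genes`.
#' @param variant_classes Mutation classes that count.
#' @return Character matrix genes x samples with values `FUSION`, `MUTATION`,
#'   `BOTH`, `NONE`.
#' @export
exclusivity_matrix <- function(fusions, maf, genes, samples = NULL,
                               variant_classes = driver_variant_classes) {
  if (length(genes) == 0)
    return(matrix(character(0), nrow = 0, ncol = 0))
  mut <- maf[maf$Variant_Classification %in% variant_classes &
               maf$Hugo_Symbol %in% genes, , drop = FALSE]
  fus <- fusions[fusions$gene5 %in% genes | fusions$gene3 %in% genes, ,
                 drop = FALSE]
  samples <- samples %||% sort(unique(c(mut$Tumor_Sample_Barcode,
                                        fus$sample_id)))
  m <- matrix("NONE", length(genes), length(samples),
              dimnames = list(genes, samples))
  for (g in genes) for (s in samples) {
    has_f <- any(fus$sample_id == s & (fus$gene5 == g | fus$gene3 == g))
    has_m <- any(mut$Tumor_Sample_Barcode == s & mut$Hugo_Symbol == g)
    m[g, s] <- if (has_f && has_m) "BOTH" else if (has_f) "FUSION"
               else if (has_m) "MUTATION" else "NONE"
  }
  m
}

#' Match fusions against a druggability table
#'
#' A fusion is druggable when literature supports a drug against it: an entry
#' matches when its gene is one of the fusion partners and, if the entry
#' requires a specific partner, the other partner matches too. Off-label
#' entries count only when `allow_off_label` is `TRUE`. A sample is druggable
#' when at least one of its fusions matches at least one entry.
#'
#' @param fusions Kept fusion calls (`sample_id`, `gene5`, `gene3`,
#'   optionally `call_id`).
#' @param drug_table Data frame: `gene`, `partner` (`NA` for any),
#'   `cancer_type`, `drug`, `label` (`ON_LABEL`/`OFF_LABEL`).
#' @param allow_off_label Include off-label drug entries.
#' @param samples Sample universe for the per-sample flag; defaults to the
#'   fusion-bearing samples.
#' @return List: `matches` (one row per fusion x matching entry) and
#'   `sample_druggable` (`sample_id`, `druggable`).
#' @export
annotate_druggable <- function(fusions, drug_table, allow_off_label = TRUE,
                               samples = NULL) {
  dt <- drug_table
  if (!allow_off_label) dt <- dt[dt$label == "ON_LABEL", , drop = FALSE]
  matches <- list()
  for (i in seq_len(nrow(fusions))) {
    pair <- c(fusions$gene5[i], fusions$gene3[i])
    for (j in seq_len(nrow(dt))) {
      if (!dt$gene[j] %in% pair) next
      if (!is.na(dt$partner[j]) && nzchar(dt$partner[j])) {
        other <- setdiff(pair, dt$gene[j])
        if (!dt$partner[j] %in% other) next
      }
      matches[[length(matches) + 1]] <- data.frame(
        call_id = fusions$call_id[i] %||% NA_character_,
        sample_id = fusions$sample_id[i],
        gene5 = pair[1], gene3 = pair[2], target = dt$gene[j],
        drug = dt$drug[j], label = dt$label[j], stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(call_id = character(0), sample_id = character(0),
               gene5 = character(0), gene3 = character(0),
               target = character(0), drug = character(0),
               label = character(0), stringsAsFactors = FALSE)
  samples <- samples %||% sort(unique(fusions$sample_id))
  list(matches = matches,
       sample_druggable = data.frame(
         sample_id = samples,
         druggable = samples %in% matches$sample_id,
         stringsAsFactors = FALSE))
}

#' Chi-square test of druggable-fusion status by smoking status
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' druggable-fusion status against smoking status.
#'
#' @param druggable Logical vector (or a prebuilt 2x2 table as first and only
#'   argument).
#' @param smoking Character/factor vector (e.g. `"never"`/`"ever"`).
#' @return List: `statistic`, `p_value`, `table`. Both are `NA` with a
#'   warning when a table margin is zero.
#' @export
smoking_association <- function(druggable, smoking = NULL) {
  tab <- if (is.matrix(druggable) || is.table(druggable)) as.table(druggable)
         else table(smoking = smoking, druggable = druggable)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 table; chi-square undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}
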