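#' Resources consumed by the fusion filter cascade
#'
#' @param exclusion_genes Symbols whose fusions are always removed
#'   (uncharacterized genes, immunoglobulin genes, mitochondrial genes, ...).
#' @param paralog_pairs Data frame with two columns of paralogous symbols
#'   (unordered pairs).
#' @param normals_panel Data frame with two columns: gene pairs observed in
#'   normal samples (panel of normals); matched as unordered pairs.
#' @param allowlist Data frame with two columns: gene pairs exempt from the
#'   recurrent-artifact rule (previously reported bona fide fusions).
#' @param ffpm_min Minimum FFPM required of single-caller calls.
#' @param recurrence_max Identical-breakpoint recurrence (distinct samples,
#'   spanning two or more cancer types) at or above which calls are removed.
#' @return An object of class `filter_resources`.
#' @export
filter_resources <- function(exclusion_genes = character(),
                             paralog_pairs = NULL, normals_panel = NULL,
                             allowlist = NULL, ffpm_min = 0.1,
                             recurrence_max = 10L) {
  if (ffpm_min <= 0 || recurrence_max <= 0)
    stop("thresholds must be positive")
  keys <- function(df) {
    if (is.null(df) || nrow(df) == 0) character(0)
    else pair_key(df[[1]], df[[2]])
  }
  structure(list(
    exclusion_genes = toupper(exclusion_genes),
    paralog_keys = keys(paralog_pairs),
    normals_keys = keys(normals_panel),
    allow_keys = keys(allowlist),
    ffpm_min = ffpm_min, recurrence_max = as.integer(recurrence_max)
  ), class = "filter_resources")
}

#' Breakpoint-level recurrence index
#'
#' Groups calls by exact coordinates of both breakpoints and counts distinct
#' samples and distinct cancer types per group.
#'
#' @param calls Canonical fusion-call data frame; a `cancer_type` column is
#'   used when present (one type assumed otherwise).
#' @return Data frame: `bp_key`, `n_samples`, `n_cancer_types`.
#' @export
recurrence_index <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(bp_key = character(0), n_samples = integer(0),
                      n_cancer_types = integer(0), stringsAsFactors = FALSE))
  ct <- if ("cancer_type" %in% names(calls)) calls$cancer_type else "ALL"
  key <- paste(calls$chrom5, calls$pos5, calls$chrom3, calls$pos3, sep = ":")
  agg <- lapply(split(seq_along(key), key), function(idx)
    c(length(unique(calls$sample_id[idx])),
      length(unique(ct[idx]))))
  data.frame(bp_key = names(agg),
             n_samples = vapply(agg, `[`, 0, 1),
             n_cancer_types = vapply(agg, `[`, 0, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

.rule_labels <- c(R1 = "R1_EXCLUDED_GENE", R2 = "R2_SELF_OR_PARALOG",
                  R3 = "R3_NORMALS_PANEL", R4 = "R4_FFPM",
                  R5 = "R5_RECURRENT_ARTIFACT")

#' Apply the five-rule fusion filter cascade
#'
#' Rules, evaluated conjunctively:
#' R1 either partner on the exclusion list; R2 self-fusion or paralog pair;
#' R3 gene pair in the panel of normals; R4 single-caller call with
#' FFPM <= `ffpm_min` (calls reported by two or more callers are exempt);
#' R5 identical breakpoints recurring in >= `recurrence_max` distinct samples
#' spanning >= 2 cancer types, unless the gene pair is allowlisted. The kept
#' set does not depend on rule order; `failed_rule` records the first
#' violated rule in `rule_order`.
#'
#' @param calls Canonical fusion-call data frame (the full multi-sample set:
#'   R5 is cohort-level). Single-caller calls must carry `ffpm`.
#' @param resources A [filter_resources()].
#' @param rule_order Permutation of `c("R1","R2","R3","R4","R5")` used only
#'   for labelling `failed_rule`.
#' @return Data frame: `call_id`, `kept`, `failed_rule`.
#' @export
apply_filter_cascade <- function(calls, resources,
                                 rule_order = c("R1", "R2", "R3", "R4", "R5")) {
  stopifnot(inherits(resources, "filter_resources"))
  stopifnot(setequal(rule_order, c("R1", "R2", "R3", "R4", "R5")))
  n <- nrow(calls)
  ids <- if ("call_id" %in% names(calls)) calls$call_id
         else sprintf("C%05d", seq_len(n))
  if (n == 0)
    return(data.frame(call_id = character(0), kept = logical(0),
                      failed_rule = character(0), stringsAsFactors = FALSE))
  g5 <- toupper(calls$gene5); g3 <- toupper(calls$gene3)
  pk <- pair_key(calls$gene5, calls$gene3)
  ncall <- .n_callers(calls$callers)
  if (any(ncall == 1 & is.na(calls$ffpm)))
    stop("single-caller call(s) missing ffpm: ",
         paste(ids[ncall == 1 & is.na(calls$ffpm)], collapse = ", "))

  fails <- cbind(
    R1 = g5 %in% resources$exclusion_genes |
         g3 %in% resources$exclusion_genes,
    R2 = g5 == g3 | pk %in% resources$paralog_keys,
    R3 = pk %in% resources$normals_keys,
    R4 = ncall == 1 & !is.na(calls$ffpm) & calls$ffpm <= resources$ffpm_min,
    R5 = {
      rec <- recurrence_index(calls)
      hot <- rec$bp_key[rec$n_samples >= resources$recurrence_max &
                        rec$n_cancer_types >= 2]
      key <- paste(calls$chrom5, calls$pos5, calls$chrom3, calls$pos3,
                   sep = ":")
      key %in% hot & !(pk %in% resources$allow_keys)
    })

  ord <- fails[, rule_order, drop = FALSE]
  first <- apply(ord, 1, function(z) {
    i <- which(z)[1]
    if (is.na(i)) "NONE" else .rule_labels[[rule_order[i]]]
  })
  data.frame(call_id = ids, kept = !apply(fails, 1, any),
             failed_rule = unname(first), stringsAsFactors = FALSE)
}
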