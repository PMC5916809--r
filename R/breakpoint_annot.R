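#' Breakpoint-region category of a fusion
#'
#' Returns the ordered (5' partner region, 3' partner region) pair used for
#' the breakpoint-category taxonomy; intronic breakpoints collapse into the
#' non-coding category.
#'
#' @param locus5,locus3 `transcript_locus` objects for the two partners.
#' @return Character vector of length 2: regions of the 5' and 3' partner.
#' @export
classify_breakpoint_pair <- function(locus5, locus3) {
  squash <- function(r) if (r == "INTRON") "NONCODING" else r
  c(squash(locus5$region), squash(locus3$region))
}

#' Predict the reading frame of a fusion junction
#'
#' `INFRAME` when the retained 5' coding bases and the discarded 3' coding
#' bases agree modulo 3 (the 3' partner's codon boundaries are preserved);
#' `FRAMESHIFT` otherwise; `NO_FRAME` when either breakpoint is outside a CDS
#' (UTR, intron, or non-coding RNA).
#'
#' @param locus5 Locus of the 5' partner computed with
#'   `locate_breakpoint(..., side = "5prime")` (cds_offset = retained bases).
#' @param locus3 Locus of the 3' partner computed with the default side
#'   (cds_offset = discarded bases).
#' @return One of `"INFRAME"`, `"FRAMESHIFT"`, `"NO_FRAME"`.
#' @export
predict_frame <- function(locus5, locus3) {
  if (locus5$region != "CDS" || locus3$region != "CDS") return("NO_FRAME")
  if ((locus5$cds_offset - locus3$cds_offset) %% 3 == 0) "INFRAME"
  else "FRAMESHIFT"
}

#' Is the kinase domain retained in the fusion product?
#'
#' For a 5'-kinase the domain is retained when the breakpoint lies at or
#' downstream of the domain end (`aa_pos >= aa_end`, boundary inclusive) or in
#' the 3' UTR; the 3' partner's frame is irrelevant because the kinase portion
#' of the ORF is upstream of the junction. For a 3'-kinase the domain is
#' retained when the breakpoint is in the kinase's 5' UTR (promoter swap,
#' whole ORF kept) or at/upstream of the domain start *and* the junction is
#' in frame. Genes with several annotated kinase domains count as intact if
#' any domain is intact.
#'
#' @param gene Kinase gene symbol (must appear in `domains`).
#' @param side `"five"` or `"three"`: which fusion end the kinase occupies.
#' @param locus5,locus3 The partner loci (see [predict_frame()] for the side
#'   conventions).
#' @param frame Result of [predict_frame()].
#' @param domains Domain table: columns `gene`, `aa_start`, `aa_end`.
#' @return `"INTACT"` or `"DISRUPTED"`.
#' @export
assess_domain_retention <- function(gene, side = c("five", "three"),
                                    locus5, locus3, frame, domains) {
  side <- match.arg(side)
  rows <- domains[domains$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("kinase gene ", gene, " is missing from the domain table")
  intact <- vapply(seq_len(nrow(rows)), function(i) {
    if (side == "five") {
      locus5$region == "THREE_UTR" ||
        (locus5$region == "CDS" && locus5$aa_pos >= rows$aa_end[i])
    } else {
      locus3$region == "FIVE_UTR" ||
        (locus3$region == "CDS" && locus3$aa_pos <= rows$aa_start[i] &&
           frame == "INFRAME")
    }
  }, logical(1))
  if (any(intact)) "INTACT" else "DISRUPTED"
}

#' Classify the kinase role of a fusion
#'
#' Assigns `FIVE_KINASE`, `THREE_KINASE`, `BOTH_KINASE`, or `NONE` by kinase
#' table membership of each partner. A both-kinase fusion with exactly one
#' intact kinase domain is reassigned to the side carrying the intact domain;
#' with two or zero intact domains it stays `BOTH_KINASE`.
#'
#' @param gene5,gene3 Partner symbols.
#' @param locus5,locus3 Partner loci.
#' @param frame Result of [predict_frame()].
#' @param kinases Kinase table: columns `gene`, `group`.
#' @param domains Domain table (see [assess_domain_retention()]).
#' @return List: `role`, `kinase_gene`, `group`, `domain_status` (`"NA"` when
#'   `role == "NONE"`).
#' @export
classify_kinase_role <- function(gene5, gene3, locus5, locus3, frame,
                                 kinases, domains) {
  grp <- function(g) kinases$group[match(g, kinases$gene)]
  k5 <- gene5 %in% kinases$gene
  k3 <- gene3 %in% kinases$gene
  if (!k5 && !k3)
    return(list(role = "NONE", kinase_gene = NA_character_,
                group = NA_character_, domain_status = "NA"))
  if (k5 && !k3) {
    st <- assess_domain_retention(gene5, "five", locus5, locus3, frame, domains)
    return(list(role = "FIVE_KINASE", kinase_gene = gene5,
                group = grp(gene5), domain_status = st))
  }
  if (!k5 && k3) {
    st <- assess_domain_retention(gene3, "three", locus5, locus3, frame, domains)
    return(list(role = "THREE_KINASE", kinase_gene = gene3,
                group = grp(gene3), domain_status = st))
  }
  s5 <- assess_domain_retention(gene5, "five", locus5, locus3, frame, domains)
  s3 <- assess_domain_retention(gene3, "three", locus5, locus3, frame, domains)
  if (s5 == "INTACT" && s3 != "INTACT")
    return(list(role = "FIVE_KINASE", kinase_gene = gene5, group = grp(gene5),
                domain_status = "INTACT"))
  if (s3 == "INTACT" && s5 != "INTACT")
    return(list(role = "THREE_KINASE", kinase_gene = gene3, group = grp(gene3),
                domain_status = "INTACT"))
  list(role = "BOTH_KINASE", kinase_gene = gene3, group = grp(gene3),
       domain_status = if (s5 == "INTACT") "INTACT" else "DISRUPTED")
}

#' Annotate fusion calls with loci, category, frame, and kinase status
#'
#' @param calls Canonical fusion-call data frame.
#' @param models Named list of [gene_model()] objects.
#' @param domains Domain table (`gene`, `aa_start`, `aa_end`).
#' @param kinases Kinase table (`gene`, `group`).
#' @return `calls` with added columns `region5`, `region3` (collapsed
#'   categories), `frame`, `kinase_role`, `kinase_gene`, `kinase_group`,
#'   `domain_status`, `aa5`, `aa3`, `offset5`, `offset3`. Calls whose partner
#'   genes are absent from `models` get `NA` annotations with a warning.
#' @export
annotate_fusions <- function(calls, models, domains, kinases) {
  n <- nrow(calls)
  cols <- list(region5 = character(n), region3 = character(n),
               frame = character(n), kinase_role = character(n),
               kinase_gene = NA_character_, kinase_group = NA_character_,
               domain_status = character(n),
               aa5 = rep(NA_integer_, n), aa3 = rep(NA_integer_, n),
               offset5 = rep(NA_integer_, n), offset3 = rep(NA_integer_, n))
  out <- cbind(calls, as.data.frame(cols, stringsAsFactors = FALSE))
  for (i in seq_len(n)) {
    m5 <- models[[calls$gene5[i]]]; m3 <- models[[calls$gene3[i]]]
    if (is.null(m5) || is.null(m3)) {
      warning("partner gene(s) missing from models for call ",
              calls$call_id[i] %||% i, "; annotations set to NA")
      out$region5[i] <- NA; out$region3[i] <- NA; out$frame[i] <- NA
      out$kinase_role[i] <- NA; out$domain_status[i] <- NA
      next
    }
    l5 <- locate_breakpoint(m5, calls$pos5[i], side = "5prime")
    l3 <- locate_breakpoint(m3, calls$pos3[i], side = "3prime")
    cat2 <- classify_breakpoint_pair(l5, l3)
    fr <- predict_frame(l5, l3)
    kr <- classify_kinase_role(calls$gene5[i], calls$gene3[i], l5, l3, fr,
                               kinases, domains)
    out$region5[i] <- cat2[1]; out$region3[i] <- cat2[2]
    out$frame[i] <- fr
    out$kinase_role[i] <- kr$role
    out$kinase_gene[i] <- kr$kinase_gene
    out$kinase_group[i] <- kr$group
    out$domain_status[i] <- kr$domain_status
    out$aa5[i] <- l5$aa_pos; out$aa3[i] <- l3$aa_pos
    out$offset5[i] <- l5$cds_offset; out$offset3[i] <- l3$cds_offset
  }
  out
}

#' Count kinase genes with fusions per cancer type and kinase group
#'
#' @param annotated Output of [annotate_fusions()] with a `cancer_type`
#'   column.
#' @param intact_only Restrict to fusions with an intact kinase domain.
#' @return Integer matrix cancer types x groups (distinct kinase genes).
#' @export
kinase_group_counts <- function(annotated, intact_only = TRUE) {
  k <- annotated[annotated$kinase_role %in%
                   c("FIVE_KINASE", "THREE_KINASE", "BOTH_KINASE"), ,
                 drop = FALSE]
  if (intact_only) k <- k[k$domain_status == "INTACT", , drop = FALSE]
  cts <- sort(unique(annotated$cancer_type))
  grps <- sort(unique(k$kinase_group))
  m <- matrix(0L, length(cts), length(grps), dimnames = list(cts, grps))
  for (ct in cts) for (g in grps) {
    sub <- k[k$cancer_type == ct & k$kinase_group == g, , drop = FALSE]
    m[ct, g] <- length(unique(sub$kinase_gene))
  }
  m
}

#' Normalized kinase-group percentages per cancer type
#'
#' The pan-cancer share of each group, `p_g = count_g / sum(count)`, is used
#' to normalize the per-cancer-type counts: `n_{g,c} = count_{g,c} / p_g`,
#' which are then rescaled within each cancer type to percentages summing to
#' 100. Groups with zero pan-cancer counts are dropped before normalization;
#' cancer types with zero kinase fusions are omitted with a warning.
#'
#' @param counts Matrix or data frame of fusion kinase-gene counts, cancer
#'   types in rows, kinase groups in columns.
#' @return List: `p_g` (pan-cancer shares), `normalized_counts`,
#'   `percentages` (rows sum to 100).
#' @export
normalized_group_percentages <- function(counts) {
  m <- as.matrix(counts)
  if (sum(m) <= 0) stop("pan-cancer total must be positive")
  tot <- colSums(m)
  if (any(tot == 0)) {
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p_g <- tot / sum(tot)
  n <- sweep(m, 2, p_g, "/")
  rs <- rowSums(n)
  if (any(rs == 0)) {
    warning("cancer type(s) with zero kinase fusions omitted: ",
            paste(rownames(m)[rs == 0], collapse = ", "))
    n <- n[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  list(p_g = p_g, normalized_counts = n, percentages = n / rs * 100)
}
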