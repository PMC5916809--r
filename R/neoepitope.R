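#' Translate a fusion transcript into its chimeric protein
#'
#' Builds the fusion CDS from the partners' transcript sequences: the retained
#' 5' coding prefix joined to the 3' coding suffix. In-frame products keep the
#' wild-type 3' residues past the junction; frameshift products are translated
#' in the shifted frame until the first stop codon (a novel tail). A fusion
#' whose breakpoints both fall in 5' UTRs is a promoter swap: the product is
#' the intact wild-type 3' protein with `junction_index = 0`. Any other
#' no-frame configuration has no resolvable start codon and errors.
#'
#' @param fusion List or one-row data frame with `gene5`, `gene3`, `pos5`,
#'   `pos3`.
#' @param models Named list of [gene_model()] objects.
#' @param tx_seqs Named character vector of transcript sequences.
#' @return Object of class `fusion_protein`: `sequence`, `junction_index`
#'   (residues fully encoded by the 5' gene; the junction lies between
#'   residues `junction_index` and `junction_index + 1`), `novel_tail`,
#'   `frame`.
#' @export
translate_fusion <- function(fusion, models, tx_seqs) {
  m5 <- models[[fusion$gene5]]; m3 <- models[[fusion$gene3]]
  if (is.null(m5) || is.null(m3))
    stop("partner gene(s) missing from models")
  l5 <- locate_breakpoint(m5, fusion$pos5, side = "5prime")
  l3 <- locate_breakpoint(m3, fusion$pos3, side = "3prime")
  frame <- predict_frame(l5, l3)
  if (frame %in% c("INFRAME", "FRAMESHIFT")) {
    cds5 <- .cds_sequence(m5, tx_seqs[[fusion$gene5]])
    cds3 <- .cds_sequence(m3, tx_seqs[[fusion$gene3]])
    r <- l5$cds_offset; d <- l3$cds_offset
    fus_cds <- paste0(substr(cds5, 1, r),
                      substr(cds3, d + 1, nchar(cds3)))
    protein <- .translate_cds(fus_cds)
    structure(list(sequence = protein,
                   junction_index = min(r %/% 3, nchar(protein)),
                   novel_tail = frame == "FRAMESHIFT", frame = frame),
              class = "fusion_protein")
  } else if (l5$region == "FIVE_UTR" && l3$region == "FIVE_UTR" &&
             m3$is_coding) {
    protein <- .translate_cds(.cds_sequence(m3, tx_seqs[[fusion$gene3]]))
    structure(list(sequence = protein, junction_index = 0L,
                   novel_tail = FALSE, frame = frame),
              class = "fusion_protein")
  } else {
    stop("no ATG context resolvable for fusion ", fusion$gene5, "--",
         fusion$gene3, " (no-frame breakpoints outside a 5'UTR swap)")
  }
}

#' @export
print.fusion_protein <- function(x, ...) {
  cat(sprintf("<fusion_protein> %d aa, junction after residue %d, %s%s\n",
              nchar(x$sequence), x$junction_index, x$frame,
              if (x$novel_tail) " (novel tail)" else ""))
  invisible(x)
}

#' Enumerate candidate junction peptides
#'
#' All full-length k-mers (default 8-11) that span the fusion junction, i.e.
#' contain both residues `junction_index` and `junction_index + 1`. For
#' frameshift products every residue past the junction is novel, so all
#' k-mers lying fully within the tail are additionally enumerated. Windows
#' truncated by the protein ends are dropped. A promoter-swap product
#' (junction_index 0, no novel residues) yields no peptides, as does a
#' product whose translation stops at or before the junction.
#'
#' @param protein A [translate_fusion()] result.
#' @param lengths Peptide lengths to enumerate.
#' @return Sorted character vector of unique peptides.
#' @export
enumerate_junction_peptides <- function(protein, lengths = 8:11) {
  stopifnot(inherits(protein, "fusion_protein"))
  p <- protein$sequence; n <- nchar(p); j <- protein$junction_index
  out <- character(0)
  for (L in lengths) {
    if (j >= 1 && j < n) {
      s_lo <- max(1, j - L + 2); s_hi <- min(j, n - L + 1)
      if (s_hi >= s_lo)
        out <- c(out, substring(p, s_lo:s_hi, (s_lo:s_hi) + L - 1))
    }
    if (protein$novel_tail && j + 1 <= n - L + 1) {
      s <- (j + 1):(n - L + 1)
      out <- c(out, substring(p, s, s + L - 1))
    }
  }
  sort(unique(out))
}

#' Call neoantigens among candidate fusion peptides
#'
#' Fusions supported by fewer than `min_split_reads` junction reads yield no
#' calls. Peptides occurring as exact substrings of any wild-type protein are
#' excluded before prediction; the rest are scored against each allele with
#' the supplied predictor. A peptide is a neoantigen when its predicted
#' affinity is at most `affinity_max` nM.
#'
#' @param peptides Candidate peptides (from
#'   [enumerate_junction_peptides()]).
#' @param wildtype_proteins Character vector of wild-type protein sequences
#'   (typically the two partners; pass a whole proteome for strict mode).
#' @param predictor Function `(peptide, allele) -> nM` (e.g.
#'   [toy_affinity_model()]).
#' @param alleles HLA allele labels to score.
#' @param affinity_max Neoantigen affinity threshold (nM).
#' @param min_split_reads Junction-read support required of the fusion.
#' @param junction_reads The fusion's junction read count.
#' @return Data frame: `peptide`, `allele`, `affinity_nM` (`NA` on predictor
#'   failure), `is_neoantigen`.
#' @export
call_neoantigens <- function(peptides, wildtype_proteins, predictor, alleles,
                             affinity_max = 500, min_split_reads = 5,
                             junction_reads = Inf) {
  empty <- data.frame(peptide = character(0), allele = character(0),
                      affinity_nM = numeric(0), is_neoantigen = logical(0),
                      stringsAsFactors = FALSE)
  if (junction_reads < min_split_reads || length(peptides) == 0) return(empty)
  wt <- vapply(peptides, function(p)
    any(vapply(wildtype_proteins, function(w) grepl(p, w, fixed = TRUE),
               logical(1))), logical(1))
  peptides <- peptides[!wt]
  if (length(peptides) == 0) return(empty)
  rows <- lapply(alleles, function(a) {
    aff <- vapply(peptides, function(p)
      tryCatch(predictor(p, a), error = function(e) NA_real_), numeric(1))
    data.frame(peptide = peptides, allele = a, affinity_nM = unname(aff),
               is_neoantigen = !is.na(aff) & aff <= affinity_max,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
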