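#' Genomic windows around the two fusion partner genes
#'
#' Each window is the partner gene's span extended by `flank` on both sides,
#' clipped at position 1. When the two windows overlap (genomic-neighbor
#' partners), the shared region is ambiguous: an ordinary concordant pair
#' falls entirely inside it, so the overlap is excluded from both windows
#' before counting.
#'
#' @param call One canonical fusion-call row (needs `gene5`, `gene3`).
#' @param models Named list of [gene_model()] objects.
#' @param flank Bases added up- and downstream of each gene span.
#' @return Object of class `partner_windows`: two interval sets (`w5`, `w3`),
#'   each a data frame `chrom`, `start`, `end` (1-based closed; possibly 0 or
#'   2 rows after overlap exclusion).
#' @export
partner_windows <- function(call, models, flank = 1e5) {
  win <- function(sym) {
    m <- models[[sym]]
    if (is.null(m)) stop("unknown gene symbol: ", sym)
    sp <- .gene_span(m)
    data.frame(chrom = m$chromosome,
               start = max(1, sp[1] + 1 - flank),
               end = sp[2] + flank, stringsAsFactors = FALSE)
  }
  w5 <- win(call$gene5); w3 <- win(call$gene3)
  if (w5$chrom == w3$chrom && w5$start <= w3$end && w3$start <= w5$end) {
    ov <- c(max(w5$start, w3$start), min(w5$end, w3$end))
    w5 <- .interval_minus(w5, ov)
    w3 <- .interval_minus(w3, ov)
  }
  structure(list(w5 = w5, w3 = w3), class = "partner_windows")
}

# Subtract closed interval ov = c(start, end) from a one-row window frame.
.interval_minus <- function(w, ov) {
  parts <- list()
  if (w$start < ov[1])
    parts[[length(parts) + 1]] <- data.frame(chrom = w$chrom, start = w$start,
                                             end = ov[1] - 1,
                                             stringsAsFactors = FALSE)
  if (w$end > ov[2])
    parts[[length(parts) + 1]] <- data.frame(chrom = w$chrom,
                                             start = ov[2] + 1, end = w$end,
                                             stringsAsFactors = FALSE)
  if (length(parts) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, parts)
}

.in_intervals <- function(iv, chrom, pos) {
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(iv)))
    hit <- hit | (chrom == iv$chrom[i] & pos >= iv$start[i] & pos <= iv$end[i])
  hit
}

# Read primary alignments from a SAM/BAM file via Rsamtools. Returns a data
# frame qname/flag/rname/pos/mapq.
.read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam_path <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else {
    first <- readLines(path, n = 1)
    if (length(first) == 0 || !startsWith(first, "@"))
      stop("invalid or truncated SAM input '", path,
           "': missing header (@HD/@SQ lines)")
    dest <- tempfile(fileext = ".bam")
    tryCatch(Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                              overwrite = TRUE, indexDestination = FALSE),
             error = function(e)
               stop("invalid or truncated SAM input '", path, "': ",
                    conditionMessage(e)))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "flag", "rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             rname = as.character(res$rname), pos = res$pos, mapq = res$mapq,
             stringsAsFactors = FALSE)
}

#' Count discordant read pairs supporting a fusion
#'
#' A template qualifies when its two primary mates land one in each partner
#' window (after overlap exclusion) and both mates have mapping quality at
#' least `min_mapq`. Pairs with both mates in the same window, pairs entirely
#' within the window overlap, secondary and supplementary records, and
#' low-quality mates do not count; each template is counted once.
#'
#' @param alignments Path to a SAM/BAM file, or a data frame with columns
#'   `qname`, `flag`, `rname`, `pos`, `mapq`.
#' @param windows A [partner_windows()] object.
#' @param min_mapq Minimum mapping quality for *both* mates.
#' @return Integer count of qualifying templates.
#' @export
count_discordant_pairs <- function(alignments, windows, min_mapq = 20) {
  stopifnot(inherits(windows, "partner_windows"))
  aln <- if (is.character(alignments)) .read_alignments(alignments)
         else alignments
  if (nrow(aln) == 0) return(0L)
  # primary mates only (flag bits 0x100/0x800 already excluded for files)
  aln <- aln[bitwAnd(aln$flag, 0x100) == 0 & bitwAnd(aln$flag, 0x800) == 0, ,
             drop = FALSE]
  in5 <- .in_intervals(windows$w5, aln$rname, aln$pos)
  in3 <- .in_intervals(windows$w3, aln$rname, aln$pos)
  ok <- aln$mapq >= min_mapq
  n <- 0L
  for (idx in split(seq_len(nrow(aln)), aln$qname)) {
    if (length(idx) < 2) next
    first <- idx[bitwAnd(aln$flag[idx], 0x40) != 0][1]
    second <- idx[bitwAnd(aln$flag[idx], 0x80) != 0][1]
    if (is.na(first) || is.na(second)) next
    if (!ok[first] || !ok[second]) next
    if ((in5[first] && in3[second]) || (in3[first] && in5[second]))
      n <- n + 1L
  }
  n
}

#' Threshold a discordant-pair count into a validation status
#'
#' @param n_discordant Qualifying discordant pair count.
#' @param has_wgs Whether WGS was available for the sample.
#' @param min_pairs Pairs required to call a fusion validated.
#' @return One of `"VALIDATED"`, `"NOT_VALIDATED"`, `"NOT_EVALUABLE"`.
#' @export
validate_call <- function(n_discordant, has_wgs, min_pairs = 3) {
  stopifnot(n_discordant >= 0)
  if (!isTRUE(has_wgs)) return("NOT_EVALUABLE")
  if (n_discordant >= min_pairs) "VALIDATED" else "NOT_VALIDATED"
}

#' WGS validation rate
#'
#' Fraction of evaluable fusions that validated; samples without WGS are
#' excluded from the denominator.
#'
#' @param results Data frame with a `status` column, or a character vector of
#'   statuses.
#' @return Fraction in (0, 1).
#' @export
validation_rate <- function(results) {
  status <- if (is.data.frame(results)) results$status else results
  n_val <- sum(status == "VALIDATED")
  n_eval <- n_val + sum(status == "NOT_VALIDATED")
  if (n_eval == 0) stop("no evaluable fusions (all NOT_EVALUABLE)")
  n_val / n_eval
}

#' Validate a set of fusion calls against per-sample WGS alignments
#'
#' @param calls Canonical fusion-call data frame.
#' @param models Named list of [gene_model()] objects.
#' @param sam_paths Named character vector or list: SAM/BAM path per sample;
#'   samples absent from it are `NOT_EVALUABLE`.
#' @param flank,min_mapq,min_pairs See [partner_windows()],
#'   [count_discordant_pairs()], [validate_call()].
#' @return Data frame: `call_id`, `n_discordant`, `status`.
#' @export
validate_fusions <- function(calls, models, sam_paths, flank = 1e5,
                             min_mapq = 20, min_pairs = 3) {
  aln_cache <- new.env(parent = emptyenv())
  get_aln <- function(s) {
    if (!is.null(aln_cache[[s]])) return(aln_cache[[s]])
    aln_cache[[s]] <- .read_alignments(sam_paths[[s]])
    aln_cache[[s]]
  }
  out <- lapply(seq_len(nrow(calls)), function(i) {
    s <- calls$sample_id[i]
    if (!s %in% names(sam_paths))
      return(data.frame(call_id = calls$call_id[i], n_discordant = NA_integer_,
                        status = "NOT_EVALUABLE", stringsAsFactors = FALSE))
    w <- partner_windows(calls[i, ], models, flank = flank)
    nd <- count_discordant_pairs(get_aln(s), w, min_mapq = min_mapq)
    data.frame(call_id = calls$call_id[i], n_discordant = nd,
               status = validate_call(nd, TRUE, min_pairs),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(call_id = character(0), n_discordant = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
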