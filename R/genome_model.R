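#' Gene model: one transcript's exon/CDS structure
#'
#' Internal coordinates are 0-based half-open genomic intervals; exons are
#' stored in transcript (5' to 3') order, so they are genomically descending
#' for minus-strand genes. `cds_start`/`cds_end` are the 0-based half-open
#' genomic bounds of the coding region (including the stop codon).
#'
#' @param gene_id Stable gene identifier.
#' @param symbol Gene symbol used throughout the pipeline.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with two columns (start, end), 0-based
#'   half-open, rows in transcript order.
#' @param cds_start,cds_end Genomic CDS bounds (0-based half-open); `NA` for
#'   non-coding models.
#' @param transcript_id Transcript identifier of the selected isoform.
#' @param is_coding Whether the model has a coding region.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol, chromosome, strand, exons,
                       cds_start = NA_integer_, cds_end = NA_integer_,
                       transcript_id = gene_id,
                       is_coding = !is.na(cds_start)) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (nrow(exons) < 1 || any(exons[, 2] <= exons[, 1]))
    stop("gene ", symbol, ": exons must be non-empty intervals")
  g <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] < g[-nrow(g), 2]))
    stop("gene ", symbol, ": exons overlap")
  tx_order_ok <- if (strand == "+") !is.unsorted(exons[, 1]) else
    !is.unsorted(rev(exons[, 1]))
  if (!tx_order_ok)
    stop("gene ", symbol, ": exons not in transcript (5'->3') order")
  m <- structure(list(
    gene_id = gene_id, symbol = symbol, chromosome = chromosome,
    strand = strand, exons = exons,
    cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
    transcript_id = transcript_id, is_coding = isTRUE(is_coding)
  ), class = "gene_model")
  if (m$is_coding) {
    if (is.na(m$cds_start) || is.na(m$cds_end) || m$cds_end <= m$cds_start)
      stop("gene ", symbol, ": coding model needs cds_start < cds_end")
    if (is.na(.genomic_to_tx(m, m$cds_start)) ||
        is.na(.genomic_to_tx(m, m$cds_end - 1)))
      stop("gene ", symbol, ": CDS bounds fall outside the exon union")
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s, %d exon(s), %s\n",
              x$symbol, x$gene_id, x$chromosome,
              paste0(min(x$exons[, 1]) + 1, "-", max(x$exons[, 2])),
              x$strand, nrow(x$exons),
              if (x$is_coding) "coding" else "non-coding"))
  invisible(x)
}

.exon_lengths <- function(model) model$exons[, 2] - model$exons[, 1]
.tx_length <- function(model) sum(.exon_lengths(model))
.gene_span <- function(model) c(min(model$exons[, 1]), max(model$exons[, 2]))

# 0-based genomic position -> 0-based transcript offset (NA when intronic).
.genomic_to_tx <- function(model, gpos0) {
  off <- 0
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1]; e <- model$exons[i, 2]
    if (gpos0 >= s && gpos0 < e) {
      within <- if (model$strand == "+") gpos0 - s else (e - 1) - gpos0
      return(off + within)
    }
    off <- off + (e - s)
  }
  NA_real_
}

# 0-based transcript offset -> 0-based genomic position.
.tx_to_genomic <- function(model, tpos0) {
  if (tpos0 < 0 || tpos0 >= .tx_length(model))
    stop("transcript position out of range for gene ", model$symbol)
  off <- 0
  for (i in seq_len(nrow(model$exons))) {
    len <- model$exons[i, 2] - model$exons[i, 1]
    if (tpos0 < off + len) {
      within <- tpos0 - off
      return(if (model$strand == "+") model$exons[i, 1] + within
             else (model$exons[i, 2] - 1) - within)
    }
    off <- off + len
  }
  stop("unreachable")
}

# CDS bounds in transcript coordinates, 0-based half-open.
.cds_tx_bounds <- function(model) {
  stopifnot(model$is_coding)
  first <- if (model$strand == "+") model$cds_start else model$cds_end - 1
  last <- if (model$strand == "+") model$cds_end - 1 else model$cds_start
  c(.genomic_to_tx(model, first), .genomic_to_tx(model, last) + 1)
}

.cds_length <- function(model) {
  b <- .cds_tx_bounds(model)
  b[2] - b[1]
}

.cds_sequence <- function(model, transcript_sequence) {
  b <- .cds_tx_bounds(model)
  substr(transcript_sequence, b[1] + 1, b[2])
}

.new_locus <- function(region, cds_offset = NA_integer_, aa_pos = NA_integer_,
                       codon_phase = NA_integer_) {
  structure(list(region = region, cds_offset = cds_offset, aa_pos = aa_pos,
                 codon_phase = codon_phase), class = "transcript_locus")
}

#' @export
print.transcript_locus <- function(x, ...) {
  cat(sprintf("<transcript_locus> region=%s cds_offset=%s aa_pos=%s phase=%s\n",
              x$region, x$cds_offset, x$aa_pos, x$codon_phase))
  invisible(x)
}

#' Locate a genomic breakpoint on a gene model
#'
#' Maps a 1-based genomic position to its transcript region (5' UTR, CDS,
#' 3' UTR, intron, or non-coding) and, for CDS positions, to a coding offset
#' and protein residue. Fusion callers report the 5'-partner breakpoint as the
#' last transcribed base retained in the chimera and the 3'-partner breakpoint
#' as the first base retained, so the coding-base count relative to the fusion
#' junction differs by one base between the two sides:
#'
#' * `side = "3prime"` (default): `cds_offset` counts coding bases strictly 5'
#'   of the breakpoint base, i.e. the coding bases *discarded* from a 3'
#'   partner.
#' * `side = "5prime"`: `cds_offset` additionally counts the breakpoint base
#'   itself, i.e. the coding bases *retained* from a 5' partner.
#'
#' In both modes `aa_pos` is the 1-based protein residue containing the
#' breakpoint base and `codon_phase` is `cds_offset %% 3`.
#'
#' @param model A [gene_model()].
#' @param genomic_pos 1-based genomic position; must fall within the gene span.
#' @param side Which fusion partner convention to use (see above).
#' @return An object of class `transcript_locus`.
#' @export
locate_breakpoint <- function(model, genomic_pos, side = c("3prime", "5prime")) {
  side <- match.arg(side)
  stopifnot(inherits(model, "gene_model"))
  p0 <- as.numeric(genomic_pos) - 1
  span <- .gene_span(model)
  if (is.na(p0) || p0 < span[1] || p0 >= span[2])
    stop(sprintf("position %s is outside the span of gene %s (%s:%d-%d)",
                 format(genomic_pos), model$symbol, model$chromosome,
                 span[1] + 1, span[2]))
  if (!model$is_coding) return(.new_locus("NONCODING"))
  t <- .genomic_to_tx(model, p0)
  if (is.na(t)) return(.new_locus("INTRON"))
  cb <- .cds_tx_bounds(model)
  if (t < cb[1]) return(.new_locus("FIVE_UTR"))
  if (t >= cb[2]) return(.new_locus("THREE_UTR"))
  strict <- t - cb[1]
  off <- if (side == "5prime") strict + 1 else strict
  .new_locus("CDS", cds_offset = as.integer(off),
             aa_pos = as.integer(strict %/% 3 + 1),
             codon_phase = as.integer(off %% 3))
}

# Translate a CDS nucleotide string; truncates any trailing partial codon and
# stops at the first stop codon. Errors on ambiguous bases.
.translate_cds <- function(nt) {
  nt <- toupper(nt)
  bad <- gregexpr("[^ACGT]", nt)[[1]]
  if (bad[1] != -1)
    stop("CDS contains ambiguous/invalid bases at position(s): ",
         paste(bad, collapse = ", "))
  n <- (nchar(nt) %/% 3) * 3
  if (n == 0) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n))))
  sub("\\*.*$", "", aa)
}

#' Extract the coding nucleotide sequence of a gene model
#'
#' @param model A coding [gene_model()].
#' @param transcript_sequence The spliced transcript sequence (5' to 3').
#' @return The CDS nucleotide string (including the stop codon).
#' @export
transcript_cds <- function(model, transcript_sequence) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$is_coding) stop("gene ", model$symbol, " is non-coding")
  if (nchar(transcript_sequence) != .tx_length(model))
    stop("sequence length does not match exon-union length for gene ",
         model$symbol)
  .cds_sequence(model, transcript_sequence)
}

#' Translate a gene model's coding sequence
#'
#' @param model A coding [gene_model()].
#' @param transcript_sequence The spliced transcript sequence (5' to 3'),
#'   whose length must equal the exon-union length.
#' @return The amino-acid string of the CDS, truncated at the first stop.
#' @export
transcript_protein <- function(model, transcript_sequence) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$is_coding) stop("gene ", model$symbol, " is non-coding")
  if (nchar(transcript_sequence) != .tx_length(model))
    stop(sprintf("sequence length (%d) does not match exon-union length (%d) for gene %s",
                 nchar(transcript_sequence), .tx_length(model), model$symbol))
  .translate_cds(.cds_sequence(model, transcript_sequence))
}

#' Read gene models from a GTF file
#'
#' Parses a GTF (1-based closed coordinates) and returns one [gene_model()]
#' per gene, keeping a single canonical transcript: the one with the longest
#' CDS, ties broken by smallest `transcript_id`; for genes without any coding
#' transcript, the longest exon union (same tie-break).
#'
#' @param path Path to a GTF file.
#' @param source_dialect Annotation source flavor; attribute keys
#'   `gene_id`, `transcript_id`, `gene_name` are expected in all dialects.
#' @return Named list (by gene symbol) of `gene_model` objects.
#' @export
read_gtf <- function(path, source_dialect = c("generic", "ensembl", "refseq")) {
  source_dialect <- match.arg(source_dialect)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1]
    stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, found %d",
                 body[i], nf[i]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(df)))
    stop("GTF is missing required attributes gene_id/transcript_id")
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]

  genes <- unique(df$gene_id[!is.na(df$gene_id)])
  models <- list()
  for (g in genes) {
    ex_g <- ex[ex$gene_id == g, , drop = FALSE]
    if (nrow(ex_g) == 0) {
      warning("gene ", g, " has no exons; skipped")
      next
    }
    txs <- unique(ex_g$transcript_id)
    cds_len <- vapply(txs, function(tx) {
      rows <- cds[cds$transcript_id == tx, , drop = FALSE]
      if (nrow(rows) == 0) 0 else sum(rows$end - rows$start + 1)
    }, numeric(1))
    exon_len <- vapply(txs, function(tx) {
      rows <- ex_g[ex_g$transcript_id == tx, , drop = FALSE]
      sum(rows$end - rows$start + 1)
    }, numeric(1))
    score <- if (any(cds_len > 0)) cds_len else exon_len
    best <- txs[score == max(score)]
    tx <- sort(best)[1]

    rows <- ex_g[ex_g$transcript_id == tx, , drop = FALSE]
    strand <- rows$strand[1]
    exons0 <- cbind(rows$start - 1, rows$end)
    exons0 <- exons0[order(exons0[, 1]), , drop = FALSE]
    if (strand == "-") exons0 <- exons0[rev(seq_len(nrow(exons0))), , drop = FALSE]
    crows <- cds[cds$transcript_id == tx, , drop = FALSE]
    coding <- nrow(crows) > 0
    symbol <- if ("gene_name" %in% names(rows) && !is.na(rows$gene_name[1]))
      rows$gene_name[1] else g
    models[[symbol]] <- gene_model(
      gene_id = g, symbol = symbol, chromosome = rows$seqnames[1],
      strand = strand, exons = exons0,
      cds_start = if (coding) min(crows$start) - 1 else NA,
      cds_end = if (coding) max(crows$end) else NA,
      transcript_id = tx, is_coding = coding)
  }
  models[order(names(models))]
}

#' Write gene models to a GTF file
#'
#' Emits exon and CDS features with `gene_id`, `transcript_id`, `gene_name`,
#' and `gene_biotype` attributes; output is byte-deterministic for a given
#' model list.
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  out <- character(0)
  for (m in models[order(names(models))]) {
    ex <- m$exons[order(m$exons[, 1]), , drop = FALSE]
    biotype <- if (m$is_coding) "protein_coding" else "lincRNA"
    attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
                    m$gene_id, m$transcript_id, m$symbol, biotype)
    for (i in seq_len(nrow(ex))) {
      out <- c(out, paste(m$chromosome, "fusionscape", "exon",
                          ex[i, 1] + 1, ex[i, 2], ".", m$strand, ".", attr,
                          sep = "\t"))
      if (m$is_coding) {
        s <- max(ex[i, 1], m$cds_start); e <- min(ex[i, 2], m$cds_end)
        if (s < e)
          out <- c(out, paste(m$chromosome, "fusionscape", "CDS",
                              s + 1, e, ".", m$strand, ".", attr, sep = "\t"))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
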