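#' @name caller_dialects
#' @title Supported fusion-caller table dialects
#' @description The pipeline reads three tab-separated dialects modelled on
#'   common fusion callers. `STARFUSION_LIKE` is the primary caller: its
#'   coordinates and read counts win when callers are merged.
#' @export
caller_dialects <- c("STARFUSION_LIKE", "ERICSCRIPT_LIKE", "BREAKFAST_LIKE")

.caller_priority <- c(STARFUSION_LIKE = 1L, ERICSCRIPT_LIKE = 2L,
                      BREAKFAST_LIKE = 3L)

.dialect_columns <- list(
  STARFUSION_LIKE = c("sample_id", "fusion_name", "junction_read_count",
                      "spanning_frag_count", "left_breakpoint",
                      "right_breakpoint", "ffpm", "total_frags"),
  ERICSCRIPT_LIKE = c("sample_id", "gene_5prime", "gene_3prime", "chr_5prime",
                      "breakpoint_5prime", "strand_5prime", "chr_3prime",
                      "breakpoint_3prime", "strand_3prime", "crossing_reads",
                      "spanning_reads", "total_frags"),
  BREAKFAST_LIKE = c("sample_id", "chrom_5p", "pos_5p", "strand_5p",
                     "gene_5p", "chrom_3p", "pos_3p", "strand_3p", "gene_3p",
                     "num_reads", "total_frags"))

.empty_calls <- function() {
  data.frame(sample_id = character(0), gene5 = character(0),
             gene3 = character(0), chrom5 = character(0), pos5 = numeric(0),
             strand5 = character(0), chrom3 = character(0), pos3 = numeric(0),
             strand3 = character(0), junction_reads = numeric(0),
             spanning_frags = numeric(0), total_frags = numeric(0),
             ffpm = numeric(0), callers = character(0),
             stringsAsFactors = FALSE)
}

# Parse "chr:pos:strand" breakpoint strings; errors carry the file row number.
.parse_bp <- function(s, what, lines) {
  parts <- strsplit(s, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) == 0) {
    pos <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    strand <- vapply(parts, `[`, "", 3)
    bad <- which(is.na(pos) | !strand %in% c("+", "-"))
  }
  if (length(bad))
    stop(sprintf("cannot parse %s breakpoint '%s' at line %d",
                 what, s[bad[1]], lines[bad[1]]))
  list(chrom = vapply(parts, `[`, "", 1),
       pos = as.numeric(vapply(parts, `[`, "", 2)),
       strand = vapply(parts, `[`, "", 3))
}

#' Read a fusion caller's output table
#'
#' Parses one of the three supported tab-separated dialects into the canonical
#' fusion-call data frame (one row per reported event, `callers` set to the
#' dialect read).
#'
#' @param path Path to the caller TSV.
#' @param dialect One of [caller_dialects].
#' @return Canonical fusion-call data frame with columns `sample_id`,
#'   `gene5`, `gene3`, `chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`,
#'   `strand3`, `junction_reads`, `spanning_frags`, `total_frags`, `ffpm`
#'   (`NA` when the dialect does not report it), `callers`.
#' @export
read_caller_tsv <- function(path, dialect = caller_dialects) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("caller file not found: ", path)
  df <- read_tsv0(path)
  want <- .dialect_columns[[dialect]]
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("dialect error: %s file '%s' is missing column(s): %s",
                 dialect, path, paste(missing, collapse = ", ")))
  if (nrow(df) == 0) return(.empty_calls())
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  out <- switch(dialect,
    STARFUSION_LIKE = {
      gn <- strsplit(df$fusion_name, "--", fixed = TRUE)
      if (any(lengths(gn) != 2))
        stop(sprintf("cannot parse fusion_name '%s' at line %d",
                     df$fusion_name[which(lengths(gn) != 2)[1]],
                     lines[which(lengths(gn) != 2)[1]]))
      l <- .parse_bp(df$left_breakpoint, "left", lines)
      r <- .parse_bp(df$right_breakpoint, "right", lines)
      data.frame(sample_id = df$sample_id,
                 gene5 = vapply(gn, `[`, "", 1),
                 gene3 = vapply(gn, `[`, "", 2),
                 chrom5 = l$chrom, pos5 = l$pos, strand5 = l$strand,
                 chrom3 = r$chrom, pos3 = r$pos, strand3 = r$strand,
                 junction_reads = as.numeric(df$junction_read_count),
                 spanning_frags = as.numeric(df$spanning_frag_count),
                 total_frags = as.numeric(df$total_frags),
                 ffpm = as.numeric(df$ffpm), stringsAsFactors = FALSE)
    },
    ERICSCRIPT_LIKE = data.frame(
      sample_id = df$sample_id, gene5 = df$gene_5prime,
      gene3 = df$gene_3prime, chrom5 = df$chr_5prime,
      pos5 = as.numeric(df$breakpoint_5prime), strand5 = df$strand_5prime,
      chrom3 = df$chr_3prime, pos3 = as.numeric(df$breakpoint_3prime),
      strand3 = df$strand_3prime,
      junction_reads = as.numeric(df$crossing_reads),
      spanning_frags = as.numeric(df$spanning_reads),
      total_frags = as.numeric(df$total_frags), ffpm = NA_real_,
      stringsAsFactors = FALSE),
    BREAKFAST_LIKE = data.frame(
      sample_id = df$sample_id, gene5 = df$gene_5p, gene3 = df$gene_3p,
      chrom5 = df$chrom_5p, pos5 = as.numeric(df$pos_5p),
      strand5 = df$strand_5p, chrom3 = df$chrom_3p,
      pos3 = as.numeric(df$pos_3p), strand3 = df$strand_3p,
      junction_reads = as.numeric(df$num_reads),
      spanning_frags = 0, total_frags = as.numeric(df$total_frags),
      ffpm = NA_real_, stringsAsFactors = FALSE))
  if (any(!nzchar(out$gene5)) || any(!nzchar(out$gene3)))
    stop("empty gene symbol in ", path)
  bad <- which(is.na(out$pos5) | is.na(out$pos3))
  if (length(bad))
    stop(sprintf("unparseable breakpoint at line %d of %s", lines[bad[1]], path))
  out$callers <- dialect
  out
}

#' Fusion fragments per million total fragments
#'
#' `ffpm = supporting_frags / total_frags * 1e6`. This is the read-support
#' normalization used to screen single-caller calls (`FFPM > 0.1`).
#'
#' @param supporting_frags Junction plus spanning fragments supporting the
#'   fusion.
#' @param total_frags Total sequenced fragments in the library; must be > 0.
#' @return FFPM value(s).
#' @export
compute_ffpm <- function(supporting_frags, total_frags) {
  if (any(is.na(total_frags)) || any(total_frags <= 0))
    stop("total_frags must be positive")
  if (any(supporting_frags < 0)) stop("supporting_frags must be >= 0")
  supporting_frags / total_frags * 1e6
}

# Fill missing FFPM from read counts where the library size is known.
.fill_ffpm <- function(calls) {
  need <- is.na(calls$ffpm) & !is.na(calls$total_frags) & calls$total_frags > 0
  calls$ffpm[need] <- compute_ffpm(
    calls$junction_reads[need] + calls$spanning_frags[need],
    calls$total_frags[need])
  calls
}

.n_callers <- function(callers) lengths(strsplit(callers, ";", fixed = TRUE))

#' Merge fusion calls across callers
#'
#' Calls from different callers collapse into one record when they share the
#' sample, the ordered gene pair, chromosomes and strands, and both
#' breakpoints agree within `bp_tolerance` bases. The merged record's
#' coordinates and read counts come from the highest-priority caller present
#' (STARFUSION_LIKE > ERICSCRIPT_LIKE > BREAKFAST_LIKE); its `callers` field
#' is the sorted union. Merging is deterministic, idempotent, and independent
#' of input order; no record is lost or duplicated.
#'
#' @param call_lists A single canonical call data frame or a list of them
#'   (one per caller).
#' @param bp_tolerance Maximum per-breakpoint coordinate difference (bases).
#' @return Merged canonical call data frame with a `call_id` column.
#' @export
merge_callers <- function(call_lists, bp_tolerance = 5) {
  if (is.data.frame(call_lists)) call_lists <- list(call_lists)
  call_lists <- Filter(function(x) !is.null(x) && nrow(x) > 0, call_lists)
  if (length(call_lists) == 0) {
    out <- .empty_calls(); out$call_id <- character(0)
    return(out)
  }
  all <- do.call(rbind, call_lists)
  all <- .fill_ffpm(all)
  # Priority of a record = best caller in its set (handles re-merging).
  prio <- vapply(strsplit(all$callers, ";", fixed = TRUE),
                 function(cs) min(.caller_priority[cs]), numeric(1))
  key <- paste(all$sample_id, all$gene5, all$gene3, all$chrom5, all$chrom3,
               all$strand5, all$strand3, sep = "\r")
  merged <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    sub <- all[idx, , drop = FALSE]
    p <- prio[idx]
    o <- order(p, sub$pos5, sub$pos3, sub$callers)
    sub <- sub[o, , drop = FALSE]
    cluster <- integer(nrow(sub)); reps <- integer(0)
    for (i in seq_len(nrow(sub))) {
      hit <- 0L
      for (ci in seq_along(reps)) {
        j <- reps[ci]
        if (abs(sub$pos5[i] - sub$pos5[j]) <= bp_tolerance &&
            abs(sub$pos3[i] - sub$pos3[j]) <= bp_tolerance) { hit <- ci; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
      cluster[i] <- hit
    }
    do.call(rbind, lapply(seq_along(reps), function(ci) {
      m <- sub[reps[ci], , drop = FALSE]  # representative: best priority
      members <- sub$callers[cluster == ci]
      m$callers <- paste(sort(unique(unlist(
        strsplit(members, ";", fixed = TRUE)))), collapse = ";")
      m
    }))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$gene5, out$gene3, out$pos5, out$pos3), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$call_id <- sprintf("C%05d", seq_len(nrow(out)))
  out
}
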