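#' Pipeline configuration
#'
#' All stage thresholds with their standard defaults, plus the master seed
#' (the only randomness in a pipeline run is the pluggable toy affinity
#' predictor, which is seeded from it).
#'
#' @param ffpm_min Minimum FFPM for single-caller calls.
#' @param recurrence_max Recurrent-artifact sample threshold.
#' @param bp_tolerance Cross-caller breakpoint merge tolerance (bases).
#' @param flank WGS partner-window flank (bases).
#' @param min_mapq Minimum mapping quality of both mates.
#' @param min_pairs Discordant pairs required for validation.
#' @param fdr BH q-value threshold for expression review flagging.
#' @param min_fusions Fusion samples required for review flagging.
#' @param copy_low,copy_high Inclusive copy-number bounds for the
#'   kinase-vs-partner comparison.
#' @param equal_band Percentile band treated as equal expression.
#' @param affinity_max Neoantigen affinity threshold (nM).
#' @param min_split_reads Junction reads required for neoantigen calling.
#' @param seed Master seed.
#' @param default_alleles Alleles used when a sample has no HLA metadata.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ffpm_min = 0.1, recurrence_max = 10L,
                            bp_tolerance = 5, flank = 1e5, min_mapq = 20,
                            min_pairs = 3, fdr = 0.05, min_fusions = 3,
                            copy_low = 1, copy_high = 3, equal_band = 5,
                            affinity_max = 500, min_split_reads = 5,
                            seed = 1L,
                            default_alleles = c("HLA-A*02:01", "HLA-B*07:02")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a complete synthetic study to disk
#'
#' Generates annotation, truth, caller tables, cohort tables, and WGS SAM
#' files under `dir`, in the plain-text formats the pipeline reads.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and `paths` (see
#'   [study_paths()]).
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "wgs"), showWarnings = FALSE)
  ann <- generate_annotation(config)
  truth <- generate_truth(ann, config)
  calls <- simulate_fusion_calls(truth, config)
  cohort <- simulate_cohort(truth, config, ann)
  wgs <- simulate_wgs_support(truth, config, ann)

  p <- study_paths(dir)
  write_gtf(ann$models, p$gtf)
  write_transcript_fasta(ann$tx_seqs, p$transcripts)
  write_tsv0(ann$domains, p$domains)
  write_tsv0(ann$kinases, p$kinases)
  writeLines(ann$exclusion_genes, p$exclusion)
  write_tsv0(ann$paralogs, p$paralogs)
  write_tsv0(ann$normals_panel, p$normals)
  write_tsv0(ann$allowlist, p$allowlist)
  write_tsv0(ann$drugs, p$drugs)
  writeLines(ann$driver_genes, p$driver_genes)
  write_tsv0(calls$STARFUSION_LIKE, p$calls[["STARFUSION_LIKE"]])
  write_tsv0(calls$ERICSCRIPT_LIKE, p$calls[["ERICSCRIPT_LIKE"]])
  write_tsv0(calls$BREAKFAST_LIKE, p$calls[["BREAKFAST_LIKE"]])
  expr <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv0(expr, p$expression)
  cnv <- data.frame(gene = rownames(cohort$copy_number),
                    cohort$copy_number, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv0(cnv, p$copy_number)
  write_tsv0(cohort$maf, p$maf)
  write_tsv0(cohort$metadata, p$metadata)
  for (s in names(wgs$sam))
    writeLines(wgs$sam[[s]], file.path(dir, "wgs", paste0(s, ".sam")))
  jsonlite::write_json(list(records = truth$records, samples = truth$samples),
                       p$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, truth = truth, calls = calls,
                 cohort = cohort, wgs = wgs, paths = p))
}

#' Standard file layout of a study directory
#'
#' @param dir Study directory.
#' @return Named list of input paths as written by [simulate_study()] and
#'   consumed by [run_pipeline()].
#' @export
study_paths <- function(dir) {
  list(gtf = file.path(dir, "annotation.gtf"),
       transcripts = file.path(dir, "transcripts.fa"),
       domains = file.path(dir, "domains.tsv"),
       kinases = file.path(dir, "kinases.tsv"),
       exclusion = file.path(dir, "exclusion_genes.txt"),
       paralogs = file.path(dir, "paralogs.tsv"),
       normals = file.path(dir, "normals_panel.tsv"),
       allowlist = file.path(dir, "allowlist.tsv"),
       drugs = file.path(dir, "drugs.tsv"),
       driver_genes = file.path(dir, "driver_genes.txt"),
       calls = c(STARFUSION_LIKE = file.path(dir, "calls_starfusion.tsv"),
                 ERICSCRIPT_LIKE = file.path(dir, "calls_ericscript.tsv"),
                 BREAKFAST_LIKE = file.path(dir, "calls_breakfast.tsv")),
       expression = file.path(dir, "expression.tsv"),
       copy_number = file.path(dir, "copy_number.tsv"),
       maf = file.path(dir, "mutations.maf"),
       metadata = file.path(dir, "metadata.tsv"),
       wgs_dir = file.path(dir, "wgs"),
       truth = file.path(dir, "truth.json"))
}

.read_matrix_tsv <- function(path) {
  df <- read_tsv0(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full fusion-interpretation pipeline
#'
#' Stages, in order: ingest (parse and merge caller tables), filter (five-rule
#' cascade), validate (WGS discordant pairs), annotate (regions, frame, kinase
#' domains), expression (association tests and kinase-vs-partner comparison),
#' drivers (alteration profiles, driver groups, burden test, exclusivity),
#' druggable (drug matching and smoking association), neoepitope (junction
#' peptides and neoantigen calls). Deterministic for a given seed and inputs.
#'
#' @param paths Named list of input paths (see [study_paths()]); `wgs_dir` may
#'   be `NULL` to skip validation.
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run after the mandatory
#'   ingest/filter.
#' @return Object of class `fusion_pipeline_report`: per-stage tables plus a
#'   `summary` list.
#' @export
run_pipeline <- function(paths, config = pipeline_config(),
                         stages = c("validate", "annotate", "expression",
                                    "drivers", "druggable", "neoepitope")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  need <- function(keys) {
    for (k in keys) {
      pth <- paths[[k]]
      if (is.null(pth) || !all(file.exists(unlist(pth))))
        stop("configuration error: missing input '", k, "'", call. = FALSE)
    }
  }
  report <- list(config = config)

  need(c("gtf", "transcripts", "metadata", "calls", "exclusion", "paralogs",
         "normals", "allowlist", "domains", "kinases"))
  if ("expression" %in% stages) need(c("expression", "copy_number"))
  if ("drivers" %in% stages) need(c("maf", "driver_genes"))
  if ("druggable" %in% stages) need("drugs")

  models <- stage("ingest", read_gtf(paths$gtf))
  tx_seqs <- stage("ingest", read_transcript_fasta(paths$transcripts))
  metadata <- read_tsv0(paths$metadata)
  domains <- read_tsv0(paths$domains)
  kinases <- read_tsv0(paths$kinases)

  merged <- stage("ingest", {
    lists <- lapply(names(paths$calls), function(d)
      read_caller_tsv(paths$calls[[d]], d))
    m <- merge_callers(lists, bp_tolerance = config$bp_tolerance)
    m$cancer_type <- metadata$cancer_type[match(m$sample_id,
                                                metadata$sample_id)]
    m
  })
  report$calls <- merged

  outcomes <- stage("filter", {
    res <- filter_resources(
      exclusion_genes = readLines(paths$exclusion),
      paralog_pairs = read_tsv0(paths$paralogs),
      normals_panel = read_tsv0(paths$normals),
      allowlist = read_tsv0(paths$allowlist),
      ffpm_min = config$ffpm_min, recurrence_max = config$recurrence_max)
    apply_filter_cascade(merged, res)
  })
  report$filter <- outcomes
  kept <- merged[outcomes$kept, , drop = FALSE]

  if ("validate" %in% stages) {
    report$validation <- stage("validate", {
      sams <- if (!is.null(paths$wgs_dir) && dir.exists(paths$wgs_dir)) {
        f <- list.files(paths$wgs_dir, pattern = "\\.sam$", full.names = TRUE)
        stats::setNames(f, sub("\\.sam$", "", basename(f)))
      } else character(0)
      validate_fusions(kept, models, sams, flank = config$flank,
                       min_mapq = config$min_mapq,
                       min_pairs = config$min_pairs)
    })
  }

  annotated <- NULL
  if ("annotate" %in% stages) {
    annotated <- stage("annotate", annotate_fusions(kept, models, domains,
                                                    kinases))
    report$annotated <- annotated
  }

  if ("expression" %in% stages) {
    expr <- .read_matrix_tsv(paths$expression)
    cnv <- .read_matrix_tsv(paths$copy_number)
    report$associations <- stage("expression", {
      fus_genes <- rbind(
        data.frame(sample_id = kept$sample_id, gene = kept$gene5,
                   stringsAsFactors = FALSE),
        data.frame(sample_id = kept$sample_id, gene = kept$gene3,
                   stringsAsFactors = FALSE))
      fusion_expression_association(expr, fus_genes, metadata,
                                    fdr = config$fdr,
                                    min_fusions = config$min_fusions)
    })
    if (!is.null(annotated)) {
      report$kinase_partner <- stage("expression", {
        kin <- annotated[annotated$kinase_role %in%
                           c("FIVE_KINASE", "THREE_KINASE") &
                           annotated$domain_status == "INTACT", ,
                         drop = FALSE]
        kin <- suppressWarnings(
          copy_number_filter(kin, cnv, config$copy_low, config$copy_high))
        kinase_partner_comparison(expr, kin, metadata,
                                  equal_band = config$equal_band)
      })
    }
  }

  if ("drivers" %in% stages) {
    maf <- read_tsv0(paths$maf)
    drivers <- readLines(paths$driver_genes)
    report$profiles <- stage("drivers",
      build_alteration_profiles(maf, kept, drivers,
                                samples = metadata$sample_id))
    report$driver_groups <- classify_driver_group(report$profiles)
    report$burden <- tryCatch(
      burden_comparison(report$profiles, "FUSION_ONLY", "NONE"),
      error = function(e) NULL)
    report$exclusivity <- stage("drivers", {
      fused_drivers <- intersect(drivers, c(kept$gene5, kept$gene3))
      exclusivity_matrix(kept, maf, fused_drivers)
    })
  }

  if ("druggable" %in% stages) {
    drug_table <- read_tsv0(paths$drugs)
    report$druggable <- stage("druggable",
                              annotate_druggable(kept, drug_table,
                                                 samples = metadata$sample_id))
    smk <- metadata$smoking_status[match(report$druggable$sample_druggable$sample_id,
                                         metadata$sample_id)]
    report$smoking <- stage("druggable", {
      dr <- report$druggable$sample_druggable$druggable
      if (length(unique(smk)) == 2 && length(unique(dr)) == 2)
        smoking_association(dr, smk)
      else list(statistic = NA_real_, p_value = NA_real_, table = NULL)
    })
  }

  if ("neoepitope" %in% stages && !is.null(annotated)) {
    report$neoantigens <- stage("neoepitope", {
      predictor <- toy_affinity_model(config$seed)
      rows <- list()
      for (i in seq_len(nrow(annotated))) {
        fus <- annotated[i, ]
        translatable <- fus$frame %in% c("INFRAME", "FRAMESHIFT") ||
          (fus$region5 == "FIVE_UTR" && fus$region3 == "FIVE_UTR")
        if (!isTRUE(translatable)) next
        fp <- tryCatch(translate_fusion(fus, models, tx_seqs),
                       error = function(e) NULL)
        if (is.null(fp)) next
        peps <- enumerate_junction_peptides(fp)
        wt <- c(if (models[[fus$gene5]]$is_coding)
                  transcript_protein(models[[fus$gene5]], tx_seqs[[fus$gene5]]),
                if (models[[fus$gene3]]$is_coding)
                  transcript_protein(models[[fus$gene3]], tx_seqs[[fus$gene3]]))
        hla <- metadata$hla_alleles[match(fus$sample_id, metadata$sample_id)]
        alleles <- if (is.na(hla) || !nzchar(hla)) config$default_alleles
                   else strsplit(hla, ";", fixed = TRUE)[[1]]
        calls <- call_neoantigens(peps, wt, predictor, alleles,
                                  affinity_max = config$affinity_max,
                                  min_split_reads = config$min_split_reads,
                                  junction_reads = fus$junction_reads)
        if (nrow(calls)) {
          calls$call_id <- fus$call_id
          calls$frame <- fus$frame
          rows[[length(rows) + 1]] <- calls
        }
      }
      if (length(rows)) do.call(rbind, rows) else
        data.frame(peptide = character(0), allele = character(0),
                   affinity_nM = numeric(0), is_neoantigen = logical(0),
                   call_id = character(0), frame = character(0),
                   stringsAsFactors = FALSE)
    })
  }

  report$summary <- .pipeline_summary(report, kept)
  class(report) <- "fusion_pipeline_report"
  report
}

.pipeline_summary <- function(report, kept) {
  s <- list(
    n_input_calls = nrow(report$calls),
    n_kept = nrow(kept),
    rejected_by_rule = if (nrow(report$filter))
      table(report$filter$failed_rule[!report$filter$kept]) else table(NULL),
    thresholds = unclass(report$config))
  if (!is.null(report$validation)) {
    st <- report$validation$status
    s$n_evaluable <- sum(st != "NOT_EVALUABLE")
    s$validation_rate <- if (s$n_evaluable > 0) validation_rate(st) else NA
  }
  if (!is.null(report$annotated)) {
    a <- report$annotated
    s$category_table <- table(paste(a$region5, a$region3, sep = "/"))
    s$frame_table <- table(a$frame)
    s$kinase_table <- table(role = a$kinase_role, domain = a$domain_status)
  }
  if (!is.null(report$driver_groups))
    s$driver_group_sizes <- table(report$driver_groups)
  if (!is.null(report$druggable))
    s$druggable_fraction <- mean(report$druggable$sample_druggable$druggable)
  if (!is.null(report$neoantigens) && nrow(report$neoantigens)) {
    neo <- report$neoantigens
    per_fus <- tapply(neo$is_neoantigen, neo$call_id, sum)
    frame_of <- tapply(neo$frame, neo$call_id, `[`, 1)
    s$mean_neoantigens_by_frame <- tapply(as.numeric(per_fus),
                                          unlist(frame_of), mean)
  }
  s
}

#' @export
print.fusion_pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Fusion pipeline report\n")
  cat(sprintf("  calls: %d merged, %d kept after filtering\n",
              s$n_input_calls, s$n_kept))
  if (length(s$rejected_by_rule)) {
    cat("  rejected by rule:\n")
    for (r in names(s$rejected_by_rule))
      cat(sprintf("    %-22s %d\n", r, s$rejected_by_rule[[r]]))
  }
  if (!is.null(s$validation_rate))
    cat(sprintf("  WGS validation: %.1f%% of %d evaluable\n",
                100 * s$validation_rate, s$n_evaluable))
  if (!is.null(s$frame_table)) {
    cat("  frames: ",
        paste(names(s$frame_table), s$frame_table, sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(s$driver_group_sizes)) {
    cat("  driver groups: ",
        paste(names(s$driver_group_sizes), s$driver_group_sizes, sep = "=",
              collapse = ", "), "\n")
  }
  if (!is.null(s$druggable_fraction))
    cat(sprintf("  druggable samples: %.1f%%\n", 100 * s$druggable_fraction))
  invisible(x)
}
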