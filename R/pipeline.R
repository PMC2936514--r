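#' Pipeline configuration
#'
#' Assembles and validates the configuration of [runPipeline()]. Input paths
#' may be omitted (`NULL`) for stages that should be skipped (benchmark
#' without label tables, regulation screen without relations). Defaults
#' mirror the standard analysis: batch filter > 25 treatments, signature
#' half-size 250, presence thresholds 1/2 (ranking) and 1/10 (target
#' screen), relation confidence > 0.7, Tanimoto > 0.8, ATC level 4, partial
#' AUC at FPR < 0.1, FDR 0.05.
#'
#' @param expr,meta,calls paths to the expression, metadata and
#'   detection-call TSVs.
#' @param relations,probe_map,tanimoto,atc optional paths for the screen and
#'   benchmark stages.
#' @param min_batch_size,center,signature_n,weighting,presence_rank,presence_regulation,min_confidence,tanimoto_threshold,atc_level,fpr_cutoff,fdr_alpha,anova
#'   stage parameters (see the stage functions).
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(expr, meta, calls, relations = NULL,
                           probe_map = NULL, tanimoto = NULL, atc = NULL,
                           min_batch_size = 25L,
                           center = c("population", "control"),
                           signature_n = 250L,
                           weighting = c("classic", "weighted"),
                           presence_rank = 0.5, presence_regulation = 0.1,
                           min_confidence = 0.7, tanimoto_threshold = 0.8,
                           atc_level = 4L, fpr_cutoff = 0.1,
                           fdr_alpha = 0.05,
                           anova = c("two.way", "one.way"), seed = 1L) {
  cfg <- list(expr = expr, meta = meta, calls = calls,
              relations = relations, probe_map = probe_map,
              tanimoto = tanimoto, atc = atc,
              min_batch_size = as.integer(min_batch_size),
              center = match.arg(center),
              signature_n = as.integer(signature_n),
              weighting = match.arg(weighting),
              presence_rank = presence_rank,
              presence_regulation = presence_regulation,
              min_confidence = min_confidence,
              tanimoto_threshold = tanimoto_threshold,
              atc_level = as.integer(atc_level),
              fpr_cutoff = fpr_cutoff, fdr_alpha = fdr_alpha,
              anova = match.arg(anova), seed = as.integer(seed))
  for (nm in c("presence_rank", "presence_regulation"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must be in (0, 1]")
  if (cfg$fpr_cutoff <= 0 || cfg$fpr_cutoff > 1)
    stop("'fpr_cutoff' must be in (0, 1]")
  for (nm in c("expr", "meta", "calls"))
    if (!file.exists(cfg[[nm]]))
      stop("input file not found: ", cfg[[nm]])
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()]; relative input paths are resolved against the YAML
#'   file's directory.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("expr", "meta", "calls", "relations", "probe_map",
               "tanimoto", "atc"))
    if (!is.null(y[[nm]]) && !file.exists(y[[nm]]))
      y[[nm]] <- file.path(base, y[[nm]])
  do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load & validate inputs, batch-size filter,
#' highest-concentration selection, per-batch centering (population mean or
#' vehicle controls), replicate merging, presence sets, per-cell-line DIPS
#' matrices, combined scores, label benchmarks (if label tables are
#' configured) and the drug-target regulation screen (if a relation table is
#' configured). All artifacts are written as TSV into `out_dir`, plus a
#' machine-readable `manifest.json` recording configuration, package
#' version, seed and per-stage row counts. Re-running with an identical
#' configuration and inputs reproduces byte-identical outputs.
#'
#' @param config a `PipelineConfig` (or path to a YAML file).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results (`ps`,
#'   `profiles`, `dips`, `combined`, `benchmarks`, `regulation`, `manifest`).
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  logStage <- function(stage, ...) {
    message("[", stage, "] ", ...)
  }

  ps <- loadPerturbationSet(cfg$expr, cfg$meta, cfg$calls)
  counts$instances_loaded <- ncol(ps)
  logStage("load", ncol(ps), " instances, ", nrow(ps), " probes")

  keep_controls <- cfg$center == "control"
  ps <- filterInstances(ps, min_batch_size = cfg$min_batch_size,
                        drop_controls = !keep_controls)
  ps <- selectHighestConcentration(ps)
  counts$instances_filtered <- sum(!isControl(ps))
  logStage("filter", counts$instances_filtered, " treatment instances kept")
  .writeTSV(as.data.frame(colData(ps)),
            file.path(out_dir, "instances_filtered.tsv"))

  centered <- if (cfg$center == "population") meanCenterBatch(ps)
              else controlCenterBatch(ps)
  logStage("center", "per-batch ", cfg$center, " centering done")

  pres_rank <- presenceByCellLine(centered, threshold = cfg$presence_rank)
  pres_reg <- presenceByCellLine(centered,
                                 threshold = cfg$presence_regulation)
  counts$present_probes <- vapply(pres_rank, function(p)
    length(p@probes), integer(1))

  profiles <- mergeReplicates(centered)
  counts$profiles <- ncol(profiles)
  logStage("merge", ncol(profiles), " drug profiles")
  a <- amplitudeValues(profiles)
  .writeTSV(data.frame(probe_id = rownames(a), a, check.names = FALSE),
            file.path(out_dir, "profiles.tsv"))

  cls <- sort(cellLines(profiles))
  dips <- list()
  sigs <- list()
  for (cl in cls) {
    sub <- profiles[, as.character(colData(profiles)$cell_line) == cl]
    dm <- dipsMatrix(sub, pres_rank[[cl]], n = cfg$signature_n,
                     weighting = cfg$weighting)
    dips[[cl]] <- dm
    ranked <- rankProfiles(sub, pres_rank[[cl]])
    sigs[[cl]] <- lapply(ranked, extractSignature, n = cfg$signature_n)
    .writeTSV(dipsLong(dm), file.path(out_dir,
                                      paste0("dips_", cl, ".tsv")))
    logStage("dips", cl, ": ", nrow(dm@scores), " drugs scored")
  }
  writeSignatures(unlist(sigs, recursive = FALSE),
                  file.path(out_dir, "signatures.grp"))
  combined <- combineCellLines(dips)
  .writeTSV(dipsLong(combined), file.path(out_dir, "dips_combined.tsv"))
  counts$dips_scores <- sum(vapply(dips, function(d)
    length(dipsLong(d)$score), integer(1))) + length(dipsLong(combined)$score)

  benchmarks <- list()
  labelSets <- list()
  if (!is.null(cfg$tanimoto))
    labelSets$tanimoto <- labelsFromTanimoto(
      utils::read.delim(cfg$tanimoto, stringsAsFactors = FALSE),
      threshold = cfg$tanimoto_threshold)
  if (!is.null(cfg$atc))
    labelSets$atc <- labelsFromAtc(
      utils::read.delim(cfg$atc, stringsAsFactors = FALSE),
      level = cfg$atc_level)
  if (length(labelSets)) {
    benchmarks <- benchmarkScores(combined, labelSets,
                                  fpr_cutoff = cfg$fpr_cutoff)
    rep <- do.call(rbind, lapply(names(benchmarks), function(nm) {
      b <- benchmarks[[nm]]
      data.frame(label_source = nm, n_pos = b$n_pos, n_neg = b$n_neg,
                 auc = b$auc, pauc = b$pauc, fpr_cutoff = b$cutoff,
                 stringsAsFactors = FALSE)
    }))
    .writeTSV(rep, file.path(out_dir, "roc_report.tsv"))
    logStage("benchmark", paste(sprintf("%s AUC=%.3f", rep$label_source,
                                        rep$auc), collapse = ", "))
  }

  regulation <- NULL
  if (!is.null(cfg$relations) && !is.null(cfg$probe_map)) {
    rel <- readRelationTable(cfg$relations)
    pmap <- utils::read.delim(cfg$probe_map, stringsAsFactors = FALSE)
    regulation <- screenTargetRegulation(
      profiles, rel, pres_reg, pmap, min_confidence = cfg$min_confidence,
      anova = cfg$anova, alpha = cfg$fdr_alpha)
    .writeTSV(regulation$summary, file.path(out_dir, "regulation.tsv"))
    .writeTSV(regulation$by_cell_line,
              file.path(out_dir, "regulation_by_cell_line.tsv"))
    .writeTSV(multiTargetReport(regulation$relations, regulation$summary),
              file.path(out_dir, "multi_target.tsv"))
    counts$hypotheses_tested <- sum(!is.na(regulation$summary$anova_p))
    counts$significant_targets <- sum(regulation$summary$significant)
    logStage("regulate", counts$significant_targets, " of ",
             counts$hypotheses_tested, " hypotheses significant at q < ",
             cfg$fdr_alpha)
  }

  manifest <- list(
    package = "dipscore",
    version = as.character(utils::packageVersion("dipscore")),
    seed = cfg$seed,
    config = unclass(cfg),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(ps = ps, centered = centered, profiles = profiles,
                 presence_rank = pres_rank, presence_regulation = pres_reg,
                 dips = dips, combined = combined, benchmarks = benchmarks,
                 regulation = regulation, manifest = manifest))
}
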