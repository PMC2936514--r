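# In-code fixtures shared across test files.

suppressPackageStartupMessages(library(SummarizedExperiment))

# Minimal hand-built PerturbationSet: `design` is a data.frame with columns
# drug, batch (and optionally cell_line, conc, unit, control); values is a
# probe x instance matrix (defaults to zeros).
makeToyPS <- function(design, values = NULL, n_probes = 4L, calls = NULL) {
  n <- nrow(design)
  meta <- data.frame(
    instance_id = design$instance_id %||% sprintf("i%02d", seq_len(n)),
    drug_id = design$drug %||% sprintf("d%02d", seq_len(n)),
    cell_line = design$cell_line %||% "MCF7",
    batch_id = design$batch %||% "b1",
    platform = design$platform %||% "HT_HG-U133A",
    concentration_value = design$conc %||% 10,
    concentration_unit = design$unit %||% "uM",
    is_control = design$control %||% FALSE,
    stringsAsFactors = FALSE)
  meta$drug_id[meta$is_control] <- NA_character_
  if (is.null(values))
    values <- matrix(0, n_probes, n)
  rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  colnames(values) <- meta$instance_id
  PerturbationSet(values, meta, calls = calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# AmplitudeProfiles straight from a probe x drug matrix (one cell line).
makeProfiles <- function(mat, cell_line = "MCF7", centering = "population",
                         drug_ids = colnames(mat)) {
  pdata <- data.frame(
    profile_id = paste(drug_ids, cell_line, sep = "."),
    drug_id = drug_ids, cell_line = cell_line, platform = "HT_HG-U133A",
    n_instances = 1L, stringsAsFactors = FALSE)
  rownames(pdata) <- pdata$profile_id
  colnames(mat) <- pdata$profile_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(amplitude = mat),
    colData = S4Vectors::DataFrame(pdata))
  out <- new("AmplitudeProfiles", se)
  S4Vectors::metadata(out)$centering <- centering
  out
}

makePresence <- function(probes, cell_line = "MCF7", threshold = 0.5,
                         n_instances = 10L) {
  new("PresenceSet", cell_line = cell_line, threshold = threshold,
      probes = probes, n_instances = as.integer(n_instances))
}

# Small default simulation used by several files (fast, deterministic).
smallSimConfig <- function(...) {
  args <- list(n_probes = 300L, n_drugs = 20L, n_cell_lines = 1L,
               batches_per_cell_line = 2L, treatments_per_batch = 12L,
               replicate_rate = 0.25, signature_size = 10L,
               signature_amplitude = 1.5, batch_sd = 0.8, noise_sd = 0.5,
               n_similar_groups = 4L, similar_group_size = 2L,
               n_relations = 6L, regulation_effect = 1.5,
               fraction_regulated = 0.5, present_rate = 0.6,
               controls_per_batch = 0L, two_conc_fraction = 0.3, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# random ranked profile over N probes, all Present, distinct values
randomRankedProfile <- function(N) {
  v <- stats::setNames(stats::rnorm(N), sprintf("p%04d", seq_len(N)))
  rankProfile(v, present = names(v))
}
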