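#' Configuration for the synthetic compendium generator
#'
#' Bundles the generative parameters of [simulateCompendium()]: a multi-batch,
#' multi-cell-line drug-treatment design with additive per-batch effects,
#' sparse drug-specific expression signatures (shared within
#' "structurally similar" drug groups), replicates, two concentration levels,
#' abundance-linked detection calls, and injected drug-target feedback
#' effects tied to a drug-target relation table.
#'
#' Expression values are generated on the log2 scale as
#' `x[p,t] = mu_p + b[batch(t),p] + s[drug(t),p]*c(t) + delta*sgn(action) + eps`
#' with `mu_p ~ N(7, 1)` (per probe, typical microarray range),
#' `b ~ N(0, batch_sd^2)` per batch x probe, `s` nonzero (value
#' `+-signature_amplitude`) on exactly `signature_size` probes per drug,
#' `c(t) = 1` at the highest concentration and `1/1.5` at the lower one, and
#' `eps ~ N(0, noise_sd^2)`. The feedback term `delta*sgn(action)` (with
#' `sgn(inhibition) = +1`, `sgn(activation) = -1`) is added to the target
#' gene's probes for instances of drugs whose relation is flagged as truly
#' regulated.
#'
#' @param n_probes,n_drugs,n_cell_lines,batches_per_cell_line,treatments_per_batch
#'   design counts; `n_cell_lines` must be 1-3 (HL60, MCF7, PC3);
#'   `treatments_per_batch` must be at least 2 (population mean-centering is
#'   undefined on singleton batches).
#' @param replicate_rate fraction of treatment slots per cell line occupied by
#'   replicate instances of already-included drugs.
#' @param signature_size number of signal probes per drug (must be
#'   `< n_probes`).
#' @param signature_amplitude absolute per-probe signature effect (log2
#'   units) at the highest concentration; the lower concentration carries
#'   `signature_amplitude / 1.5`.
#' @param batch_sd,noise_sd standard deviations (log2 units) of the additive
#'   batch effect and the i.i.d. measurement noise.
#' @param n_similar_groups,similar_group_size number and size of drug groups
#'   sharing an identical signature (the "structurally similar" drugs);
#'   grouped drugs also share an ATC level-4 prefix and get Tanimoto 0.9.
#' @param n_relations number of true drug-target relations;
#'   `drugs_per_target` of them point at each target gene.
#' @param drugs_per_target drugs annotated to each target gene.
#' @param regulation_effect feedback effect delta (log2 units) added to
#'   target probes of regulated relations, sign set by the action.
#' @param fraction_regulated fraction of target genes with a true feedback
#'   effect.
#' @param present_rate baseline probability that a probe is called Present;
#'   presence is logistic in `mu_p` around the matching abundance quantile.
#' @param controls_per_batch vehicle-control instances per batch (signature
#'   and feedback off); 0 disables controls.
#' @param two_conc_fraction fraction of drugs tested at two concentrations.
#' @param decoy_relation_rate decoy relations (low confidence or text-mining
#'   channel, never regulated) appended per true relation, to exercise the
#'   relation filters.
#' @param seed integer RNG seed; the same config yields bit-identical output.
#' @return a classed list (`SimulationConfig`) of validated parameters.
#' @export
simulationConfig <- function(n_probes = 2000L, n_drugs = 100L,
                             n_cell_lines = 3L, batches_per_cell_line = 4L,
                             treatments_per_batch = 30L,
                             replicate_rate = 0.2, signature_size = 30L,
                             signature_amplitude = 1.5, batch_sd = 0.8,
                             noise_sd = 0.5, n_similar_groups = 10L,
                             similar_group_size = 2L, n_relations = 30L,
                             drugs_per_target = 1L, regulation_effect = 1.5,
                             fraction_regulated = 0.5, present_rate = 0.5,
                             controls_per_batch = 0L,
                             two_conc_fraction = 0.5,
                             decoy_relation_rate = 0.3, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_drugs = as.integer(n_drugs),
              n_cell_lines = as.integer(n_cell_lines),
              batches_per_cell_line = as.integer(batches_per_cell_line),
              treatments_per_batch = as.integer(treatments_per_batch),
              replicate_rate = replicate_rate,
              signature_size = as.integer(signature_size),
              signature_amplitude = signature_amplitude,
              batch_sd = batch_sd, noise_sd = noise_sd,
              n_similar_groups = as.integer(n_similar_groups),
              similar_group_size = as.integer(similar_group_size),
              n_relations = as.integer(n_relations),
              drugs_per_target = as.integer(drugs_per_target),
              regulation_effect = regulation_effect,
              fraction_regulated = fraction_regulated,
              present_rate = present_rate,
              controls_per_batch = as.integer(controls_per_batch),
              two_conc_fraction = two_conc_fraction,
              decoy_relation_rate = decoy_relation_rate,
              seed = as.integer(seed))
  counts <- c("n_probes", "n_drugs", "n_cell_lines", "batches_per_cell_line",
              "treatments_per_batch", "signature_size", "drugs_per_target")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("'", nm, "' must be a count >= 1")
  if (cfg$treatments_per_batch < 2L)
    stop("'treatments_per_batch' must be >= 2: population mean-centering is ",
         "undefined on a singleton batch")
  if (cfg$signature_size >= cfg$n_probes)
    stop("'signature_size' must be < 'n_probes'")
  if (cfg$n_cell_lines > 3L)
    stop("'n_cell_lines' must be 1-3")
  for (nm in c("replicate_rate", "fraction_regulated", "two_conc_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must be in [0, 1]")
  if (cfg$present_rate <= 0 || cfg$present_rate >= 1)
    stop("'present_rate' must be in (0, 1)")
  for (nm in c("batch_sd", "noise_sd"))
    if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0")
  if (cfg$n_similar_groups * cfg$similar_group_size > cfg$n_drugs)
    stop("similar groups cannot cover more than 'n_drugs' drugs")
  if (cfg$n_similar_groups > 0L && cfg$similar_group_size < 2L)
    stop("'similar_group_size' must be >= 2 when groups are requested")
  structure(cfg, class = "SimulationConfig")
}

# deterministic 5-character ATC level-4 prefix for signature unit i
.atcPrefix <- function(i) {
  i0 <- i - 1L
  l1 <- LETTERS[i0 %% 26L + 1L]
  rest <- i0 %/% 26L
  dd <- sprintf("%02d", rest %% 100L)
  rest <- rest %/% 100L
  l2 <- LETTERS[rest %% 26L + 1L]
  l3 <- LETTERS[(rest %/% 26L) %% 26L + 1L]
  paste0(l1, dd, l2, l3)
}

#' Generate a synthetic drug-perturbation compendium with ground truth
#'
#' Draws a complete CMap-like dataset from the generative model described in
#' [simulationConfig()]: expression matrix, instance metadata, detection
#' calls, drug-target relation table, pairwise chemical-similarity
#' (Tanimoto-like) table, ATC-like code table, and a ground-truth record of
#' every injected effect, so that each downstream stage can be validated
#' against known truth.
#'
#' @param config a [simulationConfig()] object.
#' @return a list with elements `ps` ([PerturbationSet-class] with assays
#'   `exprs` and `calls`), `relations` (data.frame: `drug_id`, `gene_id`,
#'   `action`, `confidence`, `channel`), `probe_map` (`probe_id`,
#'   `gene_id`), `tanimoto` (`drug_a`, `drug_b`, `tanimoto`), `atc`
#'   (`drug_id`, `atc_code`), `truth` (list: `signature_probes`,
#'   `similar_pairs`, `relations` with `regulated`/`direction`,
#'   `instances`, `group_of`) and the `config`.
#' @examples
#' sim <- simulateCompendium(simulationConfig(n_probes = 200, n_drugs = 12,
#'   n_cell_lines = 1, batches_per_cell_line = 2, treatments_per_batch = 8,
#'   seed = 7))
#' sim$ps
#' @export
simulateCompendium <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simulationConfig, as.list(config))
  cfg <- config
  set.seed(cfg$seed)

  probes <- sprintf("P%05d", seq_len(cfg$n_probes))
  mu <- stats::rnorm(cfg$n_probes, mean = 7, sd = 1)
  # every 20th probe shares its gene with the preceding probe, so some genes
  # map to two probes (exercises multi-probe target averaging)
  gidx <- seq_len(cfg$n_probes)
  gidx <- gidx - as.integer(gidx %% 20L == 0L & gidx > 1L)
  genes <- sprintf("G%05d", gidx)
  probe_map <- data.frame(probe_id = probes, gene_id = genes,
                          stringsAsFactors = FALSE)

  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
  # signature units: similar groups first, then singleton drugs
  group_of <- rep(NA_integer_, cfg$n_drugs)
  if (cfg$n_similar_groups > 0L) {
    gm <- cfg$n_similar_groups * cfg$similar_group_size
    group_of[seq_len(gm)] <- rep(seq_len(cfg$n_similar_groups),
                                 each = cfg$similar_group_size)
  }
  unit_of <- ifelse(is.na(group_of),
                    cfg$n_similar_groups + cumsum(is.na(group_of)),
                    group_of)
  n_units <- max(unit_of)
  sig_idx <- vector("list", n_units)
  sig_val <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    sig_idx[[u]] <- sample.int(cfg$n_probes, cfg$signature_size)
    sig_val[[u]] <- sample(c(-1, 1), cfg$signature_size, replace = TRUE) *
      cfg$signature_amplitude
  }

  # presence model: logistic in abundance around the present_rate quantile
  midpoint <- stats::qnorm(1 - cfg$present_rate, mean = 7, sd = 1)
  p_present <- stats::plogis((mu - midpoint) / 0.5)

  ## ---- drug-target relations and feedback ground truth -------------------
  gene_probes <- split(seq_len(cfg$n_probes), genes)
  candidate_genes <- names(gene_probes)[vapply(gene_probes, function(ix)
    min(mu[ix]) >= midpoint + 0.5, logical(1))]
  n_targets <- ceiling(cfg$n_relations / cfg$drugs_per_target)
  if (length(candidate_genes) < n_targets + 1L)
    stop("too few presence-prone genes to host ", n_targets,
         " targets; increase n_probes or present_rate")
  target_genes <- sample(candidate_genes, n_targets)
  rel <- vector("list", n_targets)
  for (ti in seq_len(n_targets)) {
    tg <- target_genes[ti]
    tg_probes <- gene_probes[[tg]]
    # avoid drugs whose own signature touches the target's probes
    clean <- drugs[vapply(unit_of, function(u)
      !any(sig_idx[[u]] %in% tg_probes), logical(1))]
    nd <- min(cfg$drugs_per_target, length(clean))
    rel[[ti]] <- data.frame(
      drug_id = sample(clean, nd),
      gene_id = tg,
      action = sample(c("inhibition", "activation"), 1L),
      stringsAsFactors = FALSE)
  }
  rel <- do.call(rbind, rel)
  rel <- rel[seq_len(min(nrow(rel), cfg$n_relations)), , drop = FALSE]
  rel$confidence <- round(stats::runif(nrow(rel), 0.75, 0.99), 3)
  rel$channel <- sample(c("experimental", "database"), nrow(rel),
                        replace = TRUE)
  n_reg_targets <- round(cfg$fraction_regulated * n_targets)
  regulated_genes <- if (n_reg_targets > 0L)
    sample(target_genes, n_reg_targets) else character()
  rel$regulated <- rel$gene_id %in% regulated_genes
  rel$effect <- ifelse(rel$regulated,
                       ifelse(rel$action == "inhibition", 1, -1) *
                         cfg$regulation_effect, 0)

  n_decoys <- round(cfg$decoy_relation_rate * nrow(rel))
  if (n_decoys > 0L) {
    decoy_genes <- setdiff(candidate_genes, target_genes)
    dec <- data.frame(
      drug_id = sample(drugs, n_decoys, replace = TRUE),
      gene_id = sample(decoy_genes, min(n_decoys, length(decoy_genes)),
                       replace = n_decoys > length(decoy_genes)),
      action = sample(c("inhibition", "activation"), n_decoys, replace = TRUE),
      stringsAsFactors = FALSE)
    low_conf <- stats::runif(n_decoys) < 0.5
    dec$confidence <- round(ifelse(low_conf, stats::runif(n_decoys, 0.3, 0.7),
                                   stats::runif(n_decoys, 0.75, 0.99)), 3)
    dec$channel <- ifelse(low_conf,
                          sample(c("experimental", "database"), n_decoys,
                                 replace = TRUE), "textmining")
    dec$regulated <- FALSE
    dec$effect <- 0
    rel <- rbind(rel, dec)
  }
  rownames(rel) <- NULL

  ## ---- treatment design ---------------------------------------------------
  cell_lines <- c("HL60", "MCF7", "PC3")[seq_len(cfg$n_cell_lines)]
  platform <- "HT_HG-U133A"
  two_conc <- stats::runif(cfg$n_drugs) < cfg$two_conc_fraction
  names(two_conc) <- drugs
  slots <- cfg$batches_per_cell_line * cfg$treatments_per_batch

  meta_list <- list(); expr_list <- list(); call_list <- list()
  # effect lookup: gene -> probes with injected feedback, per drug
  reg_by_drug <- split(rel[rel$regulated, c("gene_id", "effect")],
                       rel$drug_id[rel$regulated])

  for (cl in cell_lines) {
    n_unique <- min(cfg$n_drugs,
                    max(1L, round(slots * (1 - cfg$replicate_rate))))
    n_unique <- min(n_unique, slots)
    chosen <- sample(drugs, n_unique)
    extra <- if (slots > n_unique)
      sample(chosen, slots - n_unique, replace = TRUE) else character()
    assign_drug <- sample(c(chosen, extra))
    batch_id <- rep(sprintf("%s_b%02d", cl, seq_len(cfg$batches_per_cell_line)),
                    each = cfg$treatments_per_batch)
    inst <- data.frame(
      instance_id = sprintf("%s_i%04d", cl, seq_len(slots)),
      drug_id = assign_drug, cell_line = cl, batch_id = batch_id,
      platform = platform, concentration_value = 10,
      concentration_unit = "uM", is_control = FALSE,
      stringsAsFactors = FALSE)
    # one instance of each two-concentration drug is measured at the lower dose
    for (d in unique(assign_drug)) {
      ix <- which(inst$drug_id == d)
      if (two_conc[d] && length(ix) >= 2L)
        inst$concentration_value[sample(ix, 1L)] <- 1
    }
    if (cfg$controls_per_batch > 0L) {
      ctrl <- do.call(rbind, lapply(unique(batch_id), function(b) data.frame(
        instance_id = sprintf("%s_c%02d", b, seq_len(cfg$controls_per_batch)),
        drug_id = NA_character_, cell_line = cl, batch_id = b,
        platform = platform, concentration_value = NA_real_,
        concentration_unit = NA_character_, is_control = TRUE,
        stringsAsFactors = FALSE)))
      inst <- rbind(inst, ctrl)
    }

    bmat <- matrix(stats::rnorm(cfg$n_probes * cfg$batches_per_cell_line,
                                0, cfg$batch_sd),
                   nrow = cfg$n_probes,
                   dimnames = list(NULL, unique(batch_id)))
    x <- matrix(0, nrow = cfg$n_probes, ncol = nrow(inst),
                dimnames = list(probes, inst$instance_id))
    for (j in seq_len(nrow(inst))) {
      col <- mu + bmat[, inst$batch_id[j]] +
        stats::rnorm(cfg$n_probes, 0, cfg$noise_sd)
      if (!inst$is_control[j]) {
        d <- inst$drug_id[j]
        u <- unit_of[match(d, drugs)]
        scale <- if (!is.na(inst$concentration_value[j]) &&
                     inst$concentration_value[j] < 10) 1 / 1.5 else 1
        col[sig_idx[[u]]] <- col[sig_idx[[u]]] + sig_val[[u]] * scale
        rg <- reg_by_drug[[d]]
        if (!is.null(rg) && nrow(rg)) {
          for (ri in seq_len(nrow(rg)))
            col[gene_probes[[rg$gene_id[ri]]]] <-
              col[gene_probes[[rg$gene_id[ri]]]] + rg$effect[ri]
        }
      }
      x[, j] <- col
    }
    pm <- matrix(stats::runif(length(x)) < p_present, nrow = cfg$n_probes)
    calls <- matrix(ifelse(pm, "P",
                           ifelse(matrix(stats::runif(length(x)), # nolint
                                         nrow = cfg$n_probes) < 0.85,
                                  "A", "M")),
                    nrow = cfg$n_probes, dimnames = dimnames(x))
    meta_list[[cl]] <- inst
    expr_list[[cl]] <- x
    call_list[[cl]] <- calls
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  exprs <- do.call(cbind, expr_list)
  calls <- do.call(cbind, call_list)
  ps <- PerturbationSet(exprs, meta, calls = calls)

  ## ---- external benchmark tables -----------------------------------------
  pr <- t(utils::combn(drugs, 2L))
  ga <- group_of[match(pr[, 1], drugs)]
  gb <- group_of[match(pr[, 2], drugs)]
  same_group <- !is.na(ga) & !is.na(gb) & ga == gb
  tanimoto <- data.frame(drug_a = pr[, 1], drug_b = pr[, 2],
                         tanimoto = ifelse(same_group, 0.9,
                                           stats::runif(nrow(pr), 0, 0.6)),
                         stringsAsFactors = FALSE)
  atc <- data.frame(
    drug_id = drugs,
    atc_code = paste0(vapply(unit_of, .atcPrefix, character(1)),
                      sprintf("%02d", stats::ave(seq_len(cfg$n_drugs),
                                                 unit_of, FUN = seq_along))),
    stringsAsFactors = FALSE)

  truth <- list(
    signature_probes = stats::setNames(
      lapply(unit_of, function(u) probes[sig_idx[[u]]]), drugs),
    similar_pairs = data.frame(drug_a = pr[, 1], drug_b = pr[, 2],
                               similar = same_group, stringsAsFactors = FALSE),
    relations = rel,
    instances = meta,
    group_of = stats::setNames(group_of, drugs),
    mu = stats::setNames(mu, probes))

  list(ps = ps,
       relations = rel[, c("drug_id", "gene_id", "action", "confidence",
                           "channel")],
       probe_map = probe_map, tanimoto = tanimoto, atc = atc,
       truth = truth, config = cfg)
}
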