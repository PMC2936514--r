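#' Fold 'binding' actions into inhibition, with manual overrides
#'
#' Drug-target relation tables annotate actions as activation, inhibition or
#' binding; binding is treated as inhibition for the screen. An optional
#' override table (columns `drug_id`, `gene_id`, `action`) replaces the
#' action of matching relations, supporting manual curation of ambiguous
#' binding annotations.
#'
#' @param relations data.frame with columns `drug_id`, `gene_id`, `action`,
#'   `confidence`, `channel`.
#' @param overrides optional data.frame of manual action corrections.
#' @return the relation table with actions in `{activation, inhibition}`.
#' @export
foldBindingActions <- function(relations, overrides = NULL) {
  relations$action <- ifelse(relations$action == "binding", "inhibition",
                             relations$action)
  if (!is.null(overrides) && nrow(overrides)) {
    key <- paste(relations$drug_id, relations$gene_id, sep = "\r")
    okey <- paste(overrides$drug_id, overrides$gene_id, sep = "\r")
    hit <- match(key, okey)
    relations$action[!is.na(hit)] <- overrides$action[hit[!is.na(hit)]]
  }
  bad <- !(relations$action %in% c("activation", "inhibition"))
  if (any(bad))
    stop("unknown action(s): ", paste(unique(relations$action[bad]),
                                      collapse = ", "))
  relations
}

#' Filter drug-target relations by confidence and evidence channel
#'
#' Retains relations with confidence strictly greater than `min_confidence`
#' (default 0.7) from the allowed evidence channels (default experimental
#' and curated-database annotations), minimizing indirect associations.
#'
#' @param relations relation data.frame (see [foldBindingActions()]).
#' @param min_confidence strict lower bound on `confidence`.
#' @param channels allowed values of the `channel` column.
#' @return the filtered relation table.
#' @export
filterRelations <- function(relations, min_confidence = 0.7,
                            channels = c("experimental", "database")) {
  keep <- relations$confidence > min_confidence &
    relations$channel %in% channels
  out <- relations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# probe ids of a gene that are Present in a cell line
.presentTargetProbes <- function(gene, presence, probe_map) {
  gp <- probe_map$probe_id[probe_map$gene_id == gene]
  intersect(gp, .presenceProbes(presence))
}

#' Keep relations whose target is expressed somewhere
#'
#' A target counts as expressed in a cell line when at least one of its
#' probes is Present there at the 1/10 threshold; relations whose target is
#' expressed in no cell line are dropped. The per-cell-line applicability is
#' recorded in an `expressed_in` column (comma-separated cell lines);
#' downstream tests are run only in those cell lines (elsewhere the target's
#' columns stay blank).
#'
#' @param relations relation data.frame.
#' @param presenceList named list of [PresenceSet-class] (computed at
#'   threshold 0.1), keyed by cell line.
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @return the filtered relation table with an `expressed_in` column.
#' @export
filterExpressedTargets <- function(relations, presenceList, probe_map) {
  cls <- names(presenceList)
  genes <- unique(relations$gene_id)
  expr_in <- vapply(genes, function(g) {
    ok <- vapply(cls, function(cl)
      length(.presentTargetProbes(g, presenceList[[cl]], probe_map)) > 0L,
      logical(1))
    paste(cls[ok], collapse = ",")
  }, character(1))
  relations$expressed_in <- expr_in[match(relations$gene_id, genes)]
  out <- relations[nzchar(relations$expressed_in), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test one drug target for drug-induced differential expression
#'
#' Compares the expression change ("average difference") of a target gene
#' under its annotated drugs against the change of the same gene under all
#' other drug treatments. Per cell line, the target amplitude of each drug
#' is the mean over the target's Present probes, and a Welch two-sample
#' t-test contrasts targeting versus background drugs. Across cell lines, a
#' fixed-effects ANOVA on the pooled per-drug amplitudes assesses the
#' overall targeting-group effect -- by default a two-way additive design
#' with cell line as blocking factor (`amplitude ~ cell_line + group`); with
#' a single usable cell line it reduces to the one-way ANOVA, whose F equals
#' the squared pooled t statistic.
#'
#' @param profiles an [AmplitudeProfiles-class] (all cell lines).
#' @param target_gene gene identifier.
#' @param targeting_drugs drug ids annotated to act on the target.
#' @param presenceList named list of [PresenceSet-class] at the 1/10
#'   expression threshold.
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param action action label carried through to the result.
#' @param anova `"two.way"` (cell line as blocking factor) or `"one.way"`
#'   (pooled, ignoring cell line).
#' @return list with `summary` (one row: gene, action, n drugs, direction,
#'   `anova_p`) and `by_cell_line` (per-cell-line means, Welch t and p;
#'   skipped cell lines flagged by `NA`).
#' @export
targetChangeTest <- function(profiles, target_gene, targeting_drugs,
                             presenceList, probe_map, action = NA_character_,
                             anova = c("two.way", "one.way")) {
  anova <- match.arg(anova)
  a <- amplitudeValues(profiles)
  cd <- colData(profiles)
  pooled <- list()
  rows <- list()
  for (cl in sort(unique(as.character(cd$cell_line)))) {
    pres <- presenceList[[cl]]
    if (is.null(pres)) next
    tp <- .presentTargetProbes(target_gene, pres, probe_map)
    if (!length(tp)) next  # target not expressed here: column stays blank
    cols <- which(as.character(cd$cell_line) == cl)
    amp <- colMeans(a[tp, cols, drop = FALSE])
    drugs <- as.character(cd$drug_id[cols])
    grp <- drugs %in% targeting_drugs
    pooled[[cl]] <- data.frame(drug_id = drugs, cell_line = cl,
                               amplitude = amp, targeting = grp,
                               stringsAsFactors = FALSE)
    if (sum(grp) >= 2L && sum(!grp) >= 2L) {
      tt <- stats::t.test(amp[grp], amp[!grp])
      rows[[cl]] <- data.frame(
        gene_id = target_gene, action = action, cell_line = cl,
        n_targeting = sum(grp), n_background = sum(!grp),
        mean_targeting = mean(amp[grp]), mean_background = mean(amp[!grp]),
        t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      rows[[cl]] <- data.frame(
        gene_id = target_gene, action = action, cell_line = cl,
        n_targeting = sum(grp), n_background = sum(!grp),
        mean_targeting = if (sum(grp)) mean(amp[grp]) else NA_real_,
        mean_background = if (sum(!grp)) mean(amp[!grp]) else NA_real_,
        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    }
  }
  dat <- do.call(rbind, pooled)
  anova_p <- NA_real_
  direction <- NA_character_
  n_drugs <- 0L
  if (!is.null(dat)) {
    n_drugs <- length(unique(dat$drug_id[dat$targeting]))
    if (sum(dat$targeting) >= 2L && sum(!dat$targeting) >= 2L) {
      dat$targeting <- factor(dat$targeting, levels = c(FALSE, TRUE))
      fit <- if (anova == "two.way" && length(unique(dat$cell_line)) > 1L)
        stats::lm(amplitude ~ factor(cell_line) + targeting, data = dat)
      else
        stats::lm(amplitude ~ targeting, data = dat)
      at <- stats::anova(fit)
      anova_p <- at["targeting", "Pr(>F)"]
      md <- mean(dat$amplitude[dat$targeting == "TRUE"]) -
        mean(dat$amplitude[dat$targeting == "FALSE"])
      direction <- if (md >= 0) "up" else "down"
    }
  }
  list(summary = data.frame(gene_id = target_gene, action = action,
                            n_targeting_drugs = n_drugs,
                            direction = direction, anova_p = anova_p,
                            stringsAsFactors = FALSE),
       by_cell_line = do.call(rbind, rows), data = dat)
}

#' Benjamini-Hochberg q-values for a regulation screen
#'
#' Adds BH FDR-adjusted q-values over all tested (target, action)
#' hypotheses and a significance flag at `q < alpha`.
#'
#' @param results summary data.frame with an `anova_p` column.
#' @param alpha FDR significance level (default 0.05).
#' @return `results` with `q` and `significant` columns.
#' @export
multipleTesting <- function(results, alpha = 0.05) {
  results$q <- NA_real_
  tested <- !is.na(results$anova_p)
  results$q[tested] <- stats::p.adjust(results$anova_p[tested],
                                       method = "BH")
  results$significant <- !is.na(results$q) & results$q < alpha
  results
}

#' Screen all drug-target relations for feedback regulation
#'
#' End-to-end drug-target screen: folds binding actions, applies the
#' confidence/channel filter, drops targets expressed nowhere (presence at
#' the 1/10 threshold), tests every (target gene, action) hypothesis with
#' [targetChangeTest()] -- activators and inhibitors of the same target are
#' separate hypotheses, as their expected directions are opposite -- and
#' adjusts the ANOVA p-values with Benjamini-Hochberg over the whole family.
#'
#' @param profiles an [AmplitudeProfiles-class] (mean-centered,
#'   replicate-merged).
#' @param relations drug-target relation table.
#' @param presenceList named list of [PresenceSet-class] at threshold 0.1.
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param min_confidence,channels see [filterRelations()].
#' @param overrides manual action corrections, see [foldBindingActions()].
#' @param anova see [targetChangeTest()].
#' @param alpha FDR level for the significance flag.
#' @return list with `summary` (one row per (gene, action): direction,
#'   `anova_p`, `q`, `significant`), `by_cell_line` (per-cell-line Welch
#'   tests) and `relations` (the relations that survived the filters).
#' @export
screenTargetRegulation <- function(profiles, relations, presenceList,
                                   probe_map, min_confidence = 0.7,
                                   channels = c("experimental", "database"),
                                   overrides = NULL,
                                   anova = c("two.way", "one.way"),
                                   alpha = 0.05) {
  anova <- match.arg(anova)
  rel <- foldBindingActions(relations, overrides)
  rel <- filterRelations(rel, min_confidence, channels)
  if (!nrow(rel))
    stop("no relation survives the confidence/channel filter")
  rel <- filterExpressedTargets(rel, presenceList, probe_map)
  if (!nrow(rel))
    stop("no relation target is expressed in any cell line")
  key <- paste(rel$gene_id, rel$action, sep = "\r")
  groups <- split(seq_len(nrow(rel)), key)
  res <- lapply(groups, function(ix) {
    targetChangeTest(profiles, rel$gene_id[ix[1L]],
                     unique(rel$drug_id[ix]), presenceList, probe_map,
                     action = rel$action[ix[1L]], anova = anova)
  })
  summary <- do.call(rbind, lapply(res, `[[`, "summary"))
  rownames(summary) <- NULL
  summary <- multipleTesting(summary, alpha = alpha)
  by_cl <- do.call(rbind, lapply(res, `[[`, "by_cell_line"))
  rownames(by_cl) <- NULL
  list(summary = summary, by_cell_line = by_cl, relations = rel)
}

#' Drugs acting on several differentially regulated targets
#'
#' Multi-target (promiscuous) drugs can induce complex cross-regulation.
#' This report counts, per drug, its distinct targets among the filtered
#' relations and how many of them are significantly regulated (matching the
#' drug's annotated action), listing the regulated targets with their
#' direction. Only drugs with at least two targets appear.
#'
#' @param relations filtered relation table (as returned in
#'   `screenTargetRegulation()$relations`).
#' @param summary the screen summary with `significant` flags.
#' @return data.frame `drug_id`, `n_targets`, `n_regulated_targets`,
#'   `regulated_targets` (comma-separated `gene(direction)`), sorted by
#'   regulated-target count.
#' @export
multiTargetReport <- function(relations, summary) {
  sig <- summary[summary$significant %in% TRUE, , drop = FALSE]
  sig_key <- paste(sig$gene_id, sig$action, sep = "\r")
  out <- lapply(split(seq_len(nrow(relations)), relations$drug_id),
                function(ix) {
    genes <- unique(relations$gene_id[ix])
    if (length(genes) < 2L) return(NULL)
    rkey <- paste(relations$gene_id[ix], relations$action[ix], sep = "\r")
    hit <- match(unique(rkey), sig_key)
    hit <- hit[!is.na(hit)]
    data.frame(
      drug_id = relations$drug_id[ix[1L]], n_targets = length(genes),
      n_regulated_targets = length(unique(sig$gene_id[hit])),
      regulated_targets = paste(sprintf("%s(%s)", sig$gene_id[hit],
                                        sig$direction[hit]), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(drug_id = character(), n_targets = integer(),
                      n_regulated_targets = integer(),
                      regulated_targets = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$n_regulated_targets, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
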