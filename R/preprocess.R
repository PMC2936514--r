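#' Filter treatment instances by production batch size and platform
#'
#' Retains only instances belonging to production batches with strictly more
#' than `min_batch_size` drug treatments (default 25, i.e. "over 25") on an
#' allowed platform, and (by default) discards vehicle-control instances.
#' Batch sizes are counted over treatments only, never controls.
#'
#' @param ps a [PerturbationSet-class].
#' @param min_batch_size batches must contain strictly more treatments than
#'   this to survive (default 25).
#' @param allowed_platforms `NULL` (all platforms allowed), a character
#'   vector of platform ids, or a named list mapping cell line to its
#'   allowed platforms.
#' @param drop_controls drop `is_control` instances from the result (keep
#'   them when the control-based centering baseline is still needed).
#' @return the filtered [PerturbationSet-class]; a warning (not an error) is
#'   emitted if nothing survives.
#' @rdname filterInstances
#' @export
setMethod("filterInstances", "PerturbationSet",
function(ps, min_batch_size = 25L, allowed_platforms = NULL,
         drop_controls = TRUE) {
  cd <- colData(ps)
  treat <- !cd$is_control
  sizes <- table(as.character(cd$batch_id[treat]))
  ok_size <- names(sizes)[sizes > min_batch_size]
  keep_batch <- as.character(cd$batch_id) %in% ok_size
  if (!is.null(allowed_platforms)) {
    if (is.list(allowed_platforms)) {
      ok_pf <- mapply(function(cl, pf) {
        pfs <- allowed_platforms[[cl]]
        is.null(pfs) || pf %in% pfs
      }, as.character(cd$cell_line), as.character(cd$platform))
    } else {
      ok_pf <- as.character(cd$platform) %in% allowed_platforms
    }
    keep_batch <- keep_batch & ok_pf
  }
  keep <- keep_batch & (!drop_controls | treat)
  if (!any(keep))
    warning("no instances survive the batch-size/platform filter")
  ps[, keep]
})

.MOLAR_FACTOR <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9,
                   pM = 1e-12)

#' Keep only the highest tested concentration per drug and cell line
#'
#' Within each (drug, cell line), discards instances at less than the maximum
#' concentration; replicates at the maximum (ties included) all remain, as
#' do vehicle controls. Molar units (`pM`/`nM`/`uM`/`mM`/`M`) are converted
#' to a common scale before comparison; concentrations in units that cannot
#' be reconciled are refused with an explicit error.
#'
#' @param ps a [PerturbationSet-class].
#' @return the filtered [PerturbationSet-class].
#' @rdname selectHighestConcentration
#' @export
setMethod("selectHighestConcentration", "PerturbationSet", function(ps) {
  cd <- colData(ps)
  keep <- rep(TRUE, ncol(ps))
  treat <- which(!cd$is_control)
  grp <- paste(cd$drug_id[treat], cd$cell_line[treat], sep = "\r")
  for (ix in split(treat, grp)) {
    units <- as.character(cd$concentration_unit[ix])
    conc <- cd$concentration_value[ix]
    if (length(unique(units)) > 1L) {
      fac <- .MOLAR_FACTOR[units]
      if (anyNA(fac))
        stop("irreconcilable concentration units for drug ",
             cd$drug_id[ix[1]], " in ", cd$cell_line[ix[1]], ": ",
             paste(unique(units), collapse = ", "))
      conc <- conc * fac
    }
    keep[ix[conc < max(conc)]] <- FALSE
  }
  ps[, keep]
})

.batchCenter <- function(ps, baseline) {
  cd <- colData(ps)
  x <- assay(ps, "exprs")
  treat <- !cd$is_control
  out_cols <- which(treat)
  for (b in unique(as.character(cd$batch_id))) {
    in_b <- as.character(cd$batch_id) == b
    tr_b <- which(in_b & treat)
    if (baseline == "population") {
      if (length(tr_b) < 2L)
        stop("batch ", b, " has fewer than 2 treatments; the population ",
             "mean-centered value would be meaningless")
      m <- rowMeans(x[, tr_b, drop = FALSE])
    } else {
      ct_b <- which(in_b & !treat)
      if (!length(ct_b))
        stop("batch ", b, " has no vehicle controls; control-based ",
             "centering is impossible")
      m <- rowMeans(x[, ct_b, drop = FALSE])
    }
    x[, which(in_b)] <- x[, which(in_b), drop = FALSE] - m
  }
  out <- ps[, out_cols]
  assay(out, "exprs") <- x[, out_cols, drop = FALSE]
  metadata(out)$centering <- if (baseline == "population") "population"
                             else "control"
  out
}

#' Mean-center each probe against the treatment population of its batch
#'
#' For every probe and production batch, subtracts the mean over all drug
#' treatments in that batch, turning absolute log2 intensities into
#' "average difference" expression changes with the heterogeneous treatment
#' population as background. This removes additive batch effects and
#' down-weights common (e.g. stress) responses without relying on the few
#' vehicle controls. Controls, if still present, are dropped from the output.
#'
#' @param ps a [PerturbationSet-class]; every batch must contain at least two
#'   treatment instances.
#' @return a [PerturbationSet-class] of centered treatment instances, with
#'   `metadata()$centering == "population"`.
#' @rdname meanCenterBatch
#' @export
setMethod("meanCenterBatch", "PerturbationSet",
          function(ps) .batchCenter(ps, "population"))

#' Center each probe against the vehicle controls of its batch
#'
#' The classical treatment-versus-control background: subtracts, per probe
#' and batch, the mean over that batch's vehicle-control instances. Kept as
#' the comparison baseline for the population mean-centering of
#' [meanCenterBatch()]. Output contains treatment instances only.
#'
#' @param ps a [PerturbationSet-class]; every batch must contain at least one
#'   control instance.
#' @return a [PerturbationSet-class] with `metadata()$centering == "control"`.
#' @rdname controlCenterBatch
#' @export
setMethod("controlCenterBatch", "PerturbationSet",
          function(ps) .batchCenter(ps, "control"))

#' Merge replicate treatments into one profile per drug and cell line
#'
#' Averages the (already centered) columns of all instances of a drug within
#' a cell line into a single amplitude ("average difference") profile.
#' Profiles from different platforms are never merged: the grouping key is
#' (drug, cell line, platform).
#'
#' @param ps a centered [PerturbationSet-class] of treatment instances.
#' @return an [AmplitudeProfiles-class] with one column per
#'   (drug, cell line, platform).
#' @rdname mergeReplicates
#' @export
setMethod("mergeReplicates", "PerturbationSet", function(ps) {
  cd <- colData(ps)
  treat <- which(!cd$is_control)
  if (!length(treat))
    stop("no treatment instances to merge")
  x <- assay(ps, "exprs")
  key <- paste(cd$drug_id[treat], cd$cell_line[treat], cd$platform[treat],
               sep = "\r")
  groups <- split(treat, key)
  prof <- vapply(groups, function(ix) rowMeans(x[, ix, drop = FALSE]),
                 numeric(nrow(x)))
  first <- vapply(groups, `[`, integer(1), 1L)
  pdata <- data.frame(
    profile_id = paste(cd$drug_id[first], cd$cell_line[first], sep = "."),
    drug_id = as.character(cd$drug_id[first]),
    cell_line = as.character(cd$cell_line[first]),
    platform = as.character(cd$platform[first]),
    n_instances = lengths(groups),
    stringsAsFactors = FALSE)
  rownames(pdata) <- pdata$profile_id
  colnames(prof) <- pdata$profile_id
  se <- SummarizedExperiment(assays = list(amplitude = prof),
                             colData = DataFrame(pdata))
  out <- new("AmplitudeProfiles", se)
  metadata(out)$centering <- metadata(ps)$centering %||% "unknown"
  out
})

#' Flag probes Present in a cell line
#'
#' A probe is 'Present in a cell line' when its detection call is `"P"` in at
#' least `threshold` of the drug-treatment instances of that cell line
#' (inclusive: exactly the threshold fraction qualifies). The ranking stage
#' uses threshold 1/2; the drug-target expression screen uses 1/10.
#'
#' @param ps a [PerturbationSet-class] carrying a `calls` assay.
#' @param cell_line cell line to count over; defaults to the only cell line
#'   present (an error if several are).
#' @param threshold required fraction of instances, in (0, 1].
#' @return a [PresenceSet-class].
#' @rdname assignPresence
#' @export
setMethod("assignPresence", "PerturbationSet",
function(ps, cell_line = NULL, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must be in (0, 1]")
  cd <- colData(ps)
  if (is.null(cell_line)) {
    cls <- unique(as.character(cd$cell_line))
    if (length(cls) != 1L)
      stop("several cell lines present; specify 'cell_line'")
    cell_line <- cls
  }
  cols <- which(as.character(cd$cell_line) == cell_line & !cd$is_control)
  if (!length(cols))
    stop("no treatment instances for cell line ", cell_line)
  calls <- callValues(ps)[, cols, drop = FALSE]
  n_present <- rowSums(calls == "P")
  in_set <- n_present >= threshold * length(cols)
  new("PresenceSet", cell_line = cell_line, threshold = threshold,
      probes = rownames(ps)[in_set], n_instances = length(cols))
})

#' Presence sets for every cell line of a compendium
#'
#' @param ps a [PerturbationSet-class] with detection calls.
#' @param threshold fraction of instances required (see [assignPresence()]).
#' @return named list of [PresenceSet-class], one per cell line.
#' @export
presenceByCellLine <- function(ps, threshold = 0.5) {
  cls <- sort(unique(as.character(colData(ps)$cell_line)))
  stats::setNames(lapply(cls, function(cl)
    assignPresence(ps, cell_line = cl, threshold = threshold)), cls)
}
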