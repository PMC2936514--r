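#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
NULL

.INSTANCE_COLUMNS <- c("instance_id", "drug_id", "cell_line", "batch_id",
                       "platform", "concentration_value", "concentration_unit",
                       "is_control")

#' Container for a drug-perturbation expression compendium
#'
#' A `PerturbationSet` holds a probe x treatment-instance matrix of
#' log2 expression values (assay `"exprs"`), optionally a same-shaped matrix
#' of detection calls (assay `"calls"`, values `"P"`/`"A"`/`"M"`), and one
#' row of instance metadata per array in `colData`: `instance_id`, `drug_id`,
#' `cell_line`, `batch_id`, `platform`, `concentration_value`,
#' `concentration_unit` and `is_control`. Vehicle-control instances carry
#' `is_control = TRUE` and `NA` for `drug_id`.
#'
#' The class extends [SummarizedExperiment::SummarizedExperiment], so all of
#' its subsetting and accessor machinery applies.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("PerturbationSet", contains = "SummarizedExperiment")

setValidity("PerturbationSet", function(object) {
  msgs <- character()
  if (!("exprs" %in% assayNames(object)))
    msgs <- c(msgs, "assay 'exprs' is required")
  cd <- colData(object)
  missing_cols <- setdiff(.INSTANCE_COLUMNS, colnames(cd))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing instance metadata column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (!length(msgs)) {
    ids <- cd$instance_id
    if (anyDuplicated(ids))
      msgs <- c(msgs, "instance_id values must be unique")
    if (!identical(as.character(colnames(object)), as.character(ids)))
      msgs <- c(msgs, "colnames must equal colData$instance_id")
    ex <- assay(object, "exprs")
    if (anyNA(ex) || any(!is.finite(ex)))
      msgs <- c(msgs, "assay 'exprs' must be finite (no NA/NaN/Inf)")
    if (anyDuplicated(rownames(object)))
      msgs <- c(msgs, "probe ids (rownames) must be unique")
    # a production batch is a single physical run: one cell line, one platform
    key <- paste(cd$cell_line, cd$platform, sep = "\r")
    if (any(vapply(split(key, as.character(cd$batch_id)),
                   function(k) length(unique(k)) > 1L, logical(1))))
      msgs <- c(msgs, "each batch_id must map to a single cell_line/platform")
    if ("calls" %in% assayNames(object)) {
      cl <- assay(object, "calls")
      bad <- !(cl %in% c("P", "A", "M"))
      if (any(bad))
        msgs <- c(msgs, "detection calls must be 'P', 'A' or 'M'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PerturbationSet
#'
#' @param exprs numeric probe x instance matrix of log2 expression values,
#'   with probe ids as rownames and instance ids as colnames.
#' @param instanceData data.frame (or DataFrame) of instance metadata with
#'   the columns listed in [PerturbationSet-class]; rows are matched to the
#'   matrix columns by `instance_id`.
#' @param calls optional character matrix of detection calls, same dimensions
#'   and dimnames as `exprs`, values in `P`/`A`/`M`.
#' @return a [PerturbationSet-class] object.
#' @examples
#' sim <- simulateCompendium(simulationConfig(n_probes = 50, n_drugs = 6,
#'   n_cell_lines = 1, batches_per_cell_line = 2, treatments_per_batch = 4))
#' sim$ps
#' @export
PerturbationSet <- function(exprs, instanceData, calls = NULL) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs))
    stop("'exprs' must be numeric")
  instanceData <- as.data.frame(instanceData, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.INSTANCE_COLUMNS, colnames(instanceData))
  if (length(missing_cols))
    stop("instanceData lacks column(s): ", paste(missing_cols, collapse = ", "))
  idx <- match(colnames(exprs), instanceData$instance_id)
  if (anyNA(idx)) {
    stop("instance(s) present in the matrix but absent from the metadata: ",
         paste(head(colnames(exprs)[is.na(idx)], 5L), collapse = ", "))
  }
  instanceData <- instanceData[idx, , drop = FALSE]
  rownames(instanceData) <- instanceData$instance_id
  assays <- list(exprs = exprs)
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    if (!identical(dim(calls), dim(exprs)))
      stop("'calls' must have the same dimensions as 'exprs'")
    dimnames(calls) <- dimnames(exprs)
    assays$calls <- calls
  }
  se <- SummarizedExperiment(assays = assays,
                             colData = DataFrame(instanceData))
  new("PerturbationSet", se)
}

#' Replicate-merged expression-change profiles
#'
#' An `AmplitudeProfiles` object stores one mean-centered, replicate-averaged
#' expression-change ("average difference") vector per (drug, cell line,
#' platform) as columns of assay `"amplitude"`. `colData` carries
#' `profile_id`, `drug_id`, `cell_line`, `platform` and `n_instances`;
#' `metadata()$centering` records which background was subtracted
#' (`"population"` or `"control"`).
#'
#' @export
setClass("AmplitudeProfiles", contains = "SummarizedExperiment")

setValidity("AmplitudeProfiles", function(object) {
  msgs <- character()
  if (!("amplitude" %in% assayNames(object)))
    msgs <- c(msgs, "assay 'amplitude' is required")
  need <- c("profile_id", "drug_id", "cell_line", "platform", "n_instances")
  missing_cols <- setdiff(need, colnames(colData(object)))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing profile metadata column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (!length(msgs)) {
    key <- paste(colData(object)$drug_id, colData(object)$cell_line,
                 colData(object)$platform)
    if (anyDuplicated(key))
      msgs <- c(msgs, "one profile per (drug, cell line, platform) expected")
    a <- assay(object, "amplitude")
    if (anyNA(a) || any(!is.finite(a)))
      msgs <- c(msgs, "amplitudes must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Probes called Present in a cell line
#'
#' Set of probe ids whose detection call is `"P"` in at least
#' `threshold` x (number of treatment instances) arrays of one cell line.
#'
#' @slot cell_line cell line the set was computed for.
#' @slot threshold fraction of instances required, in (0, 1].
#' @slot probes character vector of probe ids in the set.
#' @slot n_instances number of treatment instances the calls were counted over.
#' @export
setClass("PresenceSet",
         representation(cell_line = "character", threshold = "numeric",
                        probes = "character", n_instances = "integer"))

setValidity("PresenceSet", function(object) {
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  if (anyDuplicated(object@probes))
    return("probes must be unique")
  TRUE
})

#' Two-step ranked expression-change profile
#'
#' Probes ordered from most up- to most down-regulated. Probes absent in the
#' cell line have their value set to 0 before sorting ("effective" value) and
#' are sub-sorted within the zero block by their initial average difference.
#'
#' @slot drug_id,cell_line identifiers (may be empty for ad hoc profiles).
#' @slot probes probe ids in rank order (rank 1 = most up-regulated).
#' @slot effective per-probe value used for the primary ordering.
#' @slot initial per-probe initial average difference, same order.
#' @export
setClass("RankedProfile",
         representation(drug_id = "character", cell_line = "character",
                        probes = "character", effective = "numeric",
                        initial = "numeric"))

setValidity("RankedProfile", function(object) {
  n <- length(object@probes)
  if (length(object@effective) != n || length(object@initial) != n)
    return("probes, effective and initial must have equal length")
  if (anyDuplicated(object@probes))
    return("ranked probes must be unique")
  TRUE
})

#' Optimal signature of a ranked profile
#'
#' The top-`n` ("up") and bottom-`n` ("down") probe ids of a
#' [RankedProfile-class] (default n = 250 on full arrays).
#'
#' @slot drug_id,cell_line identifiers.
#' @slot up,down character vectors of probe ids, each of length `n`.
#' @slot n signature half-size.
#' @export
setClass("DrugSignature",
         representation(drug_id = "character", cell_line = "character",
                        up = "character", down = "character", n = "integer"))

setValidity("DrugSignature", function(object) {
  if (length(object@up) != object@n || length(object@down) != object@n)
    return("|up| and |down| must equal n")
  if (length(intersect(object@up, object@down)))
    return("up and down sets must be disjoint")
  TRUE
})

#' Drug x drug similarity matrix
#'
#' Symmetric matrix of pairwise profile-similarity scores for one cell line
#' (or `"combined"` for the cross-cell-line average). Pairs not scoreable in
#' any shared cell line are `NA`.
#'
#' @slot scores symmetric numeric matrix, drugs as dimnames.
#' @slot cell_line cell line label or `"combined"`.
#' @slot weighting `"classic"` or `"weighted"` KS increments.
#' @export
setClass("DIPSMatrix",
         representation(scores = "matrix", cell_line = "character",
                        weighting = "character"))

setValidity("DIPSMatrix", function(object) {
  s <- object@scores
  if (nrow(s) != ncol(s) || !identical(rownames(s), colnames(s)))
    return("scores must be square with matching dimnames")
  if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE)))
    return("scores must be symmetric")
  TRUE
})

setMethod("show", "PerturbationSet", function(object) {
  cd <- colData(object)
  n_tr <- sum(!cd$is_control)
  cat("PerturbationSet:", nrow(object), "probes x", ncol(object),
      "instances\n")
  cat("  treatments:", n_tr, "| controls:", ncol(object) - n_tr,
      "| drugs:", length(unique(cd$drug_id[!cd$is_control])),
      "| batches:", length(unique(cd$batch_id)),
      "| cell lines:", paste(unique(cd$cell_line), collapse = ", "), "\n")
  if ("calls" %in% assayNames(object)) cat("  detection calls: yes\n")
  ctr <- metadata(object)$centering
  if (!is.null(ctr)) cat("  centering:", ctr, "\n")
  invisible(object)
})

setMethod("show", "AmplitudeProfiles", function(object) {
  cat("AmplitudeProfiles:", nrow(object), "probes x", ncol(object),
      "profiles\n")
  cat("  cell lines:",
      paste(unique(colData(object)$cell_line), collapse = ", "),
      "| centering:", metadata(object)$centering %||% "unknown", "\n")
  invisible(object)
})

setMethod("show", "PresenceSet", function(object) {
  cat("PresenceSet:", length(object@probes), "probes Present in",
      object@cell_line, "(threshold", object@threshold, "over",
      object@n_instances, "instances)\n")
  invisible(object)
})

setMethod("show", "RankedProfile", function(object) {
  cat("RankedProfile", if (nzchar(object@drug_id))
        paste0("[", object@drug_id, "/", object@cell_line, "]") else "",
      ":", length(object@probes), "probes; top:",
      paste(head(object@probes, 3L), collapse = ", "), "...\n")
  invisible(object)
})

setMethod("show", "DrugSignature", function(object) {
  cat("DrugSignature", if (nzchar(object@drug_id))
        paste0("[", object@drug_id, "/", object@cell_line, "]") else "",
      ": n =", object@n, "up/down probes\n")
  invisible(object)
})

setMethod("show", "DIPSMatrix", function(object) {
  cat("DIPSMatrix [", object@cell_line, "]: ", nrow(object@scores), " x ",
      ncol(object@scores), " drugs, ", object@weighting,
      " KS weighting\n", sep = "")
  invisible(object)
})
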