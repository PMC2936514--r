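#' Read a probe x instance expression matrix from TSV
#'
#' First column: probe id; header: instance ids. Missing values are not
#' permitted and are rejected with an explicit error.
#'
#' @param path TSV file path.
#' @return numeric matrix with probe rownames.
#' @export
readExpressionMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value in expression matrix at probe ",
         rownames(m)[bad[1L]], ", instance ", colnames(m)[bad[2L]],
         "; missing values are not permitted")
  }
  m
}

#' Read a detection-call matrix (values P/A/M) from TSV
#'
#' @param path TSV file path, same layout as the expression matrix.
#' @return character matrix.
#' @export
readDetectionCalls <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  bad <- !(m %in% c("P", "A", "M"))
  if (any(bad))
    stop("detection calls must be P, A or M; found: ",
         paste(utils::head(unique(m[bad]), 3L), collapse = ", "))
  m
}

#' Read an instance metadata table from TSV
#'
#' Required columns: `instance_id`, `drug_id`, `cell_line`, `batch_id`,
#' `platform`, `concentration_value`, `concentration_unit`, `is_control`.
#'
#' @param path TSV file path.
#' @return data.frame of instance metadata.
#' @export
readInstanceTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.INSTANCE_COLUMNS, colnames(d))
  if (length(missing_cols))
    stop("instance table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d$is_control <- as.logical(d$is_control)
  d$drug_id[d$drug_id %in% c("", "NA")] <- NA_character_
  d
}

#' Read a drug-target relation table from TSV
#'
#' Columns: `drug_id`, `gene_id`, `action`, `confidence`, `channel`.
#'
#' @param path TSV file path.
#' @return data.frame of relations.
#' @export
readRelationTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "gene_id", "action", "confidence", "channel")
  missing_cols <- setdiff(need, colnames(d))
  if (length(missing_cols))
    stop("relation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d
}

#' Assemble a PerturbationSet from TSV inputs
#'
#' @param expr,meta,calls file paths (calls optional).
#' @return a [PerturbationSet-class].
#' @export
loadPerturbationSet <- function(expr, meta, calls = NULL) {
  x <- readExpressionMatrix(expr)
  m <- readInstanceTable(meta)
  cm <- if (!is.null(calls)) readDetectionCalls(calls) else NULL
  PerturbationSet(x, m, calls = cm)
}

.writeTSV <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-form table of a DIPS matrix
#'
#' @param dips a [DIPSMatrix-class].
#' @param keep_na keep pairs without a score.
#' @return data.frame `drug_a`, `drug_b`, `cell_line`, `score` (upper
#'   triangle, excluding the diagonal).
#' @export
dipsLong <- function(dips, keep_na = FALSE) {
  s <- dips@scores
  ut <- upper.tri(s)
  ix <- which(ut, arr.ind = TRUE)
  out <- data.frame(drug_a = rownames(s)[ix[, 1L]],
                    drug_b = colnames(s)[ix[, 2L]],
                    cell_line = dips@cell_line, score = s[ut],
                    stringsAsFactors = FALSE)
  if (!keep_na) out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a ranked profile to TSV
#'
#' Columns: probe, rank, effective_value, initial_value.
#'
#' @param ranked a [RankedProfile-class].
#' @param path output path.
#' @export
writeRankedProfile <- function(ranked, path) {
  .writeTSV(data.frame(probe = ranked@probes,
                       rank = seq_along(ranked@probes),
                       effective_value = ranked@effective,
                       initial_value = ranked@initial), path)
}

#' Serialize signatures in a two-column gene-set (GRP-like) format
#'
#' One row per probe: `set` (`<drug>.<cell_line>.up` / `.down`) and `probe`.
#'
#' @param signatures list of [DrugSignature-class].
#' @param path output path.
#' @export
writeSignatures <- function(signatures, path) {
  rows <- lapply(signatures, function(s) {
    base <- paste(s@drug_id, s@cell_line, sep = ".")
    rbind(data.frame(set = paste0(base, ".up"), probe = s@up,
                     stringsAsFactors = FALSE),
          data.frame(set = paste0(base, ".down"), probe = s@down,
                     stringsAsFactors = FALSE))
  })
  .writeTSV(do.call(rbind, rows), path)
}

#' Write a simulated compendium (and its ground truth) as pipeline inputs
#'
#' Produces the TSV files consumed by [runPipeline()]: `expr.tsv`,
#' `meta.tsv`, `calls.tsv`, `relations.tsv`, `probe_map.tsv`,
#' `tanimoto.tsv`, `atc.tsv`, plus ground-truth records
#' (`truth_relations.tsv`, `truth_similar_pairs.tsv`).
#'
#' @param sim result of [simulateCompendium()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCompendium <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- exprValues(sim$ps)
  .writeTSV(data.frame(probe_id = rownames(x), x, check.names = FALSE),
            file.path(dir, "expr.tsv"))
  cl <- callValues(sim$ps)
  .writeTSV(data.frame(probe_id = rownames(cl), cl, check.names = FALSE),
            file.path(dir, "calls.tsv"))
  .writeTSV(as.data.frame(colData(sim$ps)), file.path(dir, "meta.tsv"))
  .writeTSV(sim$relations, file.path(dir, "relations.tsv"))
  .writeTSV(sim$probe_map, file.path(dir, "probe_map.tsv"))
  .writeTSV(sim$tanimoto, file.path(dir, "tanimoto.tsv"))
  .writeTSV(sim$atc, file.path(dir, "atc.tsv"))
  .writeTSV(sim$truth$relations, file.path(dir, "truth_relations.tsv"))
  .writeTSV(sim$truth$similar_pairs,
            file.path(dir, "truth_similar_pairs.tsv"))
  invisible(dir)
}
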