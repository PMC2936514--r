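#' Binary pair labels from a chemical-similarity (Tanimoto) table
#'
#' Labels a drug pair positive when its 2D Tanimoto coefficient is strictly
#' greater than `threshold` (default 0.8). Rows with similarities outside
#' \[0, 1\] are rejected with a warning; pairs absent from the table are
#' simply unlabeled.
#'
#' @param similarity data.frame with columns `drug_a`, `drug_b`, `tanimoto`.
#' @param threshold strict lower bound for a positive label.
#' @return a `PairLabelSet`: data.frame (`drug_a`, `drug_b` in canonical
#'   order, `label` 0/1) with attributes `label_source = "tanimoto"` and
#'   `threshold`.
#' @export
labelsFromTanimoto <- function(similarity, threshold = 0.8) {
  need <- c("drug_a", "drug_b", "tanimoto")
  if (!all(need %in% colnames(similarity)))
    stop("similarity table needs columns: ", paste(need, collapse = ", "))
  bad <- is.na(similarity$tanimoto) | similarity$tanimoto < 0 |
    similarity$tanimoto > 1
  if (any(bad)) {
    warning(sum(bad), " row(s) with similarity outside [0, 1] rejected")
    similarity <- similarity[!bad, , drop = FALSE]
  }
  out <- data.frame(
    drug_a = pmin(as.character(similarity$drug_a),
                  as.character(similarity$drug_b)),
    drug_b = pmax(as.character(similarity$drug_a),
                  as.character(similarity$drug_b)),
    label = as.integer(similarity$tanimoto > threshold),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(.pairKey(out$drug_a, out$drug_b)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, label_source = "tanimoto", threshold = threshold)
}

.ATC_PREFIX_LEN <- c(1L, 3L, 4L, 5L, 7L)

#' Binary pair labels from shared ATC classification
#'
#' Labels a drug pair positive when any ATC code of one drug shares the
#' level-`level` prefix with any code of the other (level 4 = first 5
#' characters, the chemical/therapeutic subgroup). Drugs may carry several
#' codes (one row each); drugs without any valid code are excluded from the
#' labeled set. Codes not matching the WHO format (letter, 2 digits,
#' 2 letters, 2 digits) are rejected with a warning.
#'
#' @param atc data.frame with columns `drug_id`, `atc_code`.
#' @param level ATC level 1-5.
#' @return a `PairLabelSet` data.frame as in [labelsFromTanimoto()], with
#'   `label_source = "atc"`.
#' @export
labelsFromAtc <- function(atc, level = 4L) {
  if (!all(c("drug_id", "atc_code") %in% colnames(atc)))
    stop("ATC table needs columns: drug_id, atc_code")
  if (!(level %in% seq_len(5L))) stop("'level' must be 1-5")
  ok <- grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", atc$atc_code)
  if (any(!ok)) {
    warning(sum(!ok), " malformed ATC code(s) rejected: ",
            paste(utils::head(atc$atc_code[!ok], 3L), collapse = ", "))
    atc <- atc[ok, , drop = FALSE]
  }
  plen <- .ATC_PREFIX_LEN[level]
  prefixes <- split(substr(atc$atc_code, 1L, plen), as.character(atc$drug_id))
  drugs <- sort(names(prefixes))
  if (length(drugs) < 2L)
    stop("fewer than two drugs with a valid ATC code")
  pr <- t(utils::combn(drugs, 2L))
  lab <- vapply(seq_len(nrow(pr)), function(k)
    as.integer(length(intersect(prefixes[[pr[k, 1L]]],
                                prefixes[[pr[k, 2L]]])) > 0L), integer(1))
  structure(data.frame(drug_a = pr[, 1L], drug_b = pr[, 2L], label = lab,
                       stringsAsFactors = FALSE),
            label_source = "atc", level = level)
}

#' Pair labels from simulation ground truth
#'
#' Converts the generator's `truth$similar_pairs` record into the same
#' `PairLabelSet` shape as the external label builders.
#'
#' @param similar_pairs data.frame with `drug_a`, `drug_b`, `similar`.
#' @return a `PairLabelSet` data.frame with `label_source = "ground_truth"`.
#' @export
labelsFromTruth <- function(similar_pairs) {
  structure(data.frame(
    drug_a = pmin(similar_pairs$drug_a, similar_pairs$drug_b),
    drug_b = pmax(similar_pairs$drug_a, similar_pairs$drug_b),
    label = as.integer(similar_pairs$similar), stringsAsFactors = FALSE),
    label_source = "ground_truth")
}

#' Align a pairwise score matrix with a pair label set
#'
#' Pairs with a score but no label, or a label but no score (including `NA`
#' scores), are excluded listwise.
#'
#' @param dips a [DIPSMatrix-class] (or plain symmetric matrix with drug
#'   dimnames).
#' @param labels a `PairLabelSet` data.frame.
#' @return list with numeric vectors `scores` and `labels` plus the pair ids.
#' @export
matchScoresToLabels <- function(dips, labels) {
  s <- if (is(dips, "DIPSMatrix")) dips@scores else dips
  drugs <- rownames(s)
  keep <- labels$drug_a %in% drugs & labels$drug_b %in% drugs &
    labels$drug_a != labels$drug_b
  lab <- labels[keep, , drop = FALSE]
  sc <- s[cbind(match(lab$drug_a, drugs), match(lab$drug_b, drugs))]
  ok <- !is.na(sc)
  list(scores = sc[ok], labels = lab$label[ok],
       drug_a = lab$drug_a[ok], drug_b = lab$drug_b[ok])
}

#' ROC curve, AUC and unnormalized partial AUC
#'
#' Standard ROC over descending score thresholds. Tied scores are collapsed
#' into a single threshold, so ties contribute a diagonal segment and the
#' trapezoidal AUC equals the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg` (ties counted 1/2). The partial AUC is the raw area under
#' the curve for `FPR < fpr_cutoff` (unnormalized: a perfect classifier
#' attains the cutoff value itself).
#'
#' @param scores numeric vector (higher = more confident positive).
#' @param labels 0/1 (or logical) vector of the same length; both classes
#'   must be represented.
#' @param fpr_cutoff FPR cutoff for the partial AUC, in (0, 1].
#' @return an object of class `ROCResult`: list with `points` (data.frame
#'   `fpr`, `tpr`, monotone non-decreasing), `auc`, `pauc`, `cutoff`,
#'   `n_pos`, `n_neg`.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocCurve <- function(scores, labels, fpr_cutoff = 0.1) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  if (anyNA(scores) || anyNA(labels))
    stop("NA in scores or labels; align and filter first")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present (", n_pos, " positives, ",
         n_neg, " negatives)")
  if (fpr_cutoff <= 0 || fpr_cutoff > 1)
    stop("'fpr_cutoff' must be in (0, 1]")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # end of each tie group
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  # partial area on [0, cutoff): interpolate the curve at the cutoff
  pauc <- 0
  for (k in seq_len(length(fpr) - 1L)) {
    x0 <- fpr[k]; x1 <- fpr[k + 1L]
    y0 <- tpr[k]; y1 <- tpr[k + 1L]
    if (x0 >= fpr_cutoff) break
    if (x1 > fpr_cutoff) {
      y1 <- y0 + (y1 - y0) * (fpr_cutoff - x0) / (x1 - x0)
      x1 <- fpr_cutoff
    }
    pauc <- pauc + (x1 - x0) * (y0 + y1) / 2
  }
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, pauc = pauc, cutoff = fpr_cutoff,
                 n_pos = n_pos, n_neg = n_neg),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat("ROC:", x$n_pos, "positives /", x$n_neg, "negatives; AUC =",
      format(x$auc, digits = 4), "; partial AUC (FPR <", x$cutoff, ") =",
      format(x$pauc, digits = 4), "\n")
  invisible(x)
}

#' Benchmark a DIPS matrix against one or more label sets
#'
#' Convenience wrapper: aligns the score matrix with each label set and
#' returns the ROC results.
#'
#' @param dips a [DIPSMatrix-class].
#' @param labelSets named list of `PairLabelSet` data.frames.
#' @param fpr_cutoff partial-AUC cutoff.
#' @return named list of `ROCResult` objects.
#' @export
benchmarkScores <- function(dips, labelSets, fpr_cutoff = 0.1) {
  lapply(labelSets, function(lab) {
    m <- matchScoresToLabels(dips, lab)
    rocCurve(m$scores, m$labels, fpr_cutoff = fpr_cutoff)
  })
}
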