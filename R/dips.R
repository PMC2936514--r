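# Signed KS running-sum enrichment from sorted hit positions.
# Walk over the ranked list: each hit increments by its (normalized) weight,
# each miss decrements by 1/(N - m). The extrema of the walk occur at hit
# steps (just before / just after each hit) or at the flat start/end (0), so
# only O(m) candidates need evaluating. ES = deviation of maximal absolute
# value, signed; an exact +/- tie returns the positive deviation.
.esFromHits <- function(hitpos, N, hitw = NULL) {
  m <- length(hitpos)
  o <- order(hitpos)
  p <- hitpos[o]
  if (is.null(hitw)) {
    W <- seq_len(m) / m
  } else {
    w <- abs(hitw[o])
    sw <- sum(w)
    # all-zero weights degenerate to equal increments
    W <- if (sw == 0) seq_len(m) / m else cumsum(w) / sw
  }
  miss <- (p - seq_len(m)) / (N - m)
  vhi <- W - miss
  vlo <- c(0, W[-m]) - miss
  hi <- max(vhi, 0)
  lo <- min(vlo, 0)
  # an exact +/- tie resolves to the positive deviation; the comparison is
  # tolerant so summation order cannot flip the sign
  if (hi >= -lo - 1e-12) hi else lo
}

#' Kolmogorov-Smirnov enrichment score of a probe set in a ranked profile
#'
#' Computes the GSEA-style signed enrichment score (ES) of a query probe set
#' along a ranked expression-change profile: a running sum is incremented at
#' every query ("hit") probe and decremented by `1/(N - |S|)` at every miss;
#' the ES is the running-sum value of maximal absolute deviation from zero,
#' keeping its sign. With `weighting = "classic"` every hit increments by
#' `1/|S|`; with `weighting = "weighted"` hit increments are proportional to
#' the absolute effective value of the probe in the profile (exponent 1).
#'
#' @param query_set character vector of probe ids; must be a non-empty
#'   proper subset of the ranked probes.
#' @param ranked a [RankedProfile-class].
#' @param weighting `"classic"` or `"weighted"`.
#' @return an object of class `EnrichmentScore`: a list with `value` (ES in
#'   \[-1, 1\]), `query_set_size`, `list_length` and `weighting`.
#' @examples
#' v <- stats::setNames(10:1, letters[1:10])
#' r <- rankProfile(v, present = letters[1:10])
#' ksEnrichment(letters[1:3], r)$value  # +1: query is exactly the top ranks
#' @export
ksEnrichment <- function(query_set, ranked, weighting = c("classic",
                                                          "weighted")) {
  weighting <- match.arg(weighting)
  query_set <- unique(as.character(query_set))
  N <- length(ranked@probes)
  hitpos <- match(query_set, ranked@probes)
  if (anyNA(hitpos))
    stop("query set contains probe(s) absent from the ranked profile")
  if (length(hitpos) < 1L || length(hitpos) >= N)
    stop("query set must be a non-empty proper subset of the ranked list")
  hitw <- if (weighting == "weighted") ranked@effective[hitpos] else NULL
  structure(list(value = .esFromHits(hitpos, N, hitw),
                 query_set_size = length(hitpos), list_length = N,
                 weighting = weighting),
            class = "EnrichmentScore")
}

#' @export
print.EnrichmentScore <- function(x, ...) {
  cat("ES =", format(x$value, digits = 4), "(", x$weighting, "weighting,",
      x$query_set_size, "probes in a list of", x$list_length, ")\n")
  invisible(x)
}

# directional score of signature `sig` queried in ranked profile of the
# partner: (ES_up - ES_down) / 2, so a concordant match scores +1
.directionalScore <- function(up_hits, down_hits, N, up_w, down_w) {
  (.esFromHits(up_hits, N, up_w) - .esFromHits(down_hits, N, down_w)) / 2
}

#' Bidirectional profile-similarity (DIPS) score of a drug pair
#'
#' Queries the up- and down-sets of drug X's optimal signature in drug Y's
#' ranked profile and vice versa. Each query direction yields a directional
#' score `(ES_up - ES_down)/2` (the sign flip accounts for a concordant
#' down-set producing a negative ES); the DIPS score is the mean of the two
#' directional scores. The score is symmetric by construction and equals +1
#' for a self-comparison and -1 against the reversed profile under classic
#' weighting.
#'
#' Signature probes missing from the partner profile are tolerated if at
#' least 90 percent are shared (the query is restricted to the shared
#' probes); a smaller overlap is an error.
#'
#' @param sig_x,sig_y [DrugSignature-class] objects.
#' @param ranked_x,ranked_y the corresponding [RankedProfile-class] objects.
#' @param weighting `"classic"` or `"weighted"` KS increments.
#' @return a single numeric similarity in \[-1, 1\].
#' @export
dipsPair <- function(sig_x, ranked_x, sig_y, ranked_y,
                     weighting = c("classic", "weighted")) {
  weighting <- match.arg(weighting)
  query <- function(sig, ranked) {
    N <- length(ranked@probes)
    up <- match(sig@up, ranked@probes)
    dn <- match(sig@down, ranked@probes)
    shared <- mean(!is.na(c(up, dn)))
    if (shared < 0.9)
      stop("only ", round(100 * shared), "% of signature probes are in the ",
           "partner profile (>= 90% required)")
    up <- up[!is.na(up)]
    dn <- dn[!is.na(dn)]
    uw <- if (weighting == "weighted") ranked@effective[up] else NULL
    dw <- if (weighting == "weighted") ranked@effective[dn] else NULL
    .directionalScore(up, dn, N, uw, dw)
  }
  (query(sig_x, ranked_y) + query(sig_y, ranked_x)) / 2
}

# precomputed lookup tables for fast all-pairs scoring over a shared probe
# universe: rank position of every universe probe in every profile, the
# effective value at every rank, and signature ranks in the own profile
.profileIndex <- function(rankedList, n) {
  universe <- rankedList[[1L]]@probes
  np <- length(universe)
  nprof <- length(rankedList)
  rankpos <- matrix(NA_integer_, nrow = np, ncol = nprof)
  effrank <- matrix(NA_real_, nrow = np, ncol = nprof)
  upidx <- vector("list", nprof)
  dnidx <- vector("list", nprof)
  uidx <- stats::setNames(seq_len(np), universe)
  for (j in seq_len(nprof)) {
    rp <- rankedList[[j]]
    if (length(rp@probes) != np)
      stop("all profiles must share one probe universe")
    perm <- uidx[rp@probes]
    rankpos[perm, j] <- seq_len(np)
    effrank[, j] <- rp@effective
    upidx[[j]] <- unname(perm[seq_len(n)])
    dnidx[[j]] <- unname(perm[seq.int(np - n + 1L, np)])
  }
  list(rankpos = rankpos, effrank = effrank, up = upidx, down = dnidx,
       N = np, names = names(rankedList))
}

.dipsFromIndex <- function(i, j, idx, weighted) {
  N <- idx$N
  dscore <- function(q, k) {
    uh <- idx$rankpos[idx$up[[q]], k]
    dh <- idx$rankpos[idx$down[[q]], k]
    if (weighted)
      .directionalScore(uh, dh, N, idx$effrank[uh, k], idx$effrank[dh, k])
    else
      .directionalScore(uh, dh, N, NULL, NULL)
  }
  (dscore(i, j) + dscore(j, i)) / 2
}

#' All-pairs DIPS matrix for one cell line
#'
#' Ranks every drug profile of one cell line, extracts optimal signatures of
#' half-size `n` and computes the full symmetric drug x drug DIPS matrix.
#'
#' @param profiles an [AmplitudeProfiles-class] restricted to one cell line,
#'   one profile per drug.
#' @param presence the cell line's [PresenceSet-class] (ranking threshold,
#'   typically 1/2).
#' @param n signature half-size (250 on full arrays; scale down for small
#'   probe universes).
#' @param weighting `"classic"` or `"weighted"`.
#' @return a [DIPSMatrix-class].
#' @export
dipsMatrix <- function(profiles, presence, n = 250L,
                       weighting = c("classic", "weighted")) {
  weighting <- match.arg(weighting)
  cls <- cellLines(profiles)
  if (length(cls) != 1L)
    stop("'profiles' must contain a single cell line; got: ",
         paste(cls, collapse = ", "))
  dr <- drugIds(profiles)
  if (anyDuplicated(dr))
    stop("multiple profiles per drug (several platforms?); ",
         "one profile per drug is required")
  ranked <- rankProfiles(profiles, presence)
  if (length(ranked[[1L]]@probes) < 2L * n)
    stop("signature half-size n = ", n, " needs >= ", 2L * n, " probes")
  idx <- .profileIndex(ranked, as.integer(n))
  D <- length(ranked)
  s <- matrix(NA_real_, D, D, dimnames = list(dr, dr))
  weighted <- weighting == "weighted"
  for (i in seq_len(D)) {
    s[i, i] <- .dipsFromIndex(i, i, idx, weighted)
    if (i < D) for (j in seq.int(i + 1L, D)) {
      v <- .dipsFromIndex(i, j, idx, weighted)
      s[i, j] <- v
      s[j, i] <- v
    }
  }
  new("DIPSMatrix", scores = s, cell_line = cls, weighting = weighting)
}

#' Combine per-cell-line DIPS matrices into one score per drug pair
#'
#' The combined similarity of a drug pair is the arithmetic mean of its DIPS
#' scores over the cell lines in which both drugs were profiled; cell lines
#' missing either drug contribute nothing. Pairs sharing no cell line are
#' `NA`.
#'
#' @param matrices a list of [DIPSMatrix-class] objects (one per cell line).
#' @return a [DIPSMatrix-class] with `cell_line == "combined"`.
#' @export
combineCellLines <- function(matrices) {
  if (!length(matrices)) stop("no matrices to combine")
  drugs <- sort(unique(unlist(lapply(matrices, function(m)
    rownames(m@scores)))))
  acc <- matrix(0, length(drugs), length(drugs),
                dimnames = list(drugs, drugs))
  cnt <- acc
  for (m in matrices) {
    d <- rownames(m@scores)
    acc[d, d] <- acc[d, d] + m@scores
    cnt[d, d] <- cnt[d, d] + 1
  }
  s <- acc / cnt
  s[cnt == 0] <- NA_real_
  new("DIPSMatrix", scores = s, cell_line = "combined",
      weighting = matrices[[1L]]@weighting)
}

#' Pearson-correlation variant of pairwise profile similarity
#'
#' Plain Pearson correlation between amplitude vectors, the simple
#' alternative read-out for the same four drug/batch category comparison.
#' Zero-variance profiles yield `NA` correlations and a warning naming the
#' affected profiles (never a silent 0).
#'
#' @param profiles an [AmplitudeProfiles-class] (profiles share the probe
#'   space by construction).
#' @return symmetric correlation matrix with profile ids as dimnames.
#' @export
pairwisePearson <- function(profiles) {
  a <- amplitudeValues(profiles)
  sds <- apply(a, 2L, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning("zero-variance profile(s), correlations set to NA: ",
            paste(colnames(a)[flat], collapse = ", "))
  r <- suppressWarnings(stats::cor(a, method = "pearson"))
  r[flat, ] <- NA_real_
  r[, flat] <- NA_real_
  r
}

.CATEGORIES <- c("same-drug/same-batch", "same-drug/different-batch",
                 "different-drug/same-batch", "different-drug/different-batch")

#' Instance-level pair categories and score distributions
#'
#' Scores every pair of treatment instances of a centered compendium (within
#' cell lines) with the DIPS statistic, labels each pair into the four
#' drug/batch categories -- (i) same drug & same batch, (ii) same drug &
#' different batch, (iii) different drug & same batch, (iv) different drug &
#' different batch -- and compares the per-category score distributions with
#' Welch two-sample t-tests. Category (iii) exceeding (iv) is the signature
#' of a residual batch effect.
#'
#' @param ps a centered [PerturbationSet-class] (instance-level, pre-merge).
#' @param presence [PresenceSet-class] or named list keyed by cell line.
#' @param n signature half-size used for the instance-level signatures.
#' @param weighting `"classic"` or `"weighted"`.
#' @param alternative passed to [stats::t.test()] for the category
#'   comparisons, with the first category of each comparison as `x` (use
#'   `"greater"` for the directional batch-effect hypotheses).
#' @param score `"dips"` or `"pearson"`.
#' @return list with `scores` (one row per instance pair: ids, drugs,
#'   cell line, category, score) and `tests` (one row per category
#'   comparison: means, Welch t, p; comparisons with under-filled categories
#'   are skipped with a warning).
#' @export
categorizePairs <- function(ps, presence, n = 100L,
                            weighting = c("classic", "weighted"),
                            alternative = "two.sided",
                            score = c("dips", "pearson")) {
  weighting <- match.arg(weighting)
  score <- match.arg(score)
  cd <- colData(ps)
  out <- list()
  for (cl in sort(unique(as.character(cd$cell_line)))) {
    cols <- which(as.character(cd$cell_line) == cl & !cd$is_control)
    if (length(cols) < 2L) next
    pres <- if (is.list(presence)) presence[[cl]] else presence
    x <- assay(ps, "exprs")[, cols, drop = FALSE]
    drug <- as.character(cd$drug_id[cols])
    batch <- as.character(cd$batch_id[cols])
    ids <- as.character(cd$instance_id[cols])
    pairs <- utils::combn(length(cols), 2L)
    if (score == "dips") {
      ranked <- lapply(seq_along(cols), function(j)
        rankProfile(stats::setNames(x[, j], rownames(x)), pres))
      idx <- .profileIndex(ranked, as.integer(n))
      weighted <- weighting == "weighted"
      sc <- vapply(seq_len(ncol(pairs)), function(k)
        .dipsFromIndex(pairs[1L, k], pairs[2L, k], idx, weighted),
        numeric(1))
    } else {
      r <- suppressWarnings(stats::cor(x))
      sc <- r[cbind(pairs[1L, ], pairs[2L, ])]
    }
    i1 <- pairs[1L, ]; i2 <- pairs[2L, ]
    same_drug <- drug[i1] == drug[i2]
    same_batch <- batch[i1] == batch[i2]
    category <- ifelse(same_drug,
                       ifelse(same_batch, .CATEGORIES[1L], .CATEGORIES[2L]),
                       ifelse(same_batch, .CATEGORIES[3L], .CATEGORIES[4L]))
    out[[cl]] <- data.frame(instance_a = ids[i1], instance_b = ids[i2],
                            drug_a = drug[i1], drug_b = drug[i2],
                            cell_line = cl, category = category, score = sc,
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, out)
  if (is.null(scores)) stop("no cell line with at least two instances")
  rownames(scores) <- NULL

  combos <- utils::combn(.CATEGORIES, 2L)
  tests <- lapply(seq_len(ncol(combos)), function(k) {
    a <- scores$score[scores$category == combos[1L, k]]
    b <- scores$score[scores$category == combos[2L, k]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("category comparison skipped (fewer than 2 pairs): ",
              combos[1L, k], " vs ", combos[2L, k])
      return(NULL)
    }
    tt <- stats::t.test(a, b, alternative = alternative)
    data.frame(category_a = combos[1L, k], category_b = combos[2L, k],
               n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  list(scores = scores, tests = do.call(rbind, tests))
}

#' Merge cell lines on jointly Present probes
#'
#' For cross-cell-line profile comparisons, restricts every cell line's
#' profiles to the probes Present in all cell lines and concatenates the
#' columns into a single [AmplitudeProfiles-class].
#'
#' @param profilesList list of [AmplitudeProfiles-class], one per cell line
#'   (at least two).
#' @param presenceList list of matching [PresenceSet-class] objects.
#' @return an [AmplitudeProfiles-class] over the shared Present probes.
#' @export
crossCellLineMerge <- function(profilesList, presenceList) {
  if (length(profilesList) < 2L)
    stop("need profiles from at least two cell lines")
  shared <- Reduce(intersect, lapply(presenceList, .presenceProbes))
  if (!length(shared))
    stop("no probe is Present in every cell line")
  parts <- lapply(profilesList, function(p) {
    a <- amplitudeValues(p)
    a[shared, , drop = FALSE]
  })
  mat <- do.call(cbind, parts)
  cdat <- do.call(rbind, lapply(profilesList, function(p)
    as.data.frame(colData(p), stringsAsFactors = FALSE)))
  rownames(cdat) <- cdat$profile_id
  se <- SummarizedExperiment(assays = list(amplitude = mat),
                             colData = DataFrame(cdat))
  out <- new("AmplitudeProfiles", se)
  metadata(out)$centering <- metadata(profilesList[[1L]])$centering
  out
}
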