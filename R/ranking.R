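#' Rank a profile by detection call and average difference
#'
#' Implements the two-step ranking of an amplitude profile. Step 1: the
#' average difference of every probe not Present in the cell line is set
#' to 0 (the "effective" value). Step 2: probes are sorted in descending
#' order of effective value. Step 3: inside the block of probes whose value
#' was set to 0, probes are sub-sorted in descending order of their initial
#' average difference. A Present probe whose value is exactly 0 was never
#' "set to 0", so its sub-sort key is 0. All remaining ties are broken by
#' probe id (lexicographic, ascending) to make the ordering reproducible.
#'
#' @param profile named numeric vector of average differences (names are
#'   probe ids), or an [AmplitudeProfiles-class] column extracted upstream.
#' @param present a [PresenceSet-class] or character vector of probe ids
#'   Present in the cell line.
#' @param drug_id,cell_line optional identifiers stored on the result.
#' @return a [RankedProfile-class] (rank 1 = most up-regulated).
#' @examples
#' v <- c(A = 0.5, B = -0.3, C = 0.9, D = 0.1)
#' rankProfile(v, present = c("A", "B"))@probes  # A, C, D, B
#' @export
rankProfile <- function(profile, present, drug_id = "", cell_line = "") {
  v <- profile
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop("'profile' must be a named vector with unique probe ids")
  pr <- .presenceProbes(present)
  is_present <- names(v) %in% pr
  eff <- ifelse(is_present, v, 0)
  subkey <- ifelse(is_present, 0, v)  # zero-block sub-sort on initial value
  o <- order(-eff, -subkey, names(v), method = "radix")
  new("RankedProfile", drug_id = drug_id, cell_line = cell_line,
      probes = names(v)[o], effective = unname(eff[o]),
      initial = unname(v[o]))
}

#' Extract the optimal signature of a ranked profile
#'
#' The optimal signature is the set of the top-`n` and bottom-`n` ranked
#' probes of a drug's expression-change profile (default n = 250 on
#' full-size arrays) -- the characteristic cellular response used for
#' pairwise similarity scoring.
#'
#' @param ranked a [RankedProfile-class] with at least `2 * n` probes.
#' @param n signature half-size.
#' @return a [DrugSignature-class].
#' @export
extractSignature <- function(ranked, n = 250L) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  np <- length(ranked@probes)
  if (np < 2L * n)
    stop("profile has ", np, " probes; need at least 2n = ", 2L * n)
  new("DrugSignature", drug_id = ranked@drug_id,
      cell_line = ranked@cell_line,
      up = ranked@probes[seq_len(n)],
      down = ranked@probes[seq.int(np - n + 1L, np)], n = n)
}

#' Rank every profile of an AmplitudeProfiles object
#'
#' @param profiles an [AmplitudeProfiles-class].
#' @param presence a [PresenceSet-class] (single cell line) or a named list
#'   of presence sets keyed by cell line.
#' @return named list of [RankedProfile-class], keyed by profile id.
#' @export
rankProfiles <- function(profiles, presence) {
  a <- amplitudeValues(profiles)
  cd <- colData(profiles)
  lapply(stats::setNames(seq_len(ncol(a)), colnames(a)), function(j) {
    cl <- as.character(cd$cell_line[j])
    pres <- if (is.list(presence)) {
      if (is.null(presence[[cl]]))
        stop("no presence set supplied for cell line ", cl)
      presence[[cl]]
    } else presence
    rankProfile(stats::setNames(a[, j], rownames(a)), pres,
                drug_id = as.character(cd$drug_id[j]), cell_line = cl)
  })
}
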