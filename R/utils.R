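`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical unordered pair key, used to join scores with labels
.pairKey <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.treatmentIdx <- function(ps) which(!colData(ps)$is_control)

.stopifnotPS <- function(ps) {
  if (!is(ps, "PerturbationSet"))
    stop("expected a PerturbationSet")
  invisible(ps)
}

# probes of a PresenceSet, or a plain character vector passed through
.presenceProbes <- function(present) {
  if (is(present, "PresenceSet")) present@probes else as.character(present)
}
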