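#' Mechanism-pattern classes for NCO recombinants
#'
#' The classes assignable from hDNA topology, in the order used throughout:
#' unidirectional hDNA (plasmid hDNA on exactly one side of the gap; the
#' pattern predicted by SDSA), bidirectional hDNA (plasmid hDNA on both
#' sides; predicted by double-Holliday-junction dissolution, or by two
#' independent strand invasions — the two are observationally identical),
#' the Holliday-junction cleavage pattern (plasmid hDNA on one side and
#' donor-chromosome hDNA on the opposite side), conversion only, no
#' detectable transfer, and ambiguous (any pattern outside these
#' predictions, e.g. donor hDNA on the same side as plasmid hDNA).
#'
#' @return Character vector of the six class labels.
#' @export
mechanism_classes <- function() {
  c(
    "UNIDIRECTIONAL", "BIDIRECTIONAL", "CLEAVAGE_PATTERN",
    "CONVERSION_ONLY", "NO_TRANSFER", "AMBIGUOUS"
  )
}

#' Classify one NCO event from its transfer summary
#'
#' A total, deterministic function of the five primary booleans of a
#' [summarize_transfer()] result (`any_transfer` is recomputed internally).
#' Classification is by hDNA presence per side only; whether per-side hDNA is
#' contiguous or patchy, and whether conversion accompanies it, do not change
#' the class of an hDNA-bearing event.
#'
#' @param summary A `transfer_summary` (or compatible list of booleans).
#' @return One of [mechanism_classes()].
#' @export
classify_event <- function(summary) {
  pl <- isTRUE(summary$has_hdna_plasmid_left)
  pr <- isTRUE(summary$has_hdna_plasmid_right)
  cl <- isTRUE(summary$has_hdna_chromosome_left)
  cr <- isTRUE(summary$has_hdna_chromosome_right)
  conv <- isTRUE(summary$has_conversion)

  if (!pl && !pr && !cl && !cr) {
    return(if (conv) "CONVERSION_ONLY" else "NO_TRANSFER")
  }
  if (pl && pr) {
    return(if (cl || cr) "AMBIGUOUS" else "BIDIRECTIONAL")
  }
  if (xor(pl, pr)) {
    chrom_opposite <- if (pl) cr else cl
    chrom_same <- if (pl) cl else cr
    if (!cl && !cr) return("UNIDIRECTIONAL")
    if (chrom_opposite && !chrom_same) return("CLEAVAGE_PATTERN")
    return("AMBIGUOUS")
  }
  # chromosome-only hDNA: outside the predicted patterns
  "AMBIGUOUS"
}

#' Tabulate mechanism classes per strain
#'
#' @param events A data.frame with columns `strain` and `class` (values from
#'   [mechanism_classes()]), one row per sequenced NCO event.
#' @return A data.frame with one row per strain: counts of each class,
#'   `n_sequenced` (all events) and `n_with_hdna`
#'   (unidirectional + bidirectional + cleavage-pattern, i.e. every event
#'   with plasmid hDNA detected — the denominator the proportion columns of
#'   the efficiency tables use).
#' @export
tabulate_classes <- function(events) {
  cls <- mechanism_classes()
  cols <- c(
    UNIDIRECTIONAL = "unidirectional", BIDIRECTIONAL = "bidirectional",
    CLEAVAGE_PATTERN = "cleavage", CONVERSION_ONLY = "conversion_only",
    NO_TRANSFER = "no_transfer", AMBIGUOUS = "ambiguous"
  )
  strains <- unique(as.character(events$strain))
  rows <- lapply(strains, function(st) {
    x <- events$class[events$strain == st]
    if (!all(x %in% cls)) stop("unknown class label", call. = FALSE)
    cnt <- vapply(cls, function(cl) sum(x == cl), integer(1))
    names(cnt) <- cols[cls]
    out <- as.data.frame(as.list(cnt))
    out$strain <- st
    out$n_sequenced <- length(x)
    out$n_with_hdna <- cnt[["unidirectional"]] + cnt[["bidirectional"]] +
      cnt[["cleavage"]]
    out
  })
  if (length(rows) == 0L) {
    return(data.frame(
      unidirectional = integer(), bidirectional = integer(),
      cleavage = integer(), conversion_only = integer(),
      no_transfer = integer(), ambiguous = integer(),
      strain = character(), n_sequenced = integer(), n_with_hdna = integer()
    ))
  }
  out <- do.call(rbind, rows)
  out[, c(
    "strain", "unidirectional", "bidirectional", "cleavage",
    "conversion_only", "no_transfer", "ambiguous", "n_sequenced",
    "n_with_hdna"
  )]
}
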