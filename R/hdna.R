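#' Per-SNP genotype calls for one allele of a recombinant
#'
#' Sequencing of a recombinant in a mismatch-repair-deficient background
#' yields, at each diverged SNP, one of three codes: `R` (the allele's own,
#' recipient base), `D` (the other allele's base, i.e. full conversion at that
#' SNP) or `H` (a double peak, indicating an unrepaired heteroduplex mismatch
#' that segregated at replication).
#'
#' @param codes Character vector of single-letter codes (`R`/`D`/`H`), one per
#'   SNP of the map, ordered by position; or a single string, optionally with a
#'   literal `|` marking the gap (e.g. `"RRHHRRRRR|RRRRRRRRRR"`).
#' @param role `"PLASMID"` (the repaired, gapped allele) or `"CHROMOSOME"`
#'   (the donor template allele).
#' @param map A `snp_map`; used to check the code count.
#' @return An object of class `allele_calls` with fields `role` and `codes`.
#' @export
allele_calls <- function(codes, role = c("PLASMID", "CHROMOSOME"),
                         map = default_substrate()) {
  role <- match.arg(role)
  if (length(codes) == 1L && nchar(codes[1]) > 1L) {
    codes <- strsplit(gsub("|", "", codes, fixed = TRUE), "")[[1]]
  }
  codes <- as.character(codes)
  n <- length(map$snp_positions)
  if (length(codes) != n) {
    stop("expected ", n, " codes, got ", length(codes), call. = FALSE)
  }
  if (!all(codes %in% c("R", "D", "H"))) {
    stop("codes must be R, D or H", call. = FALSE)
  }
  structure(list(role = role, codes = codes), class = "allele_calls")
}

#' Format allele calls as a gap-delimited string
#'
#' @param calls An `allele_calls` object.
#' @param map The `snp_map` the calls refer to.
#' @return A string such as `"RRHHRRRRR|RRRRRRRRRR"`, with `|` at the gap.
#' @export
format_calls <- function(calls, map = default_substrate()) {
  sides <- snp_sides(map)
  paste0(
    paste(calls$codes[sides == "LEFT"], collapse = ""), "|",
    paste(calls$codes[sides == "RIGHT"], collapse = "")
  )
}

#' Call heteroduplex tracts on one allele
#'
#' A tract is a maximal contiguous run of `H` codes. Runs never span the gap:
#' they are broken there by construction, so each tract lies entirely on one
#' side. `R` and `D` codes outside the runs do not affect the result, and a
#' `D` code between two `H` runs does not merge them (discontinuous hDNA is
#' reported as multiple tracts).
#'
#' @param calls An `allele_calls` object.
#' @param map The `snp_map` the calls refer to.
#' @return A data.frame with one row per tract: `allele`, `side`,
#'   `first_snp`, `last_snp` (1-based indices into the map's SNPs), `n_snps`.
#' @export
call_tracts <- function(calls, map = default_substrate()) {
  n <- length(map$snp_positions)
  if (length(calls$codes) != n) {
    stop("calls length does not match map", call. = FALSE)
  }
  sides <- snp_sides(map)
  out <- data.frame(
    allele = character(), side = character(),
    first_snp = integer(), last_snp = integer(), n_snps = integer(),
    stringsAsFactors = FALSE
  )
  for (sd in c("LEFT", "RIGHT")) {
    idx <- which(sides == sd)
    if (length(idx) == 0L) next
    h <- calls$codes[idx] == "H"
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      out <- rbind(out, data.frame(
        allele = calls$role, side = sd,
        first_snp = idx[starts[k]], last_snp = idx[ends[k]],
        n_snps = r$lengths[k], stringsAsFactors = FALSE
      ))
    }
  }
  out[order(out$first_snp), , drop = FALSE]
}

#' Summarize sequence transfer for one recombinant
#'
#' Reduces the two alleles' calls to the per-side booleans used for mechanism
#' classification: hDNA presence on each side of each allele, whether any SNP
#' shows full conversion (a `D` code), and whether any transfer at all was
#' detected. Recombinants with only conversion, or with no detectable
#' transfer, are excluded from hDNA-proportion denominators downstream.
#'
#' @param plasmid,chromosome `allele_calls` for the repaired plasmid allele
#'   and the chromosomal donor allele.
#' @param map The `snp_map` both refer to.
#' @return A `transfer_summary` list of six booleans:
#'   `has_hdna_plasmid_left/right`, `has_hdna_chromosome_left/right`,
#'   `has_conversion`, `any_transfer`.
#' @export
summarize_transfer <- function(plasmid, chromosome, map = default_substrate()) {
  sides <- snp_sides(map)
  hd <- function(calls, sd) any(calls$codes[sides == sd] == "H")
  s <- list(
    has_hdna_plasmid_left = hd(plasmid, "LEFT"),
    has_hdna_plasmid_right = hd(plasmid, "RIGHT"),
    has_hdna_chromosome_left = hd(chromosome, "LEFT"),
    has_hdna_chromosome_right = hd(chromosome, "RIGHT"),
    has_conversion = any(plasmid$codes == "D") || any(chromosome$codes == "D")
  )
  s$any_transfer <- Reduce(`||`, s)
  structure(s, class = "transfer_summary")
}
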