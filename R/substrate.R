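#' SNP map of the gap-repair substrate
#'
#' A `snp_map` describes the physical geometry of the recipient locus used in
#' a plasmid gap-repair assay: the locus length, the restriction gap, and the
#' positions of the diverged SNPs that mark heteroduplex DNA. Coordinates are
#' 1-based and inclusive; the gap occupies positions
#' `[gap_start, gap_start + gap_length - 1]`.
#'
#' @param locus_length Length of the recipient locus in bp.
#' @param gap_start First deleted position of the gap (1-based).
#' @param gap_length Length of the gap in bp.
#' @param snp_positions Strictly increasing integer vector of SNP positions;
#'   none may fall inside the gap.
#' @return An object of class `snp_map`.
#' @seealso [default_substrate()], [side_of()], [validate_map()]
#' @export
snp_map <- function(locus_length, gap_start, gap_length, snp_positions) {
  map <- structure(
    list(
      locus_length = as.integer(locus_length),
      gap_start = as.integer(gap_start),
      gap_length = as.integer(gap_length),
      snp_positions = as.integer(snp_positions)
    ),
    class = "snp_map"
  )
  bad <- validate_map(map)
  if (length(bad) > 0L) {
    stop("invalid snp_map: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  map
}

#' Default 800-bp gap-repair substrate
#'
#' The default geometry: an 800-bp locus with a centrally located 8-bp gap
#' (positions 397-404) and 19 SNPs, the nearest of which sit 18 bp from each
#' gap edge (positions 379 and 422). Only side membership and ordering of the
#' SNPs matter to the downstream analysis, so the remaining 17 positions are a
#' documented deterministic layout: 9 SNPs spread evenly over the left arm and
#' 10 over the right arm.
#'
#' @return A `snp_map` with 19 SNPs (9 LEFT, 10 RIGHT).
#' @examples
#' map <- default_substrate()
#' length(map$snp_positions)  # 19
#' @export
default_substrate <- function() {
  gap_start <- 397L
  gap_len <- 8L
  left <- as.integer(round(seq(22, gap_start - 18L, length.out = 9)))
  right_anchor <- gap_start + gap_len - 1L + 18L
  right <- as.integer(round(seq(right_anchor, 779, length.out = 10)))
  snp_map(800L, gap_start, gap_len, c(left, right))
}

#' Last position of the gap interval
#' @param map A `snp_map`.
#' @return Integer position of the final deleted base.
#' @export
gap_end <- function(map) map$gap_start + map$gap_length - 1L

#' Side of the gap for a SNP position
#'
#' @param position A SNP position present in `map`.
#' @param map A `snp_map`.
#' @return `"LEFT"` if the position precedes the gap, `"RIGHT"` if it follows.
#' @export
side_of <- function(position, map) {
  if (!position %in% map$snp_positions) {
    stop("position ", position, " is not a SNP in the map", call. = FALSE)
  }
  if (position < map$gap_start) "LEFT" else "RIGHT"
}

#' Sides of all SNPs in a map
#' @param map A `snp_map`.
#' @return Character vector, one of `"LEFT"`/`"RIGHT"` per SNP, in map order.
#' @export
snp_sides <- function(map) {
  ifelse(map$snp_positions < map$gap_start, "LEFT", "RIGHT")
}

#' Distance of each SNP from the nearest gap edge
#'
#' Left-arm SNPs are measured to the base just before the gap, right-arm SNPs
#' to the base just after it; the anchored nearest SNPs of the default map are
#' at distance 18 on both sides.
#'
#' @param map A `snp_map`.
#' @return Integer vector of distances in bp, in map order.
#' @export
snp_edge_distance <- function(map) {
  ifelse(map$snp_positions < map$gap_start,
    map$gap_start - map$snp_positions,
    map$snp_positions - gap_end(map)
  )
}

#' Validate a SNP map
#'
#' @param map A `snp_map` (or a bare list with the same fields).
#' @return Character vector of violation messages; empty if the map is valid.
#' @export
validate_map <- function(map) {
  v <- character()
  if (map$locus_length < 1L) v <- c(v, "locus_length must be positive")
  if (map$gap_length < 1L) v <- c(v, "gap_length must be positive")
  if (map$gap_start < 1L || map$gap_start + map$gap_length - 1L > map$locus_length) {
    v <- c(v, "gap not contained in locus")
  }
  p <- map$snp_positions
  if (length(p) == 0L) v <- c(v, "no SNP positions")
  if (any(is.na(p))) v <- c(v, "NA SNP positions")
  if (length(p) > 1L && any(diff(p) <= 0L)) v <- c(v, "positions not increasing")
  if (any(p < 1L | p > map$locus_length, na.rm = TRUE)) {
    v <- c(v, "snp outside locus")
  }
  inside <- p >= map$gap_start & p <= map$gap_start + map$gap_length - 1L
  if (any(inside, na.rm = TRUE)) v <- c(v, "snp inside gap")
  v
}

#' @export
print.snp_map <- function(x, ...) {
  sides <- snp_sides(x)
  cat(sprintf(
    "snp_map: %d bp locus, gap [%d,%d] (%d bp), %d SNPs (%d LEFT / %d RIGHT)\n",
    x$locus_length, x$gap_start, gap_end(x), x$gap_length,
    length(x$snp_positions), sum(sides == "LEFT"), sum(sides == "RIGHT")
  ))
  invisible(x)
}

#' Read / write a SNP-map configuration (JSON)
#'
#' The JSON holds `locus_length`, `gap_start`, `gap_length`, `snp_positions`
#' and round-trips losslessly.
#'
#' @param path File path.
#' @return `read_snp_map()` returns a `snp_map`.
#' @export
read_snp_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  snp_map(x$locus_length, x$gap_start, x$gap_length, x$snp_positions)
}

#' @rdname read_snp_map
#' @param map A `snp_map` to write.
#' @export
write_snp_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
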