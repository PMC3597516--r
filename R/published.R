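#' Published per-strain counts shipped with the package
#'
#' The raw per-strain inputs of the published analysis — printed repair
#' efficiencies, CO/NCO partition counts, and unidirectional/bidirectional/
#' cleavage hDNA counts among sequenced NCOs — together with the printed
#' derived cells (`printed_*` columns) used as reproduction targets. Strains
#' are the MMR-deficient reference ("WT") and helicase-deficient derivatives
#' (mph1, sgs1, srs2, double mutants, and the strippase-dead srs2-860
#' allele).
#'
#' @return Data.frame, one row per strain.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_tables.tsv", package = "gaphdna")
  read_tsv(path)
}

#' Recompute the published efficiency tables from their counts
#'
#' Feeds the printed repair efficiencies and raw counts through
#' [build_efficiency_table()]; the result's efficiency and proportion
#' columns reproduce every published derived cell to within +/- 0.01 (the
#' published tables chained unrounded intermediates that are not printed,
#' so exact equality at 2 decimals is not always attainable from the printed
#' inputs).
#'
#' @return List with `table` (full precision), `report` (rounded via
#'   [round_report()]) and `published` (the fixture including `printed_*`
#'   columns).
#' @export
reproduce_published_tables <- function() {
  pub <- published_counts()
  table <- build_efficiency_table(pub[, c(
    "strain", "repair_efficiency", "co_count", "nco_count",
    "uni_count", "bi_count", "cleavage_count"
  )])
  list(table = table, report = round_report(table), published = pub)
}
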