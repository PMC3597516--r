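#' Normalize His+:Leu+ ratios to the wild-type mean, per plasmid mix
#'
#' Two different mixes of linear plasmid were used across transformation
#' experiments and give different absolute His+:Leu+ ratios in the reference
#' strain, so each transformation's raw ratio is divided by the wild-type
#' mean ratio of the SAME mix before pooling across mixes. The pooled
#' wild-type mean of the normalized values is 1 by construction when every
#' mix is equally... (exactly 1 within each mix; pooled WT mean is the
#' count-weighted mean of per-mix means, which is 1 as each mix normalizes to
#' its own mean).
#'
#' @param records Data.frame of transformations to normalize: columns
#'   `strain`, `mix_id`, `his_count`, `leu_count` (`leu_count > 0`).
#' @param wt_records Data.frame of wild-type transformations with the same
#'   columns; must contain at least one record for every `mix_id` present in
#'   `records`.
#' @param wt_mix_means Optional named numeric override of the WT mean raw
#'   ratio per mix (names = mix ids), e.g. `c("1" = 1.57, "2" = 1.05)`; when
#'   given, `wt_records` may be `NULL`.
#' @return `records` with an added column `value`, the normalized ratio.
#' @export
normalize_ratios <- function(records, wt_records = NULL, wt_mix_means = NULL) {
  if (any(records$leu_count <= 0)) {
    stop("leu_count must be positive", call. = FALSE)
  }
  mixes <- unique(records$mix_id)
  if (is.null(wt_mix_means)) {
    if (is.null(wt_records)) {
      stop("either wt_records or wt_mix_means is required", call. = FALSE)
    }
    wt_mix_means <- vapply(mixes, function(m) {
      w <- wt_records[wt_records$mix_id == m, , drop = FALSE]
      if (nrow(w) == 0L) {
        stop("no wild-type records for mix ", m, call. = FALSE)
      }
      mean(w$his_count / w$leu_count)
    }, numeric(1))
    names(wt_mix_means) <- as.character(mixes)
  }
  miss <- setdiff(as.character(mixes), names(wt_mix_means))
  if (length(miss) > 0L) {
    stop("no wild-type mean for mix ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  records$value <- (records$his_count / records$leu_count) /
    wt_mix_means[as.character(records$mix_id)]
  records
}

#' Partition His+ transformants into crossover and noncrossover events
#'
#' Crossover/noncrossover status is scored by plasmid stability (5-FOA
#' growth); this reduces the per-transformant calls to counts and exact
#' proportions.
#'
#' @param stability_calls Character vector of `"CO"` / `"NCO"` per His+
#'   transformant.
#' @return List: `co_count`, `nco_count`, `co_proportion`, `nco_proportion`.
#' @export
partition_co_nco <- function(stability_calls) {
  if (length(stability_calls) == 0L) {
    stop("no stability calls", call. = FALSE)
  }
  if (!all(stability_calls %in% c("CO", "NCO"))) {
    stop("stability calls must be CO or NCO", call. = FALSE)
  }
  co <- sum(stability_calls == "CO")
  n <- length(stability_calls)
  list(
    co_count = co, nco_count = n - co,
    co_proportion = co / n, nco_proportion = (n - co) / n
  )
}

#' Decompose repair efficiency into CO and NCO efficiencies
#'
#' Mean CO (NCO) efficiency is the mean normalized repair efficiency
#' multiplied by the proportion of transformants scored as CO (NCO), so the
#' two components sum exactly to the repair efficiency.
#'
#' @param repair_efficiency Mean WT-normalized His+:Leu+ ratio.
#' @param co_proportion Proportion of events scored CO, in `[0, 1]`.
#' @return Named numeric: `co_efficiency`, `nco_efficiency` (unrounded).
#' @export
compute_efficiencies <- function(repair_efficiency, co_proportion) {
  stopifnot(co_proportion >= 0, co_proportion <= 1)
  c(
    co_efficiency = repair_efficiency * co_proportion,
    nco_efficiency = repair_efficiency * (1 - co_proportion)
  )
}

#' Decompose NCO efficiency into unidirectional and bidirectional classes
#'
#' The NCO efficiency is split in proportion to the unidirectional and
#' bidirectional counts among hDNA-detected events. The denominator is
#' `uni_count + bi_count + other_detected`: `other_detected` covers
#' hDNA-bearing events of neither class (e.g. a cleavage-pattern event),
#' which the published tabulation keeps in the denominator while reporting
#' them separately. With `other_detected = 0` the two class efficiencies sum
#' exactly to `nco_efficiency`.
#'
#' @param nco_efficiency Mean NCO efficiency (unrounded).
#' @param uni_count,bi_count Events with unidirectional / bidirectional hDNA.
#' @param other_detected hDNA-detected events of neither class (default 0).
#' @return Named numeric: `uni_efficiency`, `bi_efficiency` (unrounded).
#' @export
compute_class_efficiencies <- function(nco_efficiency, uni_count, bi_count,
                                       other_detected = 0) {
  denom <- uni_count + bi_count + other_detected
  if (denom < 1) stop("no hDNA-detected events", call. = FALSE)
  c(
    uni_efficiency = nco_efficiency * uni_count / denom,
    bi_efficiency = nco_efficiency * bi_count / denom
  )
}

#' Assemble the per-strain efficiency table
#'
#' The machine twin of the published per-strain tables: repair efficiency,
#' CO/NCO counts, proportions and efficiencies, and (where sequencing counts
#' are given) unidirectional/bidirectional proportions and efficiencies.
#' All values are kept at full precision; round for reporting with
#' [round_report()].
#'
#' @param counts Data.frame with one row per strain and columns
#'   `strain`, `repair_efficiency`, `co_count`, `nco_count`, and optionally
#'   `uni_count`, `bi_count`, `cleavage_count` (NA where not sequenced).
#' @return Data.frame with the input columns plus `co_proportion`,
#'   `nco_proportion`, `co_efficiency`, `nco_efficiency`, `uni_proportion`,
#'   `bi_proportion`, `uni_efficiency`, `bi_efficiency`.
#' @export
build_efficiency_table <- function(counts) {
  req <- c("strain", "repair_efficiency", "co_count", "nco_count")
  if (!all(req %in% names(counts))) {
    stop("missing columns: ", paste(setdiff(req, names(counts)), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(counts$strain)) {
    stop("duplicate strain labels", call. = FALSE)
  }
  out <- counts
  tot <- out$co_count + out$nco_count
  if (any(tot < 1)) stop("strain with no events", call. = FALSE)
  out$co_proportion <- out$co_count / tot
  out$nco_proportion <- out$nco_count / tot
  out$co_efficiency <- out$repair_efficiency * out$co_proportion
  out$nco_efficiency <- out$repair_efficiency * out$nco_proportion
  if (!"uni_count" %in% names(out)) out$uni_count <- NA_integer_
  if (!"bi_count" %in% names(out)) out$bi_count <- NA_integer_
  if (!"cleavage_count" %in% names(out)) out$cleavage_count <- 0L
  out$cleavage_count[is.na(out$cleavage_count)] <- 0L
  denom <- out$uni_count + out$bi_count + out$cleavage_count
  out$uni_proportion <- out$uni_count / denom
  out$bi_proportion <- out$bi_count / denom
  out$uni_efficiency <- out$nco_efficiency * out$uni_proportion
  out$bi_efficiency <- out$nco_efficiency * out$bi_proportion
  out
}

#' Round an efficiency table for reporting
#'
#' Efficiencies round half-even to 2 decimals and proportions to whole
#' percent, the precision of the published tables; the unrounded table is
#' what all chained computations use.
#'
#' @param table Output of [build_efficiency_table()].
#' @return The table with rounded `*_efficiency` columns and `*_proportion`
#'   columns as percentages.
#' @export
round_report <- function(table) {
  for (col in grep("_efficiency$", names(table), value = TRUE)) {
    table[[col]] <- round(table[[col]], 2)
  }
  table$repair_efficiency <- round(table$repair_efficiency, 2)
  for (col in grep("_proportion$", names(table), value = TRUE)) {
    table[[col]] <- round(100 * table[[col]])
  }
  table
}

#' End-to-end analysis of a simulated or observed cohort
#'
#' Runs the full pipeline on per-event records: calls tracts, summarizes
#' transfer, classifies each NCO event, tabulates classes per strain, and —
#' combined with per-transformation counts — assembles the efficiency table.
#'
#' @param events Data.frame as written by [simulate_cohort()] (columns
#'   `event_id`, `strain`, `stability_call`, `plasmid_calls`,
#'   `chromosome_calls`).
#' @param transformations Data.frame of per-transformation counts (`strain`,
#'   `mix_id`, `his_count`, `leu_count`).
#' @param wt_strain Label of the reference strain within `transformations`.
#' @param map The `snp_map` the call strings refer to.
#' @return List with `classes` (per-event), `class_counts` (per-strain),
#'   `normalized` (per-transformation normalized ratios) and `table`
#'   (the efficiency table).
#' @export
analyze_cohort <- function(events, transformations, wt_strain = "WT",
                           map = default_substrate()) {
  nco <- events[events$stability_call == "NCO", , drop = FALSE]
  cls <- vapply(seq_len(nrow(nco)), function(i) {
    pl <- allele_calls(nco$plasmid_calls[i], "PLASMID", map)
    ch <- allele_calls(nco$chromosome_calls[i], "CHROMOSOME", map)
    classify_event(summarize_transfer(pl, ch, map))
  }, "")
  classes <- data.frame(
    event_id = nco$event_id, strain = nco$strain, class = cls,
    stringsAsFactors = FALSE
  )
  class_counts <- tabulate_classes(classes)

  wt <- transformations[transformations$strain == wt_strain, , drop = FALSE]
  if (nrow(wt) == 0L) stop("no transformations for ", wt_strain, call. = FALSE)
  normalized <- normalize_ratios(transformations, wt_records = wt)

  strains <- unique(transformations$strain)
  rows <- lapply(strains, function(st) {
    part <- partition_co_nco(events$stability_call[events$strain == st])
    cc <- class_counts[class_counts$strain == st, , drop = FALSE]
    data.frame(
      strain = st,
      repair_efficiency = mean(normalized$value[normalized$strain == st]),
      co_count = part$co_count, nco_count = part$nco_count,
      uni_count = if (nrow(cc)) cc$unidirectional else NA_integer_,
      bi_count = if (nrow(cc)) cc$bidirectional else NA_integer_,
      cleavage_count = if (nrow(cc)) cc$cleavage else 0L,
      stringsAsFactors = FALSE
    )
  })
  table <- build_efficiency_table(do.call(rbind, rows))
  list(
    classes = classes, class_counts = class_counts,
    normalized = normalized, table = table
  )
}
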