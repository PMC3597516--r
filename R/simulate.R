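#' Generator-side truth mechanisms
#'
#' The repair routes the simulator can draw. `SDSA` and the two bidirectional
#' routes (`DHJ_DISSOLUTION`, `DOUBLE_SDSA`) produce NCOs; `HJ_CLEAVAGE_NCO`
#' carries the diagnostic donor-side hDNA pattern; `HJ_CLEAVAGE_CO` yields a
#' crossover (its sequence is not simulated, matching an NCO-only sequencing
#' design); `CONVERSION_ONLY` and `NO_TRANSFER` are the undetectable classes.
#' The two bidirectional routes are observationally identical by construction
#' — the distinct truth labels exist so tests can document that
#' non-identifiability.
#'
#' @return Character vector of the seven mechanism labels.
#' @export
mechanisms <- function() {
  c(
    "SDSA", "DHJ_DISSOLUTION", "DOUBLE_SDSA", "HJ_CLEAVAGE_NCO",
    "HJ_CLEAVAGE_CO", "CONVERSION_ONLY", "NO_TRANSFER"
  )
}

#' Simulation parameters for event cohorts
#'
#' @param mechanism_weights Named nonnegative vector over [mechanisms()]
#'   (missing names get weight 0); normalised to sum 1. Default is WT-like:
#'   89% SDSA, 11% dissolution among detectable NCOs.
#' @param tract_mean Mean of the geometric tract-length model, in bp of hDNA
#'   extent beyond a gap edge (default 150). A SNP is covered iff its distance
#'   from the gap edge is at most the drawn length; lengths are drawn
#'   independently per involved side.
#' @param tract_min Minimum tract length in bp added to every geometric draw
#'   (default 0). Setting it to at least the nearest-SNP distance (18 on the
#'   default map) guarantees every involved side carries detectable hDNA.
#' @param n_events Number of events to simulate.
#' @param mmr_repair_prob Per-mismatch probability that mismatch repair
#'   restores a heteroduplex SNP before it can be detected (default 0,
#'   i.e. an MMR-deficient background).
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @return A `sim_params` list.
#' @export
sim_params <- function(mechanism_weights = c(SDSA = 0.89, DHJ_DISSOLUTION = 0.11),
                       tract_mean = 150, tract_min = 0L, n_events = 100L,
                       mmr_repair_prob = 0, seed = NULL) {
  w <- stats::setNames(numeric(length(mechanisms())), mechanisms())
  if (is.null(names(mechanism_weights)) ||
    !all(names(mechanism_weights) %in% mechanisms())) {
    stop("mechanism_weights must be named by mechanisms()", call. = FALSE)
  }
  w[names(mechanism_weights)] <- mechanism_weights
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  structure(list(
    mechanism_weights = w / sum(w), tract_mean = tract_mean,
    tract_min = as.integer(tract_min),
    n_events = as.integer(n_events), mmr_repair_prob = mmr_repair_prob,
    seed = seed
  ), class = "sim_params")
}

#' Draw hDNA tract lengths (bp beyond a gap edge)
#'
#' `tract_min` plus a geometric on \{0, 1, 2, ...\} whose mean is
#' `tract_mean - tract_min`, so overall `P(L >= k) = (1 - p)^(k - tract_min)`
#' for `k > tract_min`, with `p = 1/(tract_mean - tract_min + 1)`.
#' Monotone-decreasing tract lengths; the model is a configurable default,
#' not a biological claim.
#'
#' @param n Number of draws.
#' @param tract_mean Mean length in bp.
#' @param tract_min Minimum length in bp (< `tract_mean`).
#' @return Integer vector of lengths.
#' @export
draw_tract_length <- function(n, tract_mean = 150, tract_min = 0L) {
  stopifnot(tract_mean > tract_min)
  tract_min + stats::rgeom(n, prob = 1 / (tract_mean - tract_min + 1))
}

#' Probability that a tract reaches the nearest SNP
#'
#' Direct CDF evaluation of the geometric tract-length model: the chance that
#' a drawn length covers a SNP at the given edge distance. Used as the
#' independent enumeration route when checking detection-conditioned class
#' proportions.
#'
#' @param distance Edge distance in bp (18 for the default map's anchors).
#' @param tract_mean Mean tract length in bp.
#' @param tract_min Minimum tract length in bp.
#' @return `P(L >= distance)`.
#' @export
tract_detection_prob <- function(distance, tract_mean = 150, tract_min = 0L) {
  ifelse(distance <= tract_min, 1,
    stats::pgeom(distance - tract_min - 1,
      prob = 1 / (tract_mean - tract_min + 1),
      lower.tail = FALSE
    )
  )
}

# place H codes on one side: SNPs within `len` bp of the gap edge
.cover_side <- function(codes, side, len, map, mmr_repair_prob = 0) {
  hit <- snp_sides(map) == side & snp_edge_distance(map) <= len
  if (mmr_repair_prob > 0 && any(hit)) {
    hit[hit] <- stats::runif(sum(hit)) >= mmr_repair_prob
  }
  codes[hit] <- "H"
  codes
}

#' Simulate one gap-repair event
#'
#' Places hDNA according to the mechanism's predicted topology: SDSA gives
#' plasmid hDNA contiguous from the gap edge outward on exactly one
#' (uniformly chosen) annealing side; dissolution and double-SDSA give
#' plasmid hDNA on both sides with independent per-side extents; HJ cleavage
#' NCOs carry plasmid hDNA on one side and donor hDNA on the opposite side;
#' conversion-only events carry `D` codes; no-transfer events are all `R`.
#' SNPs are heteroduplex iff covered by the drawn tract interval, so a short
#' tract (< 18 bp on the default map) leaves the event undetectable.
#'
#' @param mechanism One of [mechanisms()].
#' @param map A `snp_map`.
#' @param params A [sim_params()] object (tract model and MMR setting).
#' @return An `event_record` list: `truth_mechanism`, `stability_call`
#'   (`"CO"` iff HJ cleavage resolved as crossover), and `plasmid` /
#'   `chromosome` allele calls (`NULL` for CO events, which are not
#'   sequenced).
#' @export
simulate_event <- function(mechanism, map = default_substrate(),
                           params = sim_params()) {
  if (!mechanism %in% mechanisms()) {
    stop("unknown mechanism: ", mechanism, call. = FALSE)
  }
  n <- length(map$snp_positions)
  blank <- rep("R", n)
  pl <- blank
  ch <- blank
  stability <- "NCO"
  tm <- params$tract_mean
  tmin <- if (is.null(params$tract_min)) 0L else params$tract_min
  mp <- params$mmr_repair_prob
  dlen <- function() draw_tract_length(1, tm, tmin)
  pick_side <- function() if (stats::runif(1) < 0.5) "LEFT" else "RIGHT"

  if (mechanism == "SDSA") {
    pl <- .cover_side(pl, pick_side(), dlen(), map, mp)
  } else if (mechanism %in% c("DHJ_DISSOLUTION", "DOUBLE_SDSA")) {
    pl <- .cover_side(pl, "LEFT", dlen(), map, mp)
    pl <- .cover_side(pl, "RIGHT", dlen(), map, mp)
  } else if (mechanism == "HJ_CLEAVAGE_NCO") {
    s <- pick_side()
    opp <- if (s == "LEFT") "RIGHT" else "LEFT"
    pl <- .cover_side(pl, s, dlen(), map, mp)
    ch <- .cover_side(ch, opp, dlen(), map, mp)
  } else if (mechanism == "HJ_CLEAVAGE_CO") {
    stability <- "CO"
  } else if (mechanism == "CONVERSION_ONLY") {
    hit <- snp_sides(map) == pick_side() &
      snp_edge_distance(map) <= dlen()
    pl[hit] <- "D"
  } # NO_TRANSFER: leave blank

  structure(list(
    truth_mechanism = mechanism, stability_call = stability,
    plasmid = if (stability == "NCO") allele_calls(pl, "PLASMID", map),
    chromosome = if (stability == "NCO") allele_calls(ch, "CHROMOSOME", map)
  ), class = "event_record")
}

#' Simulate a cohort of gap-repair events
#'
#' Mechanisms are drawn i.i.d. from `params$mechanism_weights`; output is
#' reproducible under a fixed `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param map A `snp_map`.
#' @param strain Strain label attached to every event.
#' @return A data.frame with one row per event: `event_id`, `strain`,
#'   `truth_mechanism`, `stability_call`, `plasmid_calls` and
#'   `chromosome_calls` (gap-delimited code strings; `NA` for CO events).
#' @export
simulate_cohort <- function(params, map = default_substrate(), strain = "sim") {
  if (!is.null(params$seed)) set.seed(params$seed)
  mech <- sample(mechanisms(), params$n_events,
    replace = TRUE, prob = params$mechanism_weights
  )
  recs <- lapply(mech, simulate_event, map = map, params = params)
  data.frame(
    event_id = sprintf("%s_%05d", strain, seq_along(recs)),
    strain = strain,
    truth_mechanism = mech,
    stability_call = vapply(recs, `[[`, "", "stability_call"),
    plasmid_calls = vapply(recs, function(r) {
      if (is.null(r$plasmid)) NA_character_ else format_calls(r$plasmid, map)
    }, ""),
    chromosome_calls = vapply(recs, function(r) {
      if (is.null(r$chromosome)) NA_character_ else format_calls(r$chromosome, map)
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Parameters for simulated transformation counts
#'
#' @param n_transformations Number of independent transformations (the assay
#'   uses at least 12 per strain).
#' @param true_repair_efficiency Expected His+:Leu+ ratio before WT
#'   normalization.
#' @param leu_mean Mean Leu+ colony count per transformation.
#' @param dispersion Gamma-mixing dispersion of the shared culture
#'   transformation efficiency (variance of the multiplier = dispersion);
#'   0 gives pure Poisson counts.
#' @param mix_id Linear-plasmid mix identity, 1 or 2.
#' @param seed Integer seed; `NULL` for current RNG state.
#' @return A `transformation_sim_params` list.
#' @export
transformation_sim_params <- function(n_transformations = 12L,
                                      true_repair_efficiency = 1.0,
                                      leu_mean = 200, dispersion = 0.1,
                                      mix_id = 1L, seed = NULL) {
  stopifnot(
    n_transformations >= 1, true_repair_efficiency >= 0,
    leu_mean > 0, dispersion >= 0, mix_id %in% c(1L, 2L)
  )
  structure(list(
    n_transformations = as.integer(n_transformations),
    true_repair_efficiency = true_repair_efficiency,
    leu_mean = leu_mean, dispersion = dispersion,
    mix_id = as.integer(mix_id), seed = seed
  ), class = "transformation_sim_params")
}

#' Simulate per-transformation His+/Leu+ counts
#'
#' Leu+ counts are Poisson around `leu_mean` (zeros redrawn — a
#' transformation with no transformants is not a data point). Each culture's
#' realised repair efficiency is `true_repair_efficiency` times a
#' gamma-distributed multiplier (mean 1, variance `dispersion`), and His+
#' counts are Poisson around that efficiency times the observed Leu+ count —
#' a gamma-mixed, negative-binomial-like model giving overdispersed
#' His+:Leu+ ratios centred on `true_repair_efficiency`. With
#' `dispersion = 0` the ratio variance collapses to the Poisson sampling
#' floor (approximately `true_repair_efficiency / leu_mean`).
#'
#' @param params A [transformation_sim_params()] object.
#' @param strain Strain label.
#' @return A data.frame: `strain`, `mix_id`, `his_count`, `leu_count`.
#' @export
simulate_transformation_counts <- function(params, strain = "sim") {
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_transformations
  mult <- if (params$dispersion > 0) {
    shape <- 1 / params$dispersion
    stats::rgamma(n, shape = shape, rate = shape)
  } else {
    rep(1, n)
  }
  leu <- stats::rpois(n, params$leu_mean)
  for (i in which(leu == 0L)) {
    while (leu[i] == 0L) leu[i] <- stats::rpois(1, params$leu_mean)
  }
  his <- stats::rpois(n, params$true_repair_efficiency * mult * leu)
  data.frame(
    strain = strain, mix_id = params$mix_id,
    his_count = his, leu_count = leu, stringsAsFactors = FALSE
  )
}
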