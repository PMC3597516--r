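#' Write a pipeline TSV with a provenance header
#'
#' All interchange files are tab-separated with a header row, preceded by
#' `#`-prefixed provenance comments (tool version, timestamp-free config
#' echo, seed where applicable) so a file is traceable to the run that
#' produced it.
#'
#' @param x Data.frame to write.
#' @param path Output path.
#' @param provenance Named character vector folded into `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("gaphdna"))
  writeLines(sprintf("# gaphdna %s", ver), con)
  for (k in names(provenance)) {
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  }
  utils::write.table(x, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a pipeline TSV, skipping provenance comments
#'
#' @param path Input path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path,
    sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
}

#' Render a text tract map of classified NCO events
#'
#' A plain-text analogue of a published-figure tract map: one line per
#' hDNA-bearing NCO event, one column per SNP in position order with a `|`
#' column at the gap. Glyphs: `.` recipient base, `o` converted SNP, `#`
#' heteroduplex SNP. Events are sorted by class (unidirectional first, then
#' bidirectional, then the rest), then by leftmost hDNA position, then by
#' event id — a deterministic ordering under re-runs.
#'
#' @param events Cohort data.frame (see [simulate_cohort()]).
#' @param classes Per-event classes as returned in
#'   `analyze_cohort()$classes`.
#' @param map The `snp_map` the call strings refer to.
#' @return Character vector of lines, one per rendered event, named by
#'   `"<class> <event_id>"`.
#' @export
render_tract_map <- function(events, classes, map = default_substrate()) {
  m <- merge(events, classes, by = c("event_id", "strain"))
  keep <- m$class %in% c("UNIDIRECTIONAL", "BIDIRECTIONAL", "CLEAVAGE_PATTERN")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(character())
  }
  sides <- snp_sides(map)
  glyph <- c(R = ".", D = "o", H = "#")
  lines <- character(nrow(m))
  first_h <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    codes <- allele_calls(m$plasmid_calls[i], "PLASMID", map)$codes
    g <- glyph[codes]
    lines[i] <- paste0(
      paste(g[sides == "LEFT"], collapse = ""), "|",
      paste(g[sides == "RIGHT"], collapse = "")
    )
    h <- which(codes == "H")
    first_h[i] <- if (length(h)) h[1] else length(codes) + 1L
  }
  class_rank <- match(
    m$class, c("UNIDIRECTIONAL", "BIDIRECTIONAL", "CLEAVAGE_PATTERN")
  )
  ord <- order(class_rank, first_h, m$event_id)
  stats::setNames(lines[ord], paste(m$class[ord], m$event_id[ord]))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort and transformation
#' counts), `analyze` (run the full pipeline on cohort files and write the
#' efficiency table, per-event classes and class counts) and `render` (text
#' tract map). Invoke from a shell wrapper as
#' `Rscript -e 'quit(status = gaphdna::gaphdna_main())'` with arguments, or
#' pass `args` directly. Exit codes: 0 ok, 2 usage/configuration error.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
gaphdna_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: gaphdna <simulate|analyze|render> [options]",
    "  simulate --out-dir DIR [--seed INT] [--n-events INT] [--strain LABEL]",
    "  analyze  --events FILE --transformations FILE --out-dir DIR [--wt LABEL]",
    "  render   --events FILE --classes FILE [--out FILE]",
    sep = "\n"
  )
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) {
      return(default)
    }
    if (i == length(args)) stop("missing value for ", flag, call. = FALSE)
    args[i + 1L]
  }
  run <- function() {
    if (length(args) == 0L) stop(usage, call. = FALSE)
    cmd <- args[1]
    if (cmd == "simulate") {
      out_dir <- opt("--out-dir")
      if (is.null(out_dir)) stop(usage, call. = FALSE)
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      seed <- as.integer(opt("--seed", "1"))
      n <- as.integer(opt("--n-events", "250"))
      strain <- opt("--strain", "WT")
      map <- default_substrate()
      cohort <- simulate_cohort(
        sim_params(n_events = n, seed = seed),
        map, strain = strain
      )
      tr <- simulate_transformation_counts(
        transformation_sim_params(n_transformations = 12L, seed = seed + 1L),
        strain = strain
      )
      prov <- c(seed = as.character(seed), strain = strain)
      write_tsv(cohort, file.path(out_dir, "events.tsv"), prov)
      write_tsv(tr, file.path(out_dir, "transformations.tsv"), prov)
    } else if (cmd == "analyze") {
      ev_path <- opt("--events")
      tr_path <- opt("--transformations")
      out_dir <- opt("--out-dir")
      if (is.null(ev_path) || is.null(tr_path) || is.null(out_dir)) {
        stop(usage, call. = FALSE)
      }
      events <- read_tsv(ev_path)
      if (nrow(events) == 0L) stop("empty events file", call. = FALSE)
      res <- analyze_cohort(events, read_tsv(tr_path),
        wt_strain = opt("--wt", "WT")
      )
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(res$classes, file.path(out_dir, "classes.tsv"))
      write_tsv(res$class_counts, file.path(out_dir, "class_counts.tsv"))
      write_tsv(res$table, file.path(out_dir, "efficiency_table.tsv"))
    } else if (cmd == "render") {
      ev_path <- opt("--events")
      cl_path <- opt("--classes")
      if (is.null(ev_path) || is.null(cl_path)) stop(usage, call. = FALSE)
      lines <- render_tract_map(read_tsv(ev_path), read_tsv(cl_path))
      out <- opt("--out")
      txt <- paste(names(lines), lines, sep = "\t")
      if (is.null(out)) cat(txt, sep = "\n") else writeLines(txt, out)
    } else {
      stop(usage, call. = FALSE)
    }
  }
  status <- tryCatch(
    {
      run()
      0L
    },
    error = function(e) {
      message(conditionMessage(e))
      2L
    }
  )
  invisible(status)
}
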