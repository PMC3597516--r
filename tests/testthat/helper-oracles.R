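# Independent brute-force oracles used across the test files.

# Enumerate every (start, end) index pair and keep those that are all-H,
# single-side and maximal. Deliberately quadratic and structure-free, unlike
# the rle-based implementation it checks.
oracle_tracts <- function(codes, sides) {
  n <- length(codes)
  out <- NULL
  for (s in seq_len(n)) {
    for (e in s:n) {
      run <- s:e
      if (!all(codes[run] == "H")) next
      if (length(unique(sides[run])) != 1L) next
      left_ok <- s == 1L || codes[s - 1L] != "H" || sides[s - 1L] != sides[s]
      right_ok <- e == n || codes[e + 1L] != "H" || sides[e + 1L] != sides[e]
      if (left_ok && right_ok) {
        out <- rbind(out, data.frame(
          first_snp = s, last_snp = e, side = sides[s],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (is.null(out)) {
    data.frame(first_snp = integer(), last_snp = integer(), side = character())
  } else {
    out[order(out$first_snp), , drop = FALSE]
  }
}

# Exhaustive two-sided Fisher p from first principles: enumerate all tables
# with the observed margins, weight each by its choose()-product, and sum the
# weights of tables no more probable than the observed one.
oracle_fisher <- function(a1, a2, b1, b2) {
  m1 <- a1 + a2
  m2 <- b1 + b2
  k <- a1 + b1
  xs <- max(0, k - m2):min(k, m1)
  w <- exp(lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k))
  w_obs <- w[match(a1, xs)]
  min(sum(w[w <= w_obs * (1 + 1e-7)]), 1)
}

# Hand-written mechanism specification table over the 5 free transfer flags.
# Expressed via counts rather than the implementation's branch structure.
oracle_class_table <- function() {
  g <- expand.grid(
    pl = c(FALSE, TRUE), pr = c(FALSE, TRUE),
    cl = c(FALSE, TRUE), cr = c(FALSE, TRUE),
    conv = c(FALSE, TRUE)
  )
  g$expected <- apply(g, 1, function(r) {
    pl <- r[["pl"]]; pr <- r[["pr"]]; cl <- r[["cl"]]; cr <- r[["cr"]]
    n_pl <- pl + pr
    n_ch <- cl + cr
    if (n_pl == 0 && n_ch == 0) {
      if (r[["conv"]]) "CONVERSION_ONLY" else "NO_TRANSFER"
    } else if (n_pl == 2 && n_ch == 0) {
      "BIDIRECTIONAL"
    } else if (n_pl == 1 && n_ch == 0) {
      "UNIDIRECTIONAL"
    } else if (n_pl == 1 && n_ch == 1 && ((pl && cr) || (pr && cl))) {
      "CLEAVAGE_PATTERN"
    } else {
      "AMBIGUOUS"
    }
  })
  g
}

random_codes <- function(n, p_h = 0.3) {
  sample(c("R", "D", "H"), n,
    replace = TRUE,
    prob = c(1 - p_h - 0.1, 0.1, p_h)
  )
}

summary_from_flags <- function(pl, pr, cl, cr, conv) {
  s <- list(
    has_hdna_plasmid_left = pl, has_hdna_plasmid_right = pr,
    has_hdna_chromosome_left = cl, has_hdna_chromosome_right = cr,
    has_conversion = conv
  )
  s$any_transfer <- pl || pr || cl || cr || conv
  s
}
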