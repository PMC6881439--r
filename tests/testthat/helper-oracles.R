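# Independent oracles used across the suite. These are deliberately naive
# implementations that share no code with the package internals.

# Best global alignment score by exhaustive enumeration of every alignment
# path (diag / consume-a / consume-b), with affine gap bookkeeping carried
# along the path. Exponential; only for sequences of length <= ~7.
enum_align_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, "M", sc + S[av[i + 1], bv[j + 1]])
    if (i < n) rec(i + 1L, j, "X", sc - (if (last == "X") ge else go))
    if (j < m) rec(i, j + 1L, "Y", sc - (if (last == "Y") ge else go))
  }
  rec(0L, 0L, "", 0)
  best
}

# Studentized-range CDF by direct nested numerical integration over the
# scale factor s = sqrt(chi2_df / df) and the normal order statistics.
ptukey_quadrature <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      f <- function(z) k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
    }, numeric(1))
  }
  dens <- function(s) exp(df / 2 * log(df) + (df - 1) * log(s) -
                            df * s^2 / 2 - lgamma(df / 2) -
                            (df / 2 - 1) * log(2))
  stats::integrate(function(s) dens(s) * inner(s), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Naive reverse complement, independent of the package helper.
rc_naive <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Brute-force ungapped site scan: tests every window at every offset and
# applies the same merge rule by direct search over each overlap group.
brute_scan <- function(probe, molecule, max_mm, min_run) {
  k <- nchar(probe)
  n <- nchar(molecule)
  out <- list()
  for (orient in c("antisense_compatible", "sense_incompatible")) {
    pat <- if (orient == "antisense_compatible") rc_naive(probe) else probe
    pv <- strsplit(pat, "", fixed = TRUE)[[1]]
    cand <- list()
    if (n >= k) for (st in 1:(n - k + 1)) {
      wv <- strsplit(substring(molecule, st, st + k - 1), "", fixed = TRUE)[[1]]
      eq <- wv == pv
      mm <- sum(!eq)
      if (mm > max_mm) next
      r <- rle(eq)
      run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (run < min_run) next
      cand[[length(cand) + 1]] <- c(st = st, mm = mm, run = run)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    # group overlapping windows, keep min-mismatch (leftmost on ties)
    grp <- cumsum(c(TRUE, diff(cand[, "st"]) >= k))
    for (g in unique(grp)) {
      rows <- cand[grp == g, , drop = FALSE]
      best <- rows[which.min(rows[, "mm"]), ]
      out[[length(out) + 1]] <- data.frame(
        start = unname(best["st"]), mismatches = unname(best["mm"]),
        longest_perfect_run = unname(best["run"]), orientation = orient,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), mismatches = integer(0),
                      longest_perfect_run = integer(0),
                      orientation = character(0)))
  df <- do.call(rbind, out)
  df[order(df$orientation, df$start), ]
}
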