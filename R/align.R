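# Affine-gap global pairwise alignment (Gotoh), stretcher-style reporting.
#
# Ortholog comparison between human and zebrafish genes is done with global
# alignment under affine gap penalties, reporting Identity / Similarity /
# Gaps percentages over the alignment length in the convention of the
# EMBOSS pairwise alignment tools: identity counts equal residues,
# similarity counts columns whose substitution score is positive, gaps
# counts gap columns. A gap of length L costs open + (L - 1) * extend (the
# opening column carries the open penalty, each subsequent column the
# extension penalty). Tie-breaking in the traceback is deterministic:
# diagonal, then gap-in-b (consume a), then gap-in-a (consume b).

#' Build an ambiguity-aware nucleotide substitution matrix
#'
#' Match/mismatch scores are averaged over the IUPAC base sets of the two
#' codes, the same construction as the classic full DNA matrix (+5 match,
#' -4 mismatch by default).
#'
#' @param match,mismatch Scores for identical / different bases.
#' @return A symmetric numeric matrix over the 15 IUPAC codes.
#' @export
nucleotide_matrix <- function(match = 5, mismatch = -4) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  codes <- names(iupac)
  m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  for (x in codes) for (y in codes) {
    a <- iupac[[x]]; b <- iupac[[y]]
    hits <- sum(outer(a, b, "=="))
    m[x, y] <- (hits * match + (length(a) * length(b) - hits) * mismatch) /
      (length(a) * length(b))
  }
  m
}

#' Scoring scheme for global alignment
#'
#' Defaults mirror the EMBOSS stretcher web defaults: nucleotide mode uses
#' the full DNA matrix (+5/-4) with gap open 16 and extend 4; protein mode
#' uses BLOSUM62 with gap open 12 and extend 2. Penalties are positive
#' numbers (costs).
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param gap_open,gap_extend Gap penalties (costs, >= 0); mode-specific
#'   defaults when `NULL`.
#' @param matrix Substitution matrix; mode-specific default when `NULL`.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           gap_open = NULL, gap_extend = NULL, matrix = NULL) {
  mode <- match.arg(mode)
  if (is.null(gap_open)) gap_open <- if (mode == "nucleotide") 16 else 12
  if (is.null(gap_extend)) gap_extend <- if (mode == "nucleotide") 4 else 2
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (is.null(matrix)) {
    matrix <- if (mode == "nucleotide") nucleotide_matrix() else {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    }
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  structure(list(mode = mode, gap_open = gap_open, gap_extend = gap_extend,
                 matrix = matrix), class = "scoring_scheme")
}

#' Optimal global alignment with affine gap penalties
#'
#' Quadratic-space Gotoh algorithm. The score of a gap of length L is
#' `-(gap_open + (L - 1) * gap_extend)`. Ambiguity codes score via the
#' matrix and are never errors.
#'
#' @param a,b Sequences (character scalars), non-empty, over the scheme's
#'   alphabet.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gap character `-`), `score`, `length` (columns), `identity_count`,
#'   `similarity_count`, `gap_count`, `identity_pct`, `similarity_pct`,
#'   `gaps_pct`.
#' @examples
#' global_align("ACGT", "ACGT")$identity_pct
#' @export
global_align <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (scheme$mode == "nucleotide") { a <- chartr("U", "T", a); b <- chartr("U", "T", b) }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  alpha <- rownames(scheme$matrix)
  if (any(!av %in% alpha) || any(!bv %in% alpha))
    stop("sequence contains characters outside the ", scheme$mode,
         " alphabet")
  n <- length(av); m <- length(bv)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  S <- scheme$matrix
  NEG <- -1e18
  # M: a[i] aligned to b[j]; X: gap in b (a[i] consumed); Y: gap in a.
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(go + (i - 2) * ge)
  for (j in 2:(m + 1)) Y[1, j] <- -(go + (j - 2) * ge)
  # traceback pointers: which predecessor state fed each cell (1=M,2=X,3=Y)
  ptM <- matrix(0L, n + 1, m + 1); ptX <- matrix(0L, n + 1, m + 1)
  ptY <- matrix(0L, n + 1, m + 1)
  ptX[2:(n + 1), 1] <- 2L; ptX[2, 1] <- 1L
  ptY[1, 2:(m + 1)] <- 3L; ptY[1, 2] <- 1L
  for (i in 2:(n + 1)) {
    srow <- S[av[i - 1], ]
    for (j in 2:(m + 1)) {
      sub <- srow[bv[j - 1]]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      w <- which.max(cand)          # ties: M, then X, then Y
      M[i, j] <- cand[w] + sub
      ptM[i, j] <- w
      cand <- c(M[i - 1, j] - go, X[i - 1, j] - ge, Y[i - 1, j] - go)
      w <- which.max(cand)
      X[i, j] <- cand[w]
      ptX[i, j] <- w
      cand <- c(M[i, j - 1] - go, X[i, j - 1] - go, Y[i, j - 1] - ge)
      w <- which.max(cand)
      Y[i, j] <- cand[w]
      ptY[i, j] <- w
    }
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  state <- which.max(finals)        # ties: diagonal, then up, then left
  score <- finals[state]
  # traceback
  ai <- character(0); bi <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    if (state == 1L) {
      ai <- c(av[i - 1], ai); bi <- c(bv[j - 1], bi)
      state <- ptM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ai <- c(av[i - 1], ai); bi <- c("-", bi)
      state <- ptX[i, j]; i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1], bi)
      state <- ptY[i, j]; j <- j - 1
    }
  }
  len <- length(ai)
  is_gap <- ai == "-" | bi == "-"
  ident <- sum(!is_gap & ai == bi)
  simil <- sum(!is_gap & S[cbind(match(ai, alpha), match(bi, alpha))] > 0,
               na.rm = TRUE)
  gaps <- sum(is_gap)
  structure(list(aligned_a = paste(ai, collapse = ""),
                 aligned_b = paste(bi, collapse = ""),
                 score = score, length = len,
                 identity_count = ident, similarity_count = simil,
                 gap_count = gaps,
                 identity_pct = 100 * ident / len,
                 similarity_pct = 100 * simil / len,
                 gaps_pct = 100 * gaps / len),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Length: %d\n", x$length))
  cat(sprintf("Identity:   %6d/%d (%.1f%%)\n", x$identity_count, x$length,
              x$identity_pct))
  cat(sprintf("Similarity: %6d/%d (%.1f%%)\n", x$similarity_count, x$length,
              x$similarity_pct))
  cat(sprintf("Gaps:       %6d/%d (%.1f%%)\n", x$gap_count, x$length,
              x$gaps_pct))
  cat(sprintf("Score: %g\n", x$score))
  invisible(x)
}

#' Ortholog similarity table
#'
#' Aligns each nucleotide pair and each protein pair globally and reports
#' similarity (and identity/gaps) percentages with 1-decimal formatting,
#' one row per label, in input order.
#'
#' @param pairs A data frame with columns `label`, `nt_a`, `nt_b`,
#'   `prot_a`, `prot_b` (sequences; the protein columns may be `NA` to skip
#'   protein alignment, and vice versa).
#' @param nt_scheme,prot_scheme Scoring schemes.
#' @return A data frame with columns `label`, `nt_identity_pct`,
#'   `nt_similarity_pct`, `nt_gaps_pct`, `prot_identity_pct`,
#'   `prot_similarity_pct`, `prot_gaps_pct` (rounded to 1 decimal).
#' @export
similarity_table <- function(pairs,
                             nt_scheme = scoring_scheme("nucleotide"),
                             prot_scheme = scoring_scheme("protein")) {
  stopifnot(is.data.frame(pairs), "label" %in% names(pairs))
  one <- function(sa, sb, scheme) {
    if (is.na(sa) || is.na(sb)) return(rep(NA_real_, 3))
    r <- global_align(sa, sb, scheme)
    round(c(r$identity_pct, r$similarity_pct, r$gaps_pct), 1)
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    nt <- one(pairs$nt_a[i], pairs$nt_b[i], nt_scheme)
    pr <- one(pairs$prot_a[i], pairs$prot_b[i], prot_scheme)
    data.frame(label = pairs$label[i],
               nt_identity_pct = nt[1], nt_similarity_pct = nt[2],
               nt_gaps_pct = nt[3],
               prot_identity_pct = pr[1], prot_similarity_pct = pr[2],
               prot_gaps_pct = pr[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
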