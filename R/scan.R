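# Candidate binding-site scanning.
#
# The published screen BLASTed each morpholino against the transcriptome;
# here the candidate search is an exhaustive ungapped scan, which dominates
# any BLAST parameterization (every window of every molecule is tested).
# A window is a candidate when the reverse complement of the probe aligns
# with at most `max_mismatches` mismatches and the longest perfectly
# complementary run is at least `min_perfect_run` (orientation
# "antisense_compatible"); windows where the probe itself matches the
# molecule are reported as "sense_incompatible" and feed rule 2 of the
# decision tree. Hybridization is not gapped in practice, so no indels are
# considered.

#' Scan settings for candidate-site search
#'
#' @param max_mismatches Maximum mismatches in the probe-length window
#'   (default 5).
#' @param min_perfect_run Minimum length of the longest perfectly
#'   complementary run (default 12).
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(max_mismatches = 5L, min_perfect_run = 12L) {
  stopifnot(max_mismatches >= 0, min_perfect_run >= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_perfect_run = as.integer(min_perfect_run)),
            class = "scan_params")
}

# Ungapped matches of `pattern` in `subject`: windows with <= max_mm
# mismatches. Returns a data frame with start, mismatches,
# longest_perfect_run; overlapping candidate windows are merged keeping the
# fewest-mismatch placement (ties: leftmost).
scan_pattern <- function(pattern, subject, max_mm, min_run) {
  p <- if (is.integer(pattern)) pattern else utf8ToInt(pattern)
  s <- if (is.integer(subject)) subject else utf8ToInt(subject)
  k <- length(p)
  n <- length(s)
  if (k > n)
    return(data.frame(start = integer(0), mismatches = integer(0),
                      longest_perfect_run = integer(0)))
  nw <- n - k + 1L
  mm <- integer(nw)
  for (j in seq_len(k))
    mm <- mm + (s[j:(j + nw - 1L)] != p[j])
  cand <- which(mm <= max_mm)
  if (length(cand) == 0L)
    return(data.frame(start = integer(0), mismatches = integer(0),
                      longest_perfect_run = integer(0)))
  runs <- vapply(cand, function(st)
    longest_run(s[st:(st + k - 1L)] == p), integer(1))
  keep <- runs >= min_run
  cand <- cand[keep]; runs <- runs[keep]; mmc <- mm[cand]
  if (length(cand) == 0L)
    return(data.frame(start = integer(0), mismatches = integer(0),
                      longest_perfect_run = integer(0)))
  # merge overlapping windows: group candidates whose windows overlap, keep
  # the fewest-mismatch placement (leftmost on ties)
  grp <- cumsum(c(TRUE, diff(cand) >= k))
  sel <- unlist(lapply(split(seq_along(cand), grp), function(ix) {
    ix[which.min(mmc[ix])]
  }), use.names = FALSE)
  data.frame(start = cand[sel], mismatches = mmc[sel],
             longest_perfect_run = runs[sel])
}

#' Scan one molecule for candidate morpholino binding sites
#'
#' Reports every window of `molecule_seq` where the reverse complement of
#' the probe aligns ungapped within the scan thresholds (orientation
#' `antisense_compatible`), plus windows where the probe sequence itself
#' matches (`sense_incompatible`). A probe longer than the molecule yields
#' zero sites, not an error.
#'
#' @param probe_seq Probe sequence (DNA sense, typically 25 nt).
#' @param molecule_seq Molecule sequence in transcript orientation.
#' @param params [scan_params()].
#' @return Data frame with columns `start`, `end` (1-based inclusive on the
#'   molecule), `orientation`, `matched_length`, `mismatches`,
#'   `longest_perfect_run`.
#' @export
scan_sites <- function(probe_seq, molecule_seq, params = scan_params()) {
  scan_both(utf8ToInt(probe_seq), utf8ToInt(revcomp(probe_seq)),
            utf8ToInt(molecule_seq), params)
}

# Workhorse behind scan_sites, on pre-encoded integer vectors so repeated
# scans of the same molecule do not re-encode it.
scan_both <- function(p_int, p_rc_int, s_int, params) {
  res <- list()
  for (orient in c("antisense_compatible", "sense_incompatible")) {
    pat <- if (orient == "antisense_compatible") p_rc_int else p_int
    hits <- scan_pattern(pat, s_int, params$max_mismatches,
                         params$min_perfect_run)
    if (nrow(hits)) {
      hits$orientation <- orient
      res[[orient]] <- hits
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      orientation = character(0), matched_length = integer(0),
                      mismatches = integer(0),
                      longest_perfect_run = integer(0)))
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  k <- length(p_int)
  data.frame(start = df$start, end = df$start + k - 1L,
             orientation = df$orientation, matched_length = k,
             mismatches = df$mismatches,
             longest_perfect_run = df$longest_perfect_run,
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(probe_id = character(0), gene_id = character(0),
             transcript_id = character(0), molecule = character(0),
             start = integer(0), end = integer(0), orientation = character(0),
             matched_length = integer(0), mismatches = integer(0),
             longest_perfect_run = integer(0), tm_celsius = numeric(0),
             contig = character(0), gstart = integer(0), gend = integer(0),
             stringsAsFactors = FALSE)
}

#' Find candidate binding sites for a set of probes across a genome
#'
#' Runs [scan_sites()] for every probe against the mature and pre-mRNA
#' molecule of every transcript, and against each contig (both match
#' senses) so that candidate sites outside annotated genes are found too.
#' Hits with identical genomic footprints are de-duplicated in favour of
#' mature > pre-mRNA > contig-level records (per transcript); contig-level
#' hits falling entirely inside a gene span are delegated to the molecule
#' scans. The duplex Tm of each site is computed from the molecule
#' subsequence with the per-mismatch penalty.
#'
#' @param probes Probe data frame with columns `id`, `sequence` (25-mers)
#'   and optionally `intended_gene`, `mechanism`; see [make_probes()].
#' @param genome Genome as in [build_molecules()].
#' @param annotation Feature data frame from [read_gff3()].
#' @param params [scan_params()].
#' @param tm_params [tm_parameters()].
#' @param molecules Optional precomputed [build_molecules()] result.
#' @return A site data frame, one row per candidate site, with molecule
#'   coordinates, orientation, mismatch count, longest perfect run, duplex
#'   Tm and the genomic footprint (`contig`, `gstart`, `gend`).
#' @export
find_binding_sites <- function(probes, genome, annotation,
                               params = scan_params(),
                               tm_params = tm_parameters(),
                               molecules = NULL) {
  seqs <- as_named_seqs(genome)
  if (is.null(molecules)) molecules <- build_molecules(annotation, genome)
  genes <- annotation[annotation$ftype == "gene", , drop = FALSE]
  mol_int <- lapply(molecules, function(m)
    list(mature = utf8ToInt(m$mature), pre_mRNA = utf8ToInt(m$pre_mrna)))
  ctg_int <- lapply(seqs, utf8ToInt)
  rows <- list()
  for (pi in seq_len(nrow(probes))) {
    p_id <- probes$id[pi]
    p_seq <- toupper(probes$sequence[pi])
    p_int <- utf8ToInt(p_seq)
    p_rc_int <- utf8ToInt(revcomp(p_seq))
    # transcript molecules
    for (model in molecules) {
      for (mol in c("mature", "pre_mRNA")) {
        mseq <- if (mol == "mature") model$mature else model$pre_mrna
        map <- if (mol == "mature") model$mature_map else model$pre_map
        hits <- scan_both(p_int, p_rc_int,
                          mol_int[[model$transcript_id]][[mol]], params)
        if (nrow(hits) == 0) next
        hits$probe_id <- p_id
        hits$gene_id <- model$gene_id
        hits$transcript_id <- model$transcript_id
        hits$molecule <- mol
        hits$contig <- model$contig
        gpos <- lapply(seq_len(nrow(hits)),
                       function(r) map[hits$start[r]:hits$end[r]])
        hits$gstart <- vapply(gpos, min, integer(1))
        hits$gend <- vapply(gpos, max, integer(1))
        hits$tm_celsius <- vapply(seq_len(nrow(hits)), function(r) {
          frag <- substring(mseq, hits$start[r], hits$end[r])
          duplex_tm(frag, mismatches = hits$mismatches[r], params = tm_params)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- hits
      }
    }
    # contig-level scan (sites outside annotated genes, or straddling)
    for (ctg in names(seqs)) {
      hits <- scan_both(p_int, p_rc_int, ctg_int[[ctg]], params)
      if (nrow(hits) == 0) next
      g_on_ctg <- genes[genes$contig == ctg, , drop = FALSE]
      inside <- vapply(seq_len(nrow(hits)), function(r) {
        any(hits$start[r] >= g_on_ctg$start & hits$end[r] <= g_on_ctg$end)
      }, logical(1))
      hits <- hits[!inside, , drop = FALSE]
      if (nrow(hits) == 0) next
      ov_gene <- vapply(seq_len(nrow(hits)), function(r) {
        ov <- which(hits$end[r] >= g_on_ctg$start & hits$start[r] <= g_on_ctg$end)
        if (length(ov)) g_on_ctg$id[ov[1]] else NA_character_
      }, character(1))
      hits$probe_id <- p_id
      hits$gene_id <- ov_gene
      hits$transcript_id <- NA_character_
      hits$molecule <- "genome"
      hits$contig <- ctg
      hits$gstart <- hits$start
      hits$gend <- hits$end
      hits$tm_celsius <- vapply(seq_len(nrow(hits)), function(r) {
        frag <- substring(seqs[[ctg]], hits$start[r], hits$end[r])
        duplex_tm(frag, mismatches = hits$mismatches[r], params = tm_params)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (length(rows) == 0L) return(empty_sites())
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  sites <- sites[, names(empty_sites())]
  # de-duplicate identical genomic footprints: mature > pre_mRNA > genome,
  # kept separately per transcript (isoforms are consolidated later)
  prio <- match(sites$molecule, c("mature", "pre_mRNA", "genome"))
  key <- paste(sites$probe_id, sites$contig, sites$gstart, sites$gend,
               ifelse(is.na(sites$transcript_id), "", sites$transcript_id))
  ord <- order(key, prio)
  sites <- sites[ord, , drop = FALSE]
  sites <- sites[!duplicated(key[ord]), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
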