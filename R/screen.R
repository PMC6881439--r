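# The five-rule off-target decision tree.
#
# Candidate sites pass through four ordered rules (the fifth "rule" being
# the candidate search itself):
#   1. only hits inside a named gene are examined;
#   2. the probe and the RNA must be in antisense-compatible orientation;
#   3. the binding position must be able to act like a morpholino:
#      translation blocking (5'UTR or the window of `start_window_nt`
#      beginning at the annotated start codon) or splice blocking (across an
#      exon-intron junction, within `intron_edge_nt` of an intron end, or
#      within `exon_edge_nt` of an exon end adjacent to an intron);
#   4. a duplex Tm below `tm_threshold_celsius` may still exclude the hit
#      (Tm exactly at threshold is retained: the rule excludes strictly
#      below).
# Every rule is evaluated for every site (evaluation is total, so reports
# show the full trail); the final status is the first failing rule.

FINAL_STATUSES <- c("excluded_step1", "excluded_step2", "excluded_step3",
                    "excludable_step4", "confirmed_offtarget")

#' Screening thresholds
#'
#' Defaults follow the published screen: a 25 nt window downstream of the
#' start codon, 5 nt intron-edge and 2 nt exon-edge windows, and a 70 degC
#' duplex-Tm retention threshold.
#'
#' @param start_window_nt Width of the translation-blocking window starting
#'   at the A of the start codon (default 25).
#' @param intron_edge_nt Splice window at each intron end (default 5).
#' @param exon_edge_nt Splice window at each exon end adjacent to an intron
#'   (default 2).
#' @param tm_threshold_celsius Minimum duplex Tm retained at rule 4
#'   (default 70).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(start_window_nt = 25L, intron_edge_nt = 5L,
                          exon_edge_nt = 2L, tm_threshold_celsius = 70) {
  stopifnot(start_window_nt >= 0, intron_edge_nt >= 0, exon_edge_nt >= 0)
  structure(list(start_window_nt = as.integer(start_window_nt),
                 intron_edge_nt = as.integer(intron_edge_nt),
                 exon_edge_nt = as.integer(exon_edge_nt),
                 tm_threshold_celsius = as.numeric(tm_threshold_celsius)),
            class = "screen_config")
}

#' Rule 1: does the site fall within a named gene?
#'
#' True iff the site's genomic footprint overlaps at least one `gene`
#' feature carrying a `Name` (or, as fallback, an `ID`) attribute. Any
#' overlap counts, including sites straddling a gene boundary. An empty
#' annotation yields `FALSE`.
#'
#' @param site One-row site data frame (see [find_binding_sites()]).
#' @param annotation Feature data frame.
#' @return Logical scalar.
#' @export
step1_named_gene <- function(site, annotation) {
  genes <- annotation[annotation$ftype == "gene", , drop = FALSE]
  if (nrow(genes) == 0) return(FALSE)
  named <- !is.na(genes$name) | !is.na(genes$id)
  genes <- genes[named, , drop = FALSE]
  any(genes$contig == site$contig &
        genes$start <= site$gend & genes$end >= site$gstart)
}

#' Rule 2: is the binding orientation compatible with the RNA?
#'
#' @param site One-row site data frame.
#' @return `TRUE` iff the site orientation is `antisense_compatible`.
#' @export
step2_orientation <- function(site) {
  identical(site$orientation, "antisense_compatible")
}

# Classify one site against one set of mechanism windows (genomic position
# sets from mechanism_windows()). Translation takes precedence.
classify_mechanism <- function(gpos, win) {
  translation <- length(win$translation) > 0 && any(gpos %in% win$translation)
  splice <- FALSE
  if (!is.null(win$junction_pairs) && nrow(win$junction_pairs) > 0)
    splice <- any(apply(win$junction_pairs, 1,
                        function(pr) all(pr %in% gpos)))
  if (!splice)
    splice <- any(gpos %in% win$intron_edges) || any(gpos %in% win$exon_edges)
  if (translation) "translation_blocking" else if (splice) "splice_blocking"
  else "none"
}

#' Rule 3: can the site act like a morpholino?
#'
#' Classifies a site as `translation_blocking` (overlap with the 5'UTR or
#' the start-codon window, on the mature transcript), `splice_blocking`
#' (spanning an exon-intron junction or overlapping the intron/exon edge
#' windows on the pre-mRNA), or `none`. Translation takes precedence when
#' both hold. For a transcript without CDS annotation only the splice test
#' is applied, with a warning.
#'
#' @param site One-row site data frame.
#' @param molecules [build_molecules()] result.
#' @param config [screen_config()].
#' @return One of `"translation_blocking"`, `"splice_blocking"`, `"none"`.
#' @export
step3_mechanism <- function(site, molecules, config = screen_config()) {
  models <- relevant_models(site, molecules)
  if (length(models) == 0) return("none")
  best <- "none"
  for (model in models) {
    if (is.na(model$cds_start_mature))
      warning("transcript '", model$transcript_id,
              "' has no CDS annotation; translation blocking not evaluable")
    gpos <- site_genomic_positions(site, model)
    mech <- classify_mechanism(gpos, mechanism_windows(model, config))
    if (mech == "translation_blocking") return(mech)
    if (mech == "splice_blocking") best <- mech
  }
  best
}

# Transcript models a site must be classified against: its own transcript
# for molecule-scoped sites; every transcript of any overlapped gene for
# contig-level sites.
relevant_models <- function(site, molecules) {
  if (!is.na(site$transcript_id))
    return(molecules[site$transcript_id])
  Filter(function(m) m$contig == site$contig &&
           min(m$pre_map) <= site$gend && max(m$pre_map) >= site$gstart,
         molecules)
}

# Genomic positions covered by a site. Mature-molecule sites spanning an
# exon-exon junction cover a discontiguous position set.
site_genomic_positions <- function(site, model = NULL) {
  if (site$molecule == "genome" || is.null(model))
    return(site$gstart:site$gend)
  map <- if (site$molecule == "mature") model$mature_map else model$pre_map
  map[site$start:site$end]
}

#' Rule 4: duplex Tm retention
#'
#' @param site One-row site data frame with `tm_celsius` set.
#' @param config [screen_config()].
#' @return `TRUE` (retained) iff `tm_celsius >= tm_threshold_celsius`.
#' @export
step4_tm <- function(site, config = screen_config()) {
  site$tm_celsius >= config$tm_threshold_celsius
}

#' Apply the decision tree to a set of candidate sites
#'
#' Evaluates rules 1-4 for every site (all rules are evaluated for the
#' report even after one fails) and assigns the final status: the first
#' failing rule, or `confirmed_offtarget` when rules 1-2 pass, rule 3 finds
#' a mechanism and rule 4 retains the Tm. Sites on a probe's intended
#' target gene are flagged `on_target = TRUE` and are reported separately,
#' never as off-targets.
#'
#' @param sites Site data frame from [find_binding_sites()].
#' @param annotation Feature data frame.
#' @param molecules [build_molecules()] result.
#' @param config [screen_config()].
#' @param probes Optional probe data frame with `id` and `intended_gene`,
#'   used to flag on-target hits.
#' @return A verdict data frame: the site columns plus `step1_named_gene`,
#'   `step2_orientation`, `step3_mechanism`, `step4_tm_retained`,
#'   `final_status`, `on_target`.
#' @export
screen_sites <- function(sites, annotation, molecules,
                         config = screen_config(), probes = NULL) {
  n <- nrow(sites)
  s1 <- logical(n); s2 <- logical(n); s3 <- character(n); s4 <- logical(n)
  final <- character(n)
  for (i in seq_len(n)) {
    site <- sites[i, , drop = FALSE]
    s1[i] <- step1_named_gene(site, annotation)
    s2[i] <- step2_orientation(site)
    s3[i] <- step3_mechanism(site, molecules, config)
    s4[i] <- step4_tm(site, config)
    final[i] <- if (!s1[i]) "excluded_step1"
      else if (!s2[i]) "excluded_step2"
      else if (s3[i] == "none") "excluded_step3"
      else if (!s4[i]) "excludable_step4"
      else "confirmed_offtarget"
  }
  out <- sites
  out$step1_named_gene <- s1
  out$step2_orientation <- s2
  out$step3_mechanism <- s3
  out$step4_tm_retained <- s4
  out$final_status <- final
  out$on_target <- logical(n)
  if (!is.null(probes) && n > 0) {
    intended <- probes$intended_gene[match(out$probe_id, probes$id)]
    out$on_target <- !is.na(out$gene_id) & !is.na(intended) &
      out$gene_id == intended
  }
  out
}

#' Consolidate multi-isoform verdicts to gene level
#'
#' When a gene has several transcripts, a site is classified per transcript;
#' the most severe verdict (confirmed_offtarget > excludable_step4 >
#' excluded_step3 > excluded_step2 > excluded_step1) is reported at the
#' gene level, which makes the screen conservative.
#'
#' @param verdicts Verdict data frame from [screen_sites()].
#' @return A verdict data frame with one row per (probe, gene footprint).
#' @export
consolidate_verdicts <- function(verdicts) {
  if (nrow(verdicts) == 0) return(verdicts)
  sev <- match(verdicts$final_status, FINAL_STATUSES)
  key <- paste(verdicts$probe_id, verdicts$contig, verdicts$gstart,
               verdicts$gend,
               ifelse(is.na(verdicts$gene_id), "", verdicts$gene_id))
  ord <- order(key, -sev)
  v <- verdicts[ord, , drop = FALSE]
  v <- v[!duplicated(key[ord]), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Per-probe summary of screening outcomes
#'
#' @param verdicts Verdict data frame from [screen_sites()].
#' @return A data frame of per-probe counts by `final_status` (off-target
#'   candidates only) plus an `on_target` count.
#' @export
screen_summary <- function(verdicts) {
  probes <- unique(verdicts$probe_id)
  off <- verdicts[!verdicts$on_target, , drop = FALSE]
  counts <- sapply(FINAL_STATUSES, function(st)
    vapply(probes, function(p)
      sum(off$probe_id == p & off$final_status == st), integer(1)))
  counts <- matrix(counts, nrow = length(probes),
                   dimnames = list(NULL, FINAL_STATUSES))
  data.frame(probe = probes, counts,
             on_target = vapply(probes, function(p)
               sum(verdicts$probe_id == p & verdicts$on_target), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the whole screen: scan, classify, report
#'
#' Convenience pipeline: builds molecules, finds candidate sites for all
#' probes, applies the decision tree and (optionally) writes the TSV report
#' and a JSON summary of per-probe counts by final status.
#'
#' @param probes Probe data frame (`id`, `sequence`, `intended_gene`).
#' @param genome Genome as in [build_molecules()].
#' @param annotation Feature data frame from [read_gff3()].
#' @param scan [scan_params()].
#' @param config [screen_config()].
#' @param tm_params [tm_parameters()].
#' @param report_path Optional TSV output path.
#' @param summary_path Optional JSON summary output path.
#' @return A list with `verdicts` (per-site data frame, off-target
#'   candidates and on-target hits flagged), `summary` (per-probe counts),
#'   and `n_confirmed` (number of confirmed off-target sites).
#' @export
run_screen <- function(probes, genome, annotation, scan = scan_params(),
                       config = screen_config(), tm_params = tm_parameters(),
                       report_path = NULL, summary_path = NULL) {
  molecules <- build_molecules(annotation, genome)
  sites <- find_binding_sites(probes, genome, annotation, params = scan,
                              tm_params = tm_params, molecules = molecules)
  verdicts <- screen_sites(sites, annotation, molecules, config = config,
                           probes = probes)
  summ <- screen_summary(verdicts)
  if (!is.null(report_path))
    write_screen_report(verdicts[!verdicts$on_target, , drop = FALSE],
                        report_path)
  if (!is.null(summary_path))
    jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA)
  n_confirmed <- sum(verdicts$final_status == "confirmed_offtarget" &
                       !verdicts$on_target)
  list(verdicts = verdicts, summary = summ, n_confirmed = n_confirmed)
}
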