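# Synthetic genomes, planted binding sites and readout tables.
#
# Every downstream stage of the pipeline is exercised on deterministic,
# seedable toy data: a multi-gene genome with 5'UTR/CDS/intron structure,
# morpholino probes with planted binding sites of every decision-tree truth
# class, and per-larva readout tables with configurable group effects. The
# generator is first-class, tested code: its ground-truth labels are the
# oracle for the screening decision tree.

TRUTH_CLASSES <- c("intergenic", "wrong_orientation", "translation_blocking",
                   "splice_blocking", "positional_null", "low_tm")
EXPECTED_FINAL <- c(intergenic = "excluded_step1",
                    wrong_orientation = "excluded_step2",
                    translation_blocking = "confirmed_offtarget",
                    splice_blocking = "confirmed_offtarget",
                    positional_null = "excluded_step3",
                    low_tm = "excludable_step4")

#' Simulation configuration
#'
#' Ranges are in nucleotides and sampled uniformly. The defaults give a toy
#' genome well under 100 kb with gene models large enough to host one
#' planted site of every truth class per gene.
#'
#' @param n_genes Number of genes (default 6; strands alternate so both are
#'   represented).
#' @param intron_length_range,exon_length_range,utr5_length_range,utr3_length_range,spacer_length_range
#'   Length ranges (nt).
#' @param n_exons_range Exons per gene (default 2-4).
#' @param n_planted_per_class Planted sites per truth class (default 5).
#' @param mismatch_range Mismatches introduced into a `low_tm` probe
#'   (default 2-4; the upper bound must stay at or below the scan's
#'   `max_mismatches`).
#' @param gc_range GC-content range of gene sequences (default 0.40-0.60).
#' @param probe_length Probe length (default 25).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6L,
                       intron_length_range = c(80L, 150L),
                       exon_length_range = c(120L, 250L),
                       utr5_length_range = c(30L, 60L),
                       utr3_length_range = c(20L, 40L),
                       spacer_length_range = c(200L, 400L),
                       n_exons_range = c(2L, 4L),
                       n_planted_per_class = 5L,
                       mismatch_range = c(2L, 4L),
                       gc_range = c(0.40, 0.60),
                       probe_length = 25L,
                       seed = 1L) {
  ranges <- list(intron_length_range, exon_length_range, utr5_length_range,
                 utr3_length_range, spacer_length_range, n_exons_range,
                 mismatch_range, gc_range)
  for (r in ranges)
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("all ranges must be non-empty, positive intervals")
  if (exon_length_range[2] < utr5_length_range[2] + probe_length + 15L)
    stop("exon_length_range too short: the first exon cannot host the ",
         "5'UTR plus a start-codon planting window")
  if (n_genes < 2L) stop("need at least 2 genes (both strands represented)")
  structure(list(n_genes = as.integer(n_genes),
                 intron_length_range = as.integer(intron_length_range),
                 exon_length_range = as.integer(exon_length_range),
                 utr5_length_range = as.integer(utr5_length_range),
                 utr3_length_range = as.integer(utr3_length_range),
                 spacer_length_range = as.integer(spacer_length_range),
                 n_exons_range = as.integer(n_exons_range),
                 n_planted_per_class = as.integer(n_planted_per_class),
                 mismatch_range = as.integer(mismatch_range),
                 gc_range = as.numeric(gc_range),
                 probe_length = as.integer(probe_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_dna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a toy annotated genome
#'
#' Each gene has a 5'UTR, at least two exons and one intron, a CDS starting
#' with ATG, canonical GT..AG intron dinucleotides (in transcript
#' orientation), and a short 3'UTR; strands alternate across genes; genes
#' are separated by intergenic spacers on a single contig.
#'
#' @param config [sim_config()].
#' @return A list with `genome` (a [read_fasta()]-style data frame, one
#'   contig) and `annotation` (a [read_gff3()]-style feature data frame).
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  contig_chars <- rand_dna(runif_int(1, config$spacer_length_range), 0.45)
  features <- list()
  add_feat <- function(ftype, start, end, strand, attrs) {
    features[[length(features) + 1L]] <<- list(
      ftype = ftype, start = start, end = end, strand = strand, attrs = attrs)
  }
  for (g in seq_len(config$n_genes)) {
    strand <- if (g %% 2 == 1) "+" else "-"
    gc <- stats::runif(1, config$gc_range[1], config$gc_range[2])
    n_ex <- runif_int(1, config$n_exons_range)
    u5 <- runif_int(1, config$utr5_length_range)
    u3 <- runif_int(1, config$utr3_length_range)
    ex_len <- runif_int(n_ex, config$exon_length_range)
    # first exon must host the 5'UTR, the start codon and a planting window
    min_e1 <- u5 + config$probe_length + 15L
    if (ex_len[1] < min_e1)
      ex_len[1] <- runif_int(1, c(min_e1, max(min_e1,
                                              config$exon_length_range[2])))
    if (ex_len[n_ex] < u3 + 12L) ex_len[n_ex] <- u3 + 12L
    in_len <- runif_int(n_ex - 1L, config$intron_length_range)
    mature_len <- sum(ex_len)
    cds_start <- u5 + 1L
    cds_end <- mature_len - u3
    cds_len <- cds_end - cds_start + 1L
    # keep the CDS length a codon multiple by shrinking the 3'UTR boundary
    cds_end <- cds_end - (cds_len %% 3L)
    if (cds_end - cds_start + 1L < 30L)
      stop("ranges incompatible: CDS shorter than 30 nt in gene ", g)

    # transcript-orientation pre-mRNA layout
    pre_len <- sum(ex_len) + sum(in_len)
    pre <- rand_dna(pre_len, gc)
    ex_start_pre <- integer(n_ex); ex_end_pre <- integer(n_ex)
    pos <- 1L
    for (j in seq_len(n_ex)) {
      ex_start_pre[j] <- pos
      ex_end_pre[j] <- pos + ex_len[j] - 1L
      pos <- ex_end_pre[j] + 1L
      if (j < n_ex) {
        pre[pos] <- "G"; pre[pos + 1L] <- "T"
        pre[pos + in_len[j] - 2L] <- "A"; pre[pos + in_len[j] - 1L] <- "G"
        pos <- pos + in_len[j]
      }
    }
    # start codon (mature coordinate == pre coordinate inside exon 1)
    pre[cds_start:(cds_start + 2L)] <- c("A", "T", "G")

    gstart <- length(contig_chars) + 1L
    gene_chars <- if (strand == "+") pre else
      rev(chartr("ACGT", "TGCA", pre))
    contig_chars <- c(contig_chars, gene_chars)
    gend <- length(contig_chars)
    contig_chars <- c(contig_chars,
                      rand_dna(runif_int(1, config$spacer_length_range), 0.45))

    to_genomic <- function(a, b) {
      if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
      else c(gstart + pre_len - b, gstart + pre_len - a)
    }
    gid <- sprintf("gene%02d", g)
    tid <- sprintf("tx%02d", g)
    add_feat("gene", gstart, gend, strand,
             c(ID = gid, Name = sprintf("hps%02d", g)))
    add_feat("mRNA", gstart, gend, strand,
             c(ID = tid, Parent = gid))
    # mature-coordinate intervals of each exon
    cum <- cumsum(c(0L, ex_len))
    for (j in seq_len(n_ex)) {
      gv <- to_genomic(ex_start_pre[j], ex_end_pre[j])
      add_feat("exon", gv[1], gv[2], strand,
               c(ID = sprintf("%s.e%d", tid, j), Parent = tid))
      m_lo <- cum[j] + 1L; m_hi <- cum[j + 1L]
      ov_lo <- max(m_lo, cds_start); ov_hi <- min(m_hi, cds_end)
      if (ov_lo <= ov_hi) {
        a <- ex_start_pre[j] + (ov_lo - m_lo)
        b <- ex_start_pre[j] + (ov_hi - m_lo)
        gv <- to_genomic(a, b)
        add_feat("CDS", gv[1], gv[2], strand,
                 c(ID = sprintf("%s.c%d", tid, j), Parent = tid))
      }
    }
    gv <- to_genomic(1L, u5)
    add_feat("five_prime_UTR", gv[1], gv[2], strand,
             c(ID = sprintf("%s.u5", tid), Parent = tid))
    if (cds_end < mature_len) {
      # 3'UTR lives in the last exon
      a <- ex_start_pre[n_ex] + (cds_end + 1L - (cum[n_ex] + 1L))
      gv <- to_genomic(a, ex_end_pre[n_ex])
      add_feat("three_prime_UTR", gv[1], gv[2], strand,
               c(ID = sprintf("%s.u3", tid), Parent = tid))
    }
  }
  ann <- do.call(rbind, lapply(features, function(f) {
    data.frame(contig = "chrS", source = "moscreen_sim", ftype = f$ftype,
               start = f$start, end = f$end, score = ".", strand = f$strand,
               phase = ".",
               id = if ("ID" %in% names(f$attrs)) f$attrs[["ID"]] else NA_character_,
               parent = if ("Parent" %in% names(f$attrs)) f$attrs[["Parent"]] else NA_character_,
               name = if ("Name" %in% names(f$attrs)) f$attrs[["Name"]] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  ann$attributes <- lapply(features, function(f) f$attrs)
  genome <- data.frame(id = "chrS", description = "synthetic toy contig",
                       sequence = paste(contig_chars, collapse = ""),
                       stringsAsFactors = FALSE)
  list(genome = genome, annotation = ann)
}

#' Plant probe binding sites of every truth class
#'
#' Chooses, for each truth class, `n_planted_per_class` placement windows
#' satisfying that class's definition, re-randomizes the free bases of
#' Tm-constrained windows until the perfect duplex melts in the 75-86 degC
#' band (start codons and GT..AG dinucleotides are held fixed), and derives
#' each probe from its window: the reverse complement of the window for
#' antisense classes, the window itself for `wrong_orientation`, and a
#' mutated reverse complement for `low_tm` (mismatches added until the
#' scan-level Tm drops below the 70 degC threshold). After planting, the
#' genome is re-scanned with every probe and the draw is rejected and
#' retried if any probe hits anything beyond its planted footprint, so the
#' ground truth is exact.
#'
#' @param genome,annotation Output of [generate_genome()].
#' @param config [sim_config()].
#' @param scan [scan_params()].
#' @param screen [screen_config()].
#' @param tm_params [tm_parameters()].
#' @param max_retries Rejection-sampling bound for the re-scan guard.
#' @return A list with `genome` (modified contig), `annotation` (unchanged),
#'   `probes` (data frame: `id`, `sequence`, `intended_gene`, `mechanism`,
#'   `injected_conc_uM`) and `truth` (data frame: `probe_id`, `truth_class`,
#'   `expected_final`, `gene_id`, `molecule`, `contig`, `gstart`, `gend`).
#' @export
plant_offtargets <- function(genome, annotation, config = sim_config(),
                             scan = scan_params(), screen = screen_config(),
                             tm_params = tm_parameters(), max_retries = 5L) {
  stopifnot(inherits(config, "sim_config"))
  last_err <- NULL
  for (attempt in seq_len(max_retries)) {
    set.seed(config$seed + 7919L * attempt)
    res <- try(plant_once(genome, annotation, config, scan, screen, tm_params),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      last_err <- attr(res, "condition")$message
      next
    }
    if (rescan_guard(res, annotation, scan, tm_params)) return(res)
    last_err <- "re-scan guard rejected the draw"
  }
  stop("planting failed after ", max_retries, " attempts (last: ",
       last_err, ")")
}

plant_once <- function(genome, annotation, config, scan, screen, tm_params) {
  chars <- strsplit(genome$sequence[1], "", fixed = TRUE)[[1]]
  contig <- genome$id[1]
  k <- config$probe_length
  genes <- annotation[annotation$ftype == "gene", , drop = FALSE]
  molecules <- build_molecules(annotation, genome)
  models <- molecules[order(names(molecules))]
  used <- matrix(numeric(0), ncol = 2)  # genomic intervals already claimed
  claim <- function(a, b) {
    if (nrow(used) && any(used[, 1] <= b + 30 & used[, 2] >= a - 30))
      return(FALSE)
    used <<- rbind(used, c(a, b)); TRUE
  }

  # Re-randomize free window bases until the perfect duplex Tm is in band.
  temper <- function(g_lo, g_hi, strand, fixed_genomic = integer(0)) {
    free <- setdiff(g_lo:g_hi, fixed_genomic)
    # the window is always freshly drawn (not just when out of band) so a
    # rejected planting round re-randomizes every planted sequence
    for (it in 1:200) {
      chars[free] <<- rand_dna(length(free), 0.55)
      w <- paste(chars[g_lo:g_hi], collapse = "")
      if (strand == "-") w <- revcomp(w)
      tm <- duplex_tm(w, params = tm_params)
      if (tm >= 75 && tm <= 86) return(w)
    }
    stop("could not temper window at ", g_lo)
  }

  probes <- list(); truth <- list()
  add <- function(id, seq, intended, mechanism, truth_class, gene_id,
                  molecule, g_lo, g_hi) {
    probes[[length(probes) + 1L]] <<- data.frame(
      id = id, sequence = seq, intended_gene = intended,
      mechanism = mechanism, injected_conc_uM = 100,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      probe_id = id, truth_class = truth_class,
      expected_final = EXPECTED_FINAL[[truth_class]],
      gene_id = gene_id, molecule = molecule,
      contig = contig, gstart = g_lo, gend = g_hi,
      stringsAsFactors = FALSE)
  }
  other_gene <- function(gid) {
    pool <- setdiff(genes$id, gid)
    pool[1L + (length(probes) %% length(pool))]
  }

  n_per <- config$n_planted_per_class
  for (class in TRUTH_CLASSES) {
    placed <- 0L; tries <- 0L
    while (placed < n_per) {
      tries <- tries + 1L
      if (tries > 500L)
        stop("no legal placement window for class '", class, "'")
      if (class == "intergenic") {
        # a window in a spacer, at least 30 nt from any gene
        lo <- sample.int(length(chars) - k + 1L, 1)
        hi <- lo + k - 1L
        near <- any(genes$start <= hi + 30L & genes$end >= lo - 30L)
        if (near || !claim(lo, hi)) next
        w <- paste(chars[lo:hi], collapse = "")
        id <- sprintf("mo_%s_%02d", class, placed + 1L)
        add(id, revcomp(w), genes$id[1], "ATG", class, NA_character_,
            "genome", lo, hi)
        placed <- placed + 1L
        next
      }
      model <- models[[1L + ((placed + tries) %% length(models))]]
      gid <- model$gene_id
      strand <- model$strand
      if (class == "translation_blocking") {
        # window inside the start-codon window, ATG itself preserved
        m_lo <- model$cds_start_mature + 3L
        m_hi <- m_lo + k - 1L
        if (m_hi > model$exon_lengths[1]) next  # must stay inside exon 1
        gv <- range(model$mature_map[m_lo:m_hi])
        if (!claim(gv[1], gv[2])) next
        w <- temper(gv[1], gv[2], strand)
        id <- sprintf("mo_%s_%02d", class, placed + 1L)
        add(id, revcomp(w), other_gene(gid), "ATG", class, gid,
            "mature", gv[1], gv[2])
        placed <- placed + 1L
      } else if (class %in% c("splice_blocking", "low_tm")) {
        # splice_blocking spans a donor junction (13 exon nt + 12 intron
        # nt, GT held fixed); low_tm spans an acceptor junction (12 intron
        # nt + 13 exon nt, AG held fixed) so both classes fit in one gene
        if (is.null(model$pre_introns)) next
        j <- 1L + (placed %% nrow(model$pre_introns))
        if (class == "splice_blocking") {
          a <- model$pre_introns[j, 1]           # first intron base (pre)
          p_lo <- a - 13L
          fixed_pre <- c(a, a + 1L)              # keep the GT donor
        } else {
          b <- model$pre_introns[j, 2]           # last intron base (pre)
          p_lo <- b - 11L
          fixed_pre <- c(b - 1L, b)              # keep the AG acceptor
        }
        p_hi <- p_lo + k - 1L
        if (p_lo < 1L || p_hi > length(model$pre_map)) next
        gv <- range(model$pre_map[p_lo:p_hi])
        if (!claim(gv[1], gv[2])) next
        w <- temper(gv[1], gv[2], strand,
                    fixed_genomic = model$pre_map[fixed_pre])
        id <- sprintf("mo_%s_%02d", class, placed + 1L)
        if (class == "splice_blocking") {
          add(id, revcomp(w), other_gene(gid), "splice", class, gid,
              "pre_mRNA", gv[1], gv[2])
        } else {
          probe <- mutate_to_low_tm(w, tm_params, screen$tm_threshold_celsius,
                                    config$mismatch_range)
          if (is.null(probe)) next
          add(id, probe, other_gene(gid), "splice", class, gid,
              "pre_mRNA", gv[1], gv[2])
        }
        placed <- placed + 1L
      } else if (class %in% c("positional_null", "wrong_orientation")) {
        # interior of exon 2: inside the gene, clear of the start window,
        # junction and edge windows; offset randomized so several classes
        # can share one exon
        ex2 <- model$pre_exons[2, ]
        margin <- max(screen$exon_edge_nt, 2L) + 3L
        span <- (ex2[2] - margin) - (ex2[1] + margin) + 1L
        if (span < k) next
        p_lo <- ex2[1] + margin + sample.int(span - k + 1L, 1) - 1L
        p_hi <- p_lo + k - 1L
        gv <- range(model$pre_map[p_lo:p_hi])
        if (!claim(gv[1], gv[2])) next
        id <- sprintf("mo_%s_%02d", class, placed + 1L)
        if (class == "positional_null") {
          w <- temper(gv[1], gv[2], strand)
          add(id, revcomp(w), other_gene(gid), "ATG", class, gid,
              "mature", gv[1], gv[2])
        } else {
          w <- paste(chars[gv[1]:gv[2]], collapse = "")
          if (strand == "-") w <- revcomp(w)
          add(id, w, other_gene(gid), "ATG", class, gid, "mature",
              gv[1], gv[2])
        }
        placed <- placed + 1L
      }
    }
  }
  probes <- do.call(rbind, probes)
  truth <- do.call(rbind, truth)
  genome$sequence[1] <- paste(chars, collapse = "")
  list(genome = genome, annotation = annotation, probes = probes,
       truth = truth)
}

# Introduce mismatches into the probe (positions 3, 6, 9, 12 of the probe,
# i.e. clustered toward one end so the perfect run stays >= 13 nt) until
# the scan-level Tm (perfect-window Tm minus the per-mismatch penalty)
# falls below the threshold. Returns NULL when the allowed mismatch budget
# cannot get there.
mutate_to_low_tm <- function(window_seq, tm_params, threshold, mismatch_range) {
  probe <- strsplit(revcomp(window_seq), "", fixed = TRUE)[[1]]
  base_tm <- duplex_tm(window_seq, params = tm_params)
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  m <- 0L
  for (p in c(3L, 6L, 9L, 12L)) {
    if (m >= mismatch_range[2]) break
    if (base_tm - tm_params$mismatch_penalty * m < threshold - 1 &&
        m >= mismatch_range[1]) break
    probe[p] <- rot[[probe[p]]]
    m <- m + 1L
  }
  if (base_tm - tm_params$mismatch_penalty * m >= threshold - 1) return(NULL)
  if (m < mismatch_range[1]) return(NULL)
  paste(probe, collapse = "")
}

# Every probe must hit exactly its planted footprint, nothing else.
rescan_guard <- function(res, annotation, scan, tm_params) {
  sites <- find_binding_sites(res$probes, res$genome, res$annotation,
                              params = scan, tm_params = tm_params)
  for (i in seq_len(nrow(res$truth))) {
    tr <- res$truth[i, ]
    hits <- sites[sites$probe_id == tr$probe_id, , drop = FALSE]
    if (nrow(hits) != 1L) return(FALSE)
    if (hits$gstart != tr$gstart || hits$gend != tr$gend) return(FALSE)
  }
  TRUE
}

#' One-call synthetic screening dataset
#'
#' [generate_genome()] followed by [plant_offtargets()].
#'
#' @param config [sim_config()].
#' @param ... Passed to [plant_offtargets()].
#' @return See [plant_offtargets()].
#' @export
simulate_screen_dataset <- function(config = sim_config(), ...) {
  gen <- generate_genome(config)
  plant_offtargets(gen$genome, gen$annotation, config, ...)
}

#' Group specifications emulating a knockdown experiment
#'
#' One control group plus four splice-knockdown groups whose true knockdown
#' fractions match the efficiencies a qPCR readout is expected to recover
#' (30%, 33%, 32% and 81%). Phenotype-score probabilities and MFI effects
#' are qualitative: severe groups shift mass toward P3/P4/dead and lose
#' fluorescence.
#'
#' @param n_larvae Larvae per group (default 30).
#' @param n_qpcr qPCR replicates per group and gene (default 6).
#' @return A data frame of group specifications for
#'   [generate_readout_tables()].
#' @export
default_group_specs <- function(n_larvae = 30L, n_qpcr = 6L) {
  data.frame(
    group = c("CTRL-MO", "HPS1_KD_i6e7", "HPS3_KD_e7i7", "HPS4_KD_e8i8",
              "HPS5_KD_e12i12"),
    gene = c(NA, "hps1", "hps3", "hps4", "hps5"),
    n = n_larvae, n_qpcr = n_qpcr,
    p1 = c(0.90, 0.20, 0.80, 0.70, 0.10),
    p2 = c(0.05, 0.30, 0.10, 0.10, 0.15),
    p3 = c(0.03, 0.25, 0.05, 0.05, 0.45),
    p4 = c(0.01, 0.15, 0.02, 0.05, 0.20),
    dead = c(0.01, 0.10, 0.03, 0.10, 0.10),
    mfi_mean = c(100, 60, 95, 95, 55),
    mfi_sd = c(15, 15, 15, 15, 15),
    knockdown = c(0, 0.30, 0.33, 0.32, 0.81),
    stringsAsFactors = FALSE)
}

#' Generate synthetic readout tables
#'
#' Produces per-larva phenotype scores (multinomial over P1-P4 and dead),
#' per-larva maximum fluorescence intensities (normal, truncated at 0), and
#' per-sample qPCR Ct values consistent with each group's true fold change
#' under the delta-delta-Ct model (reference gene Ct ~ N(15, sd); target Ct
#' offset by the group's true delta-Ct; measurement noise sd 0.25 cycles on
#' each channel).
#'
#' @param groups Group-spec data frame; see [default_group_specs()].
#' @param seed Integer seed.
#' @param ct_sd Per-channel Ct measurement noise, cycles (default 0.25).
#' @return A list of data frames: `phenotype` (`larva_id`, `group`, `score`,
#'   `timepoint_hpf`), `mfi` (`larva_id`, `group`, `mfi`), `qpcr`
#'   (`sample_id`, `group`, `gene`, `ct_target`, `ct_reference`).
#' @export
generate_readout_tables <- function(groups = default_group_specs(), seed = 1L,
                                    ct_sd = 0.25) {
  psum <- rowSums(groups[, c("p1", "p2", "p3", "p4", "dead")])
  if (any(abs(psum - 1) > 1e-8))
    stop("phenotype probabilities must sum to 1 (group '",
         groups$group[which(abs(psum - 1) > 1e-8)[1]], "')")
  set.seed(seed)
  scores <- c("P1", "P2", "P3", "P4", "dead")
  phen <- list(); mfi <- list(); qpcr <- list()
  # per-gene control delta-Ct baselines, shared by control and KD groups
  target_genes <- stats::na.omit(unique(groups$gene))
  base_dct <- stats::setNames(stats::runif(length(target_genes), 4, 8),
                              target_genes)
  ref_ct <- 15
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sc <- sample(scores, g$n, replace = TRUE,
                 prob = unlist(g[c("p1", "p2", "p3", "p4", "dead")]))
    phen[[i]] <- data.frame(
      larva_id = sprintf("%s_L%03d", g$group, seq_len(g$n)),
      group = g$group, score = sc, timepoint_hpf = 96,
      stringsAsFactors = FALSE)
    alive <- which(sc != "dead")
    vals <- vapply(alive, function(j) {
      repeat {
        v <- stats::rnorm(1, g$mfi_mean, g$mfi_sd)
        if (v >= 0) return(v)
      }
    }, numeric(1))
    mfi[[i]] <- data.frame(
      larva_id = sprintf("%s_L%03d", g$group, alive),
      group = g$group, mfi = vals, stringsAsFactors = FALSE)
    # qPCR: the control group is measured for every target gene
    q_genes <- if (is.na(g$gene)) target_genes else g$gene
    for (gene in q_genes) {
      fold <- if (is.na(g$gene)) 1 else 1 - g$knockdown
      dct <- base_dct[[gene]] - log2(fold)
      qpcr[[length(qpcr) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_S%02d", g$group, gene, seq_len(g$n_qpcr)),
        group = g$group, gene = gene,
        ct_target = ref_ct + dct + stats::rnorm(g$n_qpcr, 0, ct_sd),
        ct_reference = ref_ct + stats::rnorm(g$n_qpcr, 0, ct_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(phenotype = do.call(rbind, phen),
       mfi = do.call(rbind, mfi),
       qpcr = do.call(rbind, qpcr))
}
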