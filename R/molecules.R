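# Transcript models: mature and pre-mRNA molecules with coordinate maps.
#
# A morpholino can act on the mature mRNA (translation blocking) or on the
# unspliced pre-mRNA (splice blocking), so candidate-site scanning needs
# both molecules per transcript plus maps between molecule and genome
# coordinates. Molecule coordinates are 1-based in transcript orientation
# (position 1 is the transcript 5' end); maps are integer vectors giving the
# genomic position of every molecule position.

#' Build mature and pre-mRNA molecules for every transcript
#'
#' For each `mRNA` feature in the annotation, assembles the mature sequence
#' (exons concatenated in transcript orientation), the pre-mRNA sequence
#' (the gene span in transcript orientation), coordinate maps from molecule
#' to genome positions, and landmark coordinates (CDS start, 5'UTR length,
#' exon/intron boundaries) used by site classification.
#'
#' @param annotation Feature data frame from [read_gff3()].
#' @param genome Genome sequences: a [read_fasta()] data frame or a named
#'   character vector.
#' @return A named list (one element per transcript id) of transcript
#'   models; each model is a list with elements `transcript_id`, `gene_id`,
#'   `gene_name`, `contig`, `strand`, `mature`, `pre_mrna`, `mature_map`,
#'   `pre_map`, `cds_start_mature`, `utr5_length`, `exon_lengths`,
#'   `pre_exons`, `pre_introns`.
#' @export
build_molecules <- function(annotation, genome) {
  seqs <- as_named_seqs(genome)
  tx <- annotation[annotation$ftype == "mRNA", , drop = FALSE]
  genes <- annotation[annotation$ftype == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tx))) {
    t_id <- tx$id[i]
    strand <- tx$strand[i]
    contig <- tx$contig[i]
    if (!contig %in% names(seqs))
      stop("contig '", contig, "' of transcript '", t_id, "' not in genome")
    gi <- match(tx$parent[i], genes$id)
    if (is.na(gi)) stop("transcript '", t_id, "' has no parent gene feature")
    gene <- genes[gi, ]
    exons <- annotation[annotation$ftype == "exon" &
                          !is.na(annotation$parent) &
                          annotation$parent == t_id, , drop = FALSE]
    if (nrow(exons) == 0) stop("transcript '", t_id, "' has no exons")
    exons <- exons[order(exons$start), , drop = FALSE]
    if (any(exons$end[-nrow(exons)] >= exons$start[-1]))
      stop("overlapping exons in transcript '", t_id, "'")
    if (min(exons$start) < gene$start || max(exons$end) > gene$end)
      stop("exon outside gene span in transcript '", t_id, "'")
    contig_seq <- seqs[[contig]]

    # Genomic positions of the pre-mRNA (gene span) and mature (exon bases),
    # both listed 5'->3' in transcript orientation.
    pre_map <- gene$start:gene$end
    mature_map <- unlist(lapply(seq_len(nrow(exons)),
                                function(j) exons$start[j]:exons$end[j]))
    if (strand == "-") {
      pre_map <- rev(pre_map)
      mature_map <- rev(mature_map)
    }
    base_at <- function(map) {
      s <- paste(strsplit(contig_seq, "", fixed = TRUE)[[1]][sort(unique(map))],
                 collapse = "")
      s
    }
    extract <- function(map) {
      fwd <- substring(contig_seq, min(map), max(map))
      chs <- strsplit(fwd, "", fixed = TRUE)[[1]]
      sel <- chs[map - min(map) + 1L]
      s <- paste(sel, collapse = "")
      if (strand == "-") chartr("ACGT", "TGCA", s) else s
    }
    pre_seq <- extract(pre_map)
    mature_seq <- extract(mature_map)

    # Landmarks. CDS features may be absent (non-coding fixture): warn later
    # at classification time, not here.
    cds <- annotation[annotation$ftype == "CDS" & !is.na(annotation$parent) &
                        annotation$parent == t_id, , drop = FALSE]
    cds_start_mature <- NA_integer_
    if (nrow(cds) > 0) {
      cds_start_genomic <- if (strand == "+") min(cds$start) else max(cds$end)
      cds_start_mature <- match(cds_start_genomic, mature_map)
      if (is.na(cds_start_mature))
        stop("CDS start of '", t_id, "' is not inside an exon")
      codon <- substring(mature_seq, cds_start_mature, cds_start_mature + 2L)
      if (!is.na(codon) && nchar(codon) == 3L && codon != "ATG")
        warning("CDS of transcript '", t_id, "' does not start with ATG (",
                codon, ")")
    }
    utr5_length <- if (is.na(cds_start_mature)) 0L else cds_start_mature - 1L

    # Exon/intron intervals in pre-mRNA coordinates (transcript orientation).
    exon_iv <- t(vapply(seq_len(nrow(exons)), function(j) {
      range(match(c(exons$start[j], exons$end[j]), pre_map))
    }, integer(2)))
    exon_iv <- exon_iv[order(exon_iv[, 1]), , drop = FALSE]
    intron_iv <- NULL
    if (nrow(exon_iv) > 1)
      intron_iv <- cbind(exon_iv[-nrow(exon_iv), 2] + 1L,
                         exon_iv[-1, 1] - 1L)
    out[[t_id]] <- list(
      transcript_id = t_id,
      gene_id = gene$id,
      gene_name = if (!is.na(gene$name)) gene$name else gene$id,
      contig = contig, strand = strand,
      mature = mature_seq, pre_mrna = pre_seq,
      mature_map = mature_map, pre_map = pre_map,
      cds_start_mature = cds_start_mature,
      utr5_length = utr5_length,
      exon_lengths = exons$end - exons$start + 1L,
      pre_exons = exon_iv, pre_introns = intron_iv)
  }
  out
}

# Genomic position sets for the mechanism windows of one transcript model,
# under a given screen_config. Used by the classification step; computing
# the windows in genomic coordinates makes the same test apply uniformly to
# mature, pre-mRNA and contig-level sites.
mechanism_windows <- function(model, config) {
  translation <- integer(0)
  if (!is.na(model$cds_start_mature)) {
    lo <- 1L
    hi <- min(length(model$mature_map),
              model$cds_start_mature + config$start_window_nt - 1L)
    if (config$start_window_nt == 0L) hi <- model$cds_start_mature - 1L
    if (hi >= lo) translation <- model$mature_map[lo:hi]
  }
  intron_edges <- integer(0)
  exon_edges <- integer(0)
  junction_pairs <- NULL
  if (!is.null(model$pre_introns) && nrow(model$pre_introns) > 0) {
    for (j in seq_len(nrow(model$pre_introns))) {
      a <- model$pre_introns[j, 1]; b <- model$pre_introns[j, 2]
      k <- min(config$intron_edge_nt, b - a + 1L)
      if (k > 0)
        intron_edges <- c(intron_edges,
                          model$pre_map[a:(a + k - 1L)],
                          model$pre_map[(b - k + 1L):b])
      # exon bases adjacent to this intron (donor-side exon end and
      # acceptor-side exon start, in transcript orientation)
      e <- config$exon_edge_nt
      if (e > 0) {
        don <- (a - e):(a - 1L)
        acc <- (b + 1L):(b + e)
        don <- don[don >= 1L]
        acc <- acc[acc <= length(model$pre_map)]
        exon_edges <- c(exon_edges, model$pre_map[don], model$pre_map[acc])
      }
      junction_pairs <- rbind(junction_pairs,
                              c(model$pre_map[a - 1L], model$pre_map[a]),
                              c(model$pre_map[b], model$pre_map[b + 1L]))
    }
  }
  list(translation = translation, intron_edges = intron_edges,
       exon_edges = exon_edges, junction_pairs = junction_pairs,
       has_cds = !is.na(model$cds_start_mature))
}
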