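# Hand-built miniature gene models with fully known coordinates, used where
# tests need exact expectations rather than generated data.

# One + strand gene on a 140 nt contig:
#   gene g1: 11..100; exon1 11..40 (5'UTR 11..16, ATG at 17), intron 41..70
#   (GT..AG), exon2 71..100; CDS 17..40 + 71..94; 3'UTR 95..100.
# The sequence is deterministic (seeded) with the landmark bases forced.
tiny_plus_fixture <- function() {
  set.seed(4711)
  chars <- sample(c("A", "C", "G", "T"), 140, replace = TRUE)
  chars[17:19] <- c("A", "T", "G")
  chars[41:42] <- c("G", "T")
  chars[69:70] <- c("A", "G")
  genome <- data.frame(id = "c1", description = "",
                       sequence = paste(chars, collapse = ""),
                       stringsAsFactors = FALSE)
  f <- function(ftype, start, end, id, parent = NA, name = NA) {
    attrs <- c(ID = id)
    if (!is.na(parent)) attrs <- c(attrs, Parent = parent)
    if (!is.na(name)) attrs <- c(attrs, Name = name)
    df <- data.frame(contig = "c1", source = "test", ftype = ftype,
                     start = start, end = end, score = ".", strand = "+",
                     phase = ".", id = id, parent = parent, name = name,
                     stringsAsFactors = FALSE)
    df$attributes <- list(attrs)
    df
  }
  annotation <- rbind(
    f("gene", 11, 100, "g1", name = "tinyA"),
    f("mRNA", 11, 100, "t1", parent = "g1"),
    f("exon", 11, 40, "t1.e1", parent = "t1"),
    f("exon", 71, 100, "t1.e2", parent = "t1"),
    f("CDS", 17, 40, "t1.c1", parent = "t1"),
    f("CDS", 71, 94, "t1.c2", parent = "t1"),
    f("five_prime_UTR", 11, 16, "t1.u5", parent = "t1"),
    f("three_prime_UTR", 95, 100, "t1.u3", parent = "t1"))
  list(genome = genome, annotation = annotation)
}

# Same layout mirrored onto the - strand: gene span 11..100 on the reverse
# strand, built by reverse-complementing the + strand fixture sequence
# between those coordinates and flipping feature strands.
tiny_minus_fixture <- function() {
  fx <- tiny_plus_fixture()
  chars <- strsplit(fx$genome$sequence, "", fixed = TRUE)[[1]]
  gene <- paste(chars[11:100], collapse = "")
  chars[11:100] <- rev(strsplit(chartr("ACGT", "TGCA", gene), "",
                                fixed = TRUE)[[1]])
  ann <- fx$annotation
  flip <- function(s, e) c(11 + 100 - e, 11 + 100 - s)
  for (i in seq_len(nrow(ann))) {
    v <- flip(ann$start[i], ann$end[i])
    ann$start[i] <- v[1]; ann$end[i] <- v[2]
  }
  ann$strand <- "-"
  fx$genome$sequence <- paste(chars, collapse = "")
  list(genome = fx$genome, annotation = ann)
}

# Two-isoform gene: isoform t1 splices out intron 41..70, isoform t2
# retains it (single exon). A site across the t1 donor junction is
# splice-blocking for t1 but positionally null for t2.
two_isoform_fixture <- function() {
  fx <- tiny_plus_fixture()
  ann <- fx$annotation
  f <- function(ftype, start, end, id, parent) {
    attrs <- c(ID = id, Parent = parent)
    df <- data.frame(contig = "c1", source = "test", ftype = ftype,
                     start = start, end = end, score = ".", strand = "+",
                     phase = ".", id = id, parent = parent,
                     name = NA_character_, stringsAsFactors = FALSE)
    df$attributes <- list(attrs)
    df
  }
  ann <- rbind(ann,
               f("mRNA", 11, 100, "t2", "g1"),
               f("exon", 11, 100, "t2.e1", "t2"),
               f("CDS", 17, 100, "t2.c1", "t2"))
  list(genome = fx$genome, annotation = ann)
}

# A small planted dataset shared by several test files (cached per session).
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_screen_dataset(sim_config(seed = 11,
                                                   n_planted_per_class = 3L))
    cache
  }
})
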