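# helpers to fabricate one-row site data frames for rule-level tests
make_site <- function(molecule, start, end, gstart, gend,
                      orientation = "antisense_compatible",
                      transcript_id = "t1", gene_id = "g1",
                      tm = 80, contig = "c1") {
  data.frame(probe_id = "p", gene_id = gene_id, transcript_id = transcript_id,
             molecule = molecule, start = start, end = end,
             orientation = orientation, matched_length = end - start + 1L,
             mismatches = 0L, longest_perfect_run = end - start + 1L,
             tm_celsius = tm, contig = contig, gstart = gstart, gend = gend,
             stringsAsFactors = FALSE)
}

test_that("rule 1: named-gene overlap, including boundary straddles", {
  fx <- tiny_plus_fixture()
  inside <- make_site("genome", 20, 44, 20, 44, transcript_id = NA)
  expect_true(step1_named_gene(inside, fx$annotation))
  intergenic <- make_site("genome", 102, 126, 102, 126, transcript_id = NA)
  expect_false(step1_named_gene(intergenic, fx$annotation))
  straddle <- make_site("genome", 95, 119, 95, 119, transcript_id = NA)
  expect_true(step1_named_gene(straddle, fx$annotation))
  expect_false(step1_named_gene(inside, fx$annotation[0, ]))
})

test_that("rule 2: only antisense-compatible sites pass", {
  expect_true(step2_orientation(make_site("mature", 1, 25, 11, 35)))
  expect_false(step2_orientation(
    make_site("mature", 1, 25, 11, 35, orientation = "sense_incompatible")))
})

test_that("rule 3 matches a hand-derived window oracle on every placement", {
  fx <- tiny_plus_fixture()
  mols <- build_molecules(fx$annotation, fx$genome)
  config <- screen_config()
  # hand-derived genomic window sets for the fixture layout:
  #   5'UTR 11..16; start window (25 nt from the ATG, transcript coords)
  #   covers genomic 17..40 plus 71; intron 41..70 edges 41..45 / 66..70;
  #   exon edges adjacent to the intron 39..40 / 71..72; junction pairs
  #   (40,41) and (70,71)
  translation <- c(11:16, 17:40, 71)
  splice_pos <- c(41:45, 66:70, 39:40, 71:72)
  pairs <- list(c(40, 41), c(70, 71))
  oracle <- function(gpos) {
    if (any(gpos %in% translation)) return("translation_blocking")
    if (any(vapply(pairs, function(p) all(p %in% gpos), logical(1))) ||
        any(gpos %in% splice_pos)) return("splice_blocking")
    "none"
  }
  maps <- list(mature = c(11:40, 71:100), pre_mRNA = 11:100)
  n_none <- 0; n_tr <- 0; n_sp <- 0
  for (mol in names(maps)) {
    map <- maps[[mol]]
    for (st in seq_len(length(map) - 24L)) {
      gpos <- map[st:(st + 24L)]
      site <- make_site(mol, st, st + 24L, min(gpos), max(gpos))
      got <- step3_mechanism(site, mols, config)
      exp <- oracle(gpos)
      expect_equal(got, exp,
                   info = sprintf("molecule %s, start %d", mol, st))
      if (exp == "none") n_none <- n_none + 1
      if (exp == "translation_blocking") n_tr <- n_tr + 1
      if (exp == "splice_blocking") n_sp <- n_sp + 1
    }
  }
  expect_true(n_none > 0 && n_tr > 0 && n_sp > 0)
})

test_that("rule 3 honours a zero-width start window (5'UTR only)", {
  fx <- tiny_plus_fixture()
  mols <- build_molecules(fx$annotation, fx$genome)
  config <- screen_config(start_window_nt = 0L)
  utr <- 11:16
  map <- c(11:40, 71:100)
  for (st in seq_len(length(map) - 24L)) {
    gpos <- map[st:(st + 24L)]
    site <- make_site("mature", st, st + 24L, min(gpos), max(gpos))
    got <- step3_mechanism(site, mols, config)
    if (got == "translation_blocking")
      expect_true(any(gpos %in% utr))
  }
})

test_that("rule 4: threshold is retained at exactly 70", {
  expect_true(step4_tm(make_site("mature", 1, 25, 11, 35, tm = 75.0)))
  expect_false(step4_tm(make_site("mature", 1, 25, 11, 35, tm = 69.99)))
  expect_true(step4_tm(make_site("mature", 1, 25, 11, 35, tm = 70.0)))
})

test_that("screening a planted genome recovers every ground-truth label", {
  ds <- shared_dataset()
  out <- run_screen(ds$probes, ds$genome, ds$annotation)
  v <- out$verdicts
  expect_equal(nrow(v), nrow(ds$truth))
  cmp <- merge(ds$truth, v[, c("probe_id", "gstart", "gend", "final_status")],
               by = "probe_id")
  expect_equal(cmp$final_status, cmp$expected_final)
  expect_equal(cmp$gstart.x, cmp$gstart.y)
  expect_equal(cmp$gend.x, cmp$gend.y)
})

test_that("verdicts are total, exhaustive and order-independent", {
  ds <- shared_dataset()
  mols <- build_molecules(ds$annotation, ds$genome)
  sites <- find_binding_sites(ds$probes, ds$genome, ds$annotation,
                              molecules = mols)
  v1 <- screen_sites(sites, ds$annotation, mols, probes = ds$probes)
  expect_equal(nrow(v1), nrow(sites))
  # all rule fields populated even after the failing step
  expect_false(anyNA(v1$step1_named_gene))
  expect_false(anyNA(v1$step2_orientation))
  expect_false(anyNA(v1$step3_mechanism))
  expect_false(anyNA(v1$step4_tm_retained))
  # permuting input permutes output only
  set.seed(9)
  perm <- sample(nrow(sites))
  v2 <- screen_sites(sites[perm, ], ds$annotation, mols, probes = ds$probes)
  rownames(v2) <- NULL
  v1p <- v1[perm, ]; rownames(v1p) <- NULL
  expect_equal(v2, v1p)
  # empty input: empty verdict set
  v0 <- screen_sites(sites[0, ], ds$annotation, mols)
  expect_equal(nrow(v0), 0L)
})

test_that("widening windows or lowering the Tm cut never loses confirmed hits", {
  ds <- shared_dataset()
  mols <- build_molecules(ds$annotation, ds$genome)
  sites <- find_binding_sites(ds$probes, ds$genome, ds$annotation,
                              molecules = mols)
  n_confirmed <- function(cfg) {
    v <- screen_sites(sites, ds$annotation, mols, config = cfg)
    sum(v$final_status == "confirmed_offtarget")
  }
  base <- n_confirmed(screen_config())
  expect_gte(n_confirmed(screen_config(start_window_nt = 40L)), base)
  expect_gte(n_confirmed(screen_config(intron_edge_nt = 10L)), base)
  expect_gte(n_confirmed(screen_config(exon_edge_nt = 6L)), base)
  expect_gte(n_confirmed(screen_config(tm_threshold_celsius = 60)), base)
})

test_that("multi-isoform sites take the most severe verdict at gene level", {
  fx <- two_isoform_fixture()
  mols <- build_molecules(fx$annotation, fx$genome)
  # window in the 3' end of t1's intron (genomic 46..70, overlapping the
  # 5 nt acceptor edge); for the intron-retaining isoform t2 the same
  # window is deep inside the single exon, past every mechanism window
  window <- substring(fx$genome$sequence, 46, 70)
  probes <- data.frame(id = "p1", sequence = rc_naive(window),
                       intended_gene = NA_character_,
                       stringsAsFactors = FALSE)
  sites <- find_binding_sites(probes, fx$genome, fx$annotation,
                              molecules = mols)
  expect_equal(sort(unique(sites$transcript_id)), c("t1", "t2"))
  v <- screen_sites(sites, fx$annotation, mols, probes = probes)
  v_t1 <- v[v$transcript_id == "t1", ]
  v_t2 <- v[v$transcript_id == "t2", ]
  expect_equal(v_t1$step3_mechanism, "splice_blocking")
  expect_equal(v_t2$step3_mechanism, "none")
  expect_equal(v_t2$final_status, "excluded_step3")
  cons <- consolidate_verdicts(v)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$transcript_id, "t1")  # the more severe verdict wins
})

test_that("on-target hits are flagged and excluded from off-target counts", {
  fx <- tiny_plus_fixture()
  mols <- build_molecules(fx$annotation, fx$genome)
  window <- substring(mols[["t1"]]$mature, 5, 29)   # over the start codon
  probes <- data.frame(id = "p1", sequence = rc_naive(window),
                       intended_gene = "g1", stringsAsFactors = FALSE)
  out <- run_screen(probes, fx$genome, fx$annotation)
  expect_true(all(out$verdicts$on_target))
  expect_equal(out$n_confirmed, 0L)
  expect_equal(out$summary$on_target, 1L)
})
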