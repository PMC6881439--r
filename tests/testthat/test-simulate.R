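test_that("genome generation is byte-deterministic in the seed", {
  g1 <- generate_genome(sim_config(seed = 1, n_genes = 3))
  g2 <- generate_genome(sim_config(seed = 1, n_genes = 3))
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$annotation$start, g2$annotation$start)
  g3 <- generate_genome(sim_config(seed = 2, n_genes = 3))
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("generated gene models satisfy the construction invariants", {
  for (seed in c(1, 7)) {
    gen <- generate_genome(sim_config(seed = seed))
    mols <- build_molecules(gen$annotation, gen$genome)
    expect_equal(length(mols), 6L)
    strands <- vapply(mols, `[[`, character(1), "strand")
    expect_setequal(unique(strands), c("+", "-"))
    for (m in mols) {
      # CDS begins ATG
      expect_equal(substring(m$mature, m$cds_start_mature,
                             m$cds_start_mature + 2L), "ATG")
      expect_gte(m$utr5_length, 1L)
      # >= 2 exons, >= 1 intron, canonical GT..AG
      expect_gte(nrow(m$pre_exons), 2L)
      expect_gte(nrow(m$pre_introns), 1L)
      for (j in seq_len(nrow(m$pre_introns))) {
        a <- m$pre_introns[j, 1]; b <- m$pre_introns[j, 2]
        expect_equal(substring(m$pre_mrna, a, a + 1L), "GT")
        expect_equal(substring(m$pre_mrna, b - 1L, b), "AG")
      }
    }
  }
})

test_that("range validation rejects impossible configurations", {
  expect_error(sim_config(exon_length_range = c(20L, 30L)),
               "exon_length_range too short")
  expect_error(sim_config(gc_range = c(0.6, 0.4)), "ranges")
  expect_error(sim_config(n_genes = 1L), "at least 2 genes")
})

test_that("planting is deterministic and labels every class", {
  ds1 <- simulate_screen_dataset(sim_config(seed = 3,
                                            n_planted_per_class = 2L))
  ds2 <- simulate_screen_dataset(sim_config(seed = 3,
                                            n_planted_per_class = 2L))
  expect_identical(ds1$genome$sequence, ds2$genome$sequence)
  expect_identical(ds1$probes, ds2$probes)
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(as.vector(table(ds1$truth$truth_class)),
               rep(2L, 6))
  expect_setequal(unique(ds1$truth$expected_final),
                  c("excluded_step1", "excluded_step2", "excluded_step3",
                    "excludable_step4", "confirmed_offtarget"))
  expect_true(all(nchar(ds1$probes$sequence) == 25L))
})

test_that("planted-site classes honour their defining constraints", {
  ds <- shared_dataset()
  mols <- build_molecules(ds$annotation, ds$genome)
  genes <- ds$annotation[ds$annotation$ftype == "gene", ]
  tmp <- tm_parameters()
  chars <- strsplit(ds$genome$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    ov <- genes$start <= tr$gend & genes$end >= tr$gstart
    if (tr$truth_class == "intergenic") {
      expect_false(any(ov))
    } else {
      expect_true(any(ov))
    }
    if (tr$truth_class == "translation_blocking") {
      # overlaps the 25 nt start-codon window on the mature transcript
      model <- Filter(function(m) m$gene_id == tr$gene_id, mols)[[1]]
      win <- model$mature_map[
        model$cds_start_mature:(model$cds_start_mature + 24L)]
      expect_true(any(tr$gstart:tr$gend %in% win))
    }
    if (tr$truth_class == "positional_null") {
      # overlaps neither start window, 5'UTR nor any junction window
      model <- Filter(function(m) m$gene_id == tr$gene_id, mols)[[1]]
      win <- moscreen:::mechanism_windows(model, screen_config())
      gpos <- tr$gstart:tr$gend
      expect_false(any(gpos %in% win$translation))
      expect_false(any(gpos %in% c(win$intron_edges, win$exon_edges)))
    }
    if (tr$truth_class == "low_tm") {
      # scan-level Tm of the planted site is below the threshold
      probe <- ds$probes$sequence[ds$probes$id == tr$probe_id]
      window <- paste(chars[tr$gstart:tr$gend], collapse = "")
      model <- Filter(function(m) m$gene_id == tr$gene_id, mols)[[1]]
      if (model$strand == "-") window <- rc_naive(window)
      mm <- sum(strsplit(window, "")[[1]] !=
                  strsplit(rc_naive(probe), "")[[1]])
      expect_gte(mm, 2L)
      expect_lt(duplex_tm(window, mismatches = mm, params = tmp), 70)
    }
  }
})

test_that("readout tables: degenerate distributions and determinism", {
  gs <- default_group_specs(n_larvae = 12L)
  gs[2:5, c("p1", "p2", "p3", "p4", "dead")] <-
    rep(c(1, 0, 0, 0, 0), each = 4)
  tabs <- generate_readout_tables(gs, seed = 5)
  sc <- tabs$phenotype$score[tabs$phenotype$group != "CTRL-MO"]
  expect_true(all(sc == "P1"))

  t1 <- generate_readout_tables(seed = 8)
  t2 <- generate_readout_tables(seed = 8)
  expect_identical(t1, t2)
  expect_true(all(t1$mfi$mfi >= 0))
  # dead larvae carry no MFI record
  dead <- t1$phenotype$larva_id[t1$phenotype$score == "dead"]
  expect_false(any(dead %in% t1$mfi$larva_id))

  bad <- default_group_specs()
  bad$p1[1] <- 0.5
  expect_error(generate_readout_tables(bad), "sum to 1")
})

test_that("knockdown efficiency is recovered from generated qPCR tables", {
  # single-seed spot check; the acceptance suite averages over 200 seeds
  est <- vapply(1:25, function(s) {
    tabs <- generate_readout_tables(seed = s)
    ke <- knockdown_efficiency(tabs$qpcr, "CTRL-MO")
    ke$efficiency_pct[ke$group == "HPS5_KD_e12i12"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 81), 3)
})
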