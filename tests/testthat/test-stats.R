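test_that("phenotype tabulation: counts, proportions, unknown tokens", {
  rec <- data.frame(group = rep("A", 10), score = rep("P1", 10))
  tab <- tabulate_phenotypes(rec)
  expect_equal(tab$prop_P1, 1)
  expect_equal(tab$n, 10L)

  set.seed(61)
  rec <- data.frame(
    group = rep(c("A", "B"), c(40, 60)),
    score = sample(c("P1", "P2", "P3", "P4", "dead"), 100, TRUE))
  tab <- tabulate_phenotypes(rec)
  props <- rowSums(tab[, paste0("prop_", c("P1", "P2", "P3", "P4", "dead"))])
  expect_equal(unname(props), c(1, 1))
  counts <- rowSums(tab[, c("P1", "P2", "P3", "P4", "dead")])
  expect_equal(unname(counts), c(40, 60))
  # counts match direct bookkeeping of the draws
  expect_equal(tab$P2[1], sum(rec$score[rec$group == "A"] == "P2"))

  rec$score[3] <- "P9"
  expect_error(tabulate_phenotypes(rec), "unknown score token 'P9' in row 3")
})

test_that("MFI extraction respects the mask", {
  img <- matrix(7, 5, 5)
  mask <- matrix(TRUE, 5, 5)
  expect_equal(max_fluorescence_intensity(img, mask), 7)
  img[3, 3] <- 200
  mask2 <- matrix(FALSE, 5, 5); mask2[3, 3] <- TRUE
  expect_equal(max_fluorescence_intensity(img, mask2), 200)
  # bright pixel outside the mask is ignored
  mask3 <- matrix(TRUE, 5, 5); mask3[3, 3] <- FALSE
  expect_equal(max_fluorescence_intensity(img, mask3), 7)
  expect_error(max_fluorescence_intensity(img, matrix(FALSE, 5, 5)),
               "empty mask")
})

test_that("one-way ANOVA: identities and error contracts", {
  set.seed(62)
  # identical groups: F = 0
  x <- rnorm(6)
  a <- anova_oneway(list(g1 = x, g2 = x, g3 = x))
  expect_equal(a$f, 0)
  # SS decomposition
  g <- list(a = rnorm(8), b = rnorm(5, 1), c = rnorm(6, 2))
  a <- anova_oneway(g)
  expect_equal(a$ss_between + a$ss_within, a$ss_total,
               tolerance = 1e-12)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 16L)
  # two groups: F = t^2, same p
  g <- list(a = rnorm(7), b = rnorm(9, 0.5))
  a <- anova_oneway(g)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  expect_error(anova_oneway(list(a = 1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(a = 1:3, b = 2)), "n >= 2")
})

test_that("Tukey HSD: degenerate case, tiers, and base-R cross-check", {
  x <- c(1.2, 0.8, 1.1, 0.9)
  tk <- tukey_hsd(list(a = x, b = x, c = x))
  expect_equal(tk$adjusted_p, rep(1, 3))
  expect_equal(tk$tier, rep("n.s.", 3))

  expect_equal(significance_tier(c(0.2, 0.05, 0.01, 0.001, 1e-4, 1e-6)),
               c("n.s.", "*", "**", "***", "****", "****"))
  # tiers are monotone in p
  p <- sort(stats::runif(50))
  lev <- factor(significance_tier(p),
                levels = c("****", "***", "**", "*", "n.s."))
  expect_true(all(diff(as.integer(lev)) >= 0))

  set.seed(63)
  d <- data.frame(group = rep(c("a", "b", "c"), c(6, 6, 6)),
                  value = c(rnorm(6), rnorm(6, 1), rnorm(6, -1)))
  tk <- tukey_hsd(d)
  th <- stats::TukeyHSD(stats::aov(value ~ group, d))$group
  expect_equal(sort(tk$adjusted_p), sort(unname(th[, "p adj"])),
               tolerance = 1e-10)
  expect_equal(sort(abs(tk$mean_difference)), sort(abs(unname(th[, "diff"]))),
               tolerance = 1e-12)
})

test_that("Tukey adjusted p matches the quadrature oracle", {
  set.seed(64)
  for (r in 1:4) {
    g <- list(a = rnorm(5), b = rnorm(6, 0.8), c = rnorm(5, -0.5))
    tk <- tukey_hsd(g)
    a <- anova_oneway(g)
    for (i in seq_len(nrow(tk))) {
      p_oracle <- 1 - ptukey_quadrature(tk$q_statistic[i], 3, a$df_within)
      expect_equal(tk$adjusted_p[i], p_oracle, tolerance = 1e-6)
    }
  }
})

test_that("delta-delta-Ct closed forms and invariances", {
  rec <- data.frame(
    group = rep(c("ctrl", "kd"), each = 3), gene = "hps5",
    ct_target = c(20, 20, 20, 21, 21, 21),
    ct_reference = c(15, 15, 15, 15, 15, 15))
  ke <- knockdown_efficiency(rec, "ctrl")
  expect_equal(ke$delta_delta_ct, 1)
  expect_equal(ke$fold_change, 0.5)
  expect_equal(ke$efficiency_pct, 50)

  rec$ct_target[4:6] <- 20   # ddCt = 0
  ke <- knockdown_efficiency(rec, "ctrl")
  expect_equal(ke$fold_change, 1)
  expect_equal(ke$efficiency_pct, 0)

  # invariance: adding a constant to every Ct leaves the fold unchanged
  set.seed(65)
  rec2 <- data.frame(group = rep(c("ctrl", "kd"), each = 5), gene = "g",
                     ct_target = rnorm(10, 22), ct_reference = rnorm(10, 15))
  k1 <- knockdown_efficiency(rec2, "ctrl")
  rec3 <- rec2
  rec3$ct_target <- rec3$ct_target + 3.7
  rec3$ct_reference <- rec3$ct_reference + 3.7
  k2 <- knockdown_efficiency(rec3, "ctrl")
  expect_equal(k1$fold_change, k2$fold_change, tolerance = 1e-12)
  # efficiency strictly decreasing in fold change
  folds <- seq(0.05, 1, by = 0.05)
  eff <- (1 - folds) * 100
  expect_true(all(diff(eff) < 0))

  expect_error(knockdown_efficiency(rec2, "nope"), "not present")
})
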