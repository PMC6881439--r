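# Quantitative readouts of a knockdown experiment: phenotype-score tables,
# maximum fluorescence intensity, one-way ANOVA + Tukey multiple
# comparisons with significance tiers, and delta-delta-Ct knockdown
# efficiency.

PHENOTYPE_SCORES <- c("P1", "P2", "P3", "P4", "dead")

#' Tabulate ordinal phenotype scores per group
#'
#' Larvae are graded from physiological appearance (P1) to the most severe
#' edema and pericardial effusion (P4); dead larvae are counted separately.
#'
#' @param records Data frame with columns `group` and `score` (one of
#'   P1, P2, P3, P4, dead).
#' @return A data frame with one row per group: `n`, counts `P1`..`dead`,
#'   and proportions `prop_P1`..`prop_dead` (summing to 1 per group).
#' @export
tabulate_phenotypes <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("group", "score") %in% names(records)))
  bad <- which(!records$score %in% PHENOTYPE_SCORES)
  if (length(bad))
    stop("unknown score token '", records$score[bad[1]], "' in row ", bad[1])
  groups <- unique(records$group)
  out <- lapply(groups, function(g) {
    sc <- records$score[records$group == g]
    counts <- vapply(PHENOTYPE_SCORES, function(s) sum(sc == s), integer(1))
    props <- counts / length(sc)
    df <- data.frame(group = g, n = length(sc), stringsAsFactors = FALSE)
    df[PHENOTYPE_SCORES] <- as.list(counts)
    df[paste0("prop_", PHENOTYPE_SCORES)] <- as.list(props)
    df
  })
  do.call(rbind, out)
}

#' Maximum fluorescence intensity within a region of interest
#'
#' The proteinuria readout: the maximum gray value of a fluorescence image
#' over a binary mask (the retinal vessel plexus), in arbitrary units.
#' Values outside the mask never influence the result.
#'
#' @param image Numeric matrix (grayscale).
#' @param roi Logical (or 0/1) matrix of the same shape; must select at
#'   least one pixel.
#' @return The maximum image value over mask-true positions.
#' @export
max_fluorescence_intensity <- function(image, roi) {
  stopifnot(is.matrix(image), is.matrix(roi),
            all(dim(image) == dim(roi)))
  roi <- roi != 0
  if (!any(roi)) stop("empty mask")
  max(image[roi])
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition, fitted via `lm`; p-value from
#' the F distribution.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each with
#'   n >= 2), or a data frame with columns `group` and `value`.
#' @return A list: `f`, `df_between`, `df_within`, `p`, `ss_between`,
#'   `ss_within`, `ss_total`, `ms_within`, `group_means`, `group_n`.
#' @export
anova_oneway <- function(groups) {
  d <- as_group_data(groups)
  if (length(unique(d$group)) < 2) stop("need at least 2 groups")
  n_per <- table(d$group)
  if (any(n_per < 2)) stop("every group needs n >= 2")
  fit <- stats::lm(value ~ group, data = d)
  an <- stats::anova(fit)
  list(f = an$`F value`[1],
       df_between = an$Df[1], df_within = an$Df[2],
       p = an$`Pr(>F)`[1],
       ss_between = an$`Sum Sq`[1], ss_within = an$`Sum Sq`[2],
       ss_total = sum((d$value - mean(d$value))^2),
       ms_within = an$`Mean Sq`[2],
       group_means = tapply(d$value, d$group, mean),
       group_n = as.integer(n_per))
}

as_group_data <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    d <- data.frame(group = as.character(groups$group),
                    value = as.numeric(groups$value),
                    stringsAsFactors = FALSE)
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    d <- data.frame(group = rep(names(groups), lengths(groups)),
                    value = unlist(groups, use.names = FALSE),
                    stringsAsFactors = FALSE)
  }
  d$group <- factor(d$group, levels = unique(d$group))
  d
}

#' Significance tier for an adjusted p-value
#'
#' The star convention: n.s. for p > 0.05, then `*` (<= 0.05), `**`
#' (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001).
#'
#' @param p Numeric vector of adjusted p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", "n.s."))))
}

#' Tukey's multiple comparisons test
#'
#' All pairwise comparisons after a one-way ANOVA. The Tukey-Kramer
#' studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))`
#' and the adjusted p comes from the studentized-range distribution with
#' the number of groups and the within-groups degrees of freedom.
#'
#' @inheritParams anova_oneway
#' @return A data frame, one row per pair: `group_a`, `group_b`,
#'   `mean_difference` (a minus b), `q_statistic`, `adjusted_p`, `tier`.
#' @export
tukey_hsd <- function(groups) {
  a <- anova_oneway(groups)
  means <- a$group_means
  ns <- a$group_n
  k <- length(means)
  labs <- names(means)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- means[[i]] - means[[j]]
    se <- sqrt(a$ms_within / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (se == 0) (if (diff == 0) 0 else Inf) else abs(diff) / se
    p <- 1 - stats::ptukey(q, nmeans = k, df = a$df_within)
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = labs[i], group_b = labs[j], mean_difference = diff,
      q_statistic = q, adjusted_p = p, tier = significance_tier(p),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Knockdown efficiency by delta-delta-Ct
#'
#' Per sample, `dCt = ct_target - ct_reference`; per gene and group,
#' `ddCt = mean dCt(group) - mean dCt(control)`; fold change `2^(-ddCt)`;
#' efficiency `(1 - fold change) * 100` percent. Equal amplification
#' efficiencies of target and reference are assumed.
#'
#' @param records Data frame with columns `group`, `gene`, `ct_target`,
#'   `ct_reference`.
#' @param control_group Name of the control group (must be present for
#'   every gene evaluated).
#' @return A data frame, one row per (gene, non-control group):
#'   `gene`, `group`, `n`, `delta_delta_ct`, `fold_change`,
#'   `efficiency_pct`.
#' @export
knockdown_efficiency <- function(records, control_group) {
  stopifnot(is.data.frame(records),
            all(c("group", "gene", "ct_target", "ct_reference") %in%
                  names(records)))
  if (!control_group %in% records$group)
    stop("control group '", control_group, "' not present")
  records$dct <- records$ct_target - records$ct_reference
  rows <- list()
  for (gene in unique(records$gene)) {
    rg <- records[records$gene == gene, , drop = FALSE]
    ctrl <- rg$dct[rg$group == control_group]
    if (length(ctrl) < 1)
      stop("control group '", control_group, "' has no replicates for gene '",
           gene, "'")
    for (g in setdiff(unique(rg$group), control_group)) {
      dct <- rg$dct[rg$group == g]
      ddct <- mean(dct) - mean(ctrl)
      fold <- 2^(-ddct)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = g, n = length(dct),
        delta_delta_ct = ddct, fold_change = fold,
        efficiency_pct = (1 - fold) * 100, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
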