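# Group-level analyses: burden comparisons, risk-allele frequencies,
# rare/fixed classification, frequency spectrum, selection test.

GROUPINGS <- c("super_population", "population", "sex")

# join a score_set with the panel and return data.frame(sample_id, group, score)
scores_by_group <- function(scores, panel, grouping) {
  stopifnot(inherits(scores, "score_set"), inherits(panel, "sample_panel"))
  grouping <- match.arg(grouping, GROUPINGS)
  idx <- match(names(scores$scores), panel$sample_id)
  if (anyNA(idx))
    analysis_error("score set contains samples absent from the panel")
  data.frame(sample_id = names(scores$scores),
             group = panel[[grouping]][idx],
             score = as.numeric(scores$scores),
             stringsAsFactors = FALSE)
}

#' Compare mean burden between groups
#'
#' Computes, for every group, the mean and sample standard deviation of
#' the burden score and -- for each non-reference group -- the mean
#' difference versus the reference group with a 95% confidence interval
#' and p-value from a two-sample t-test. Welch's unequal-variance test
#' is the default; a pooled-variance test is available behind
#' `var_equal = TRUE` for sensitivity analyses.
#'
#' @param scores a `score_set` (see [compute_grb()]).
#' @param panel a `sample_panel`.
#' @param grouping one of `"super_population"`, `"population"`, `"sex"`.
#' @param reference label of the reference group (e.g. `"EUR"`).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return a `data.frame` with one row per group: `group`, `n`, `mean`,
#'   `sd`, `mean_diff` (group minus reference), `ci_low`, `ci_high`,
#'   `p_value`. The reference row carries `mean_diff = 0` and `NA`
#'   CI/p. Groups with fewer than 2 non-missing scores are excluded
#'   with a warning.
#' @export
compare_grb_groups <- function(scores, panel,
                               grouping = c("super_population",
                                            "population", "sex"),
                               reference, var_equal = FALSE) {
  grouping <- match.arg(grouping)
  df <- scores_by_group(scores, panel, grouping)
  df <- df[!is.na(df$score) & !is.na(df$group), , drop = FALSE]
  groups <- split(df$score, df$group)
  if (!reference %in% names(groups))
    analysis_error(sprintf("reference group '%s' not present", reference))
  small <- names(groups)[lengths(groups) < 2L]
  if (reference %in% small)
    analysis_error(sprintf("reference group '%s' has fewer than 2 samples",
                           reference))
  if (length(small)) {
    warning(sprintf("compare_grb_groups: excluding group(s) with n < 2: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    groups <- groups[!names(groups) %in% small]
  }
  ref <- groups[[reference]]
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    base <- data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x),
                       stringsAsFactors = FALSE)
    if (g == reference) {
      cbind(base, mean_diff = 0, ci_low = NA_real_, ci_high = NA_real_,
            p_value = NA_real_)
    } else {
      tt <- t.test(x, ref, var.equal = var_equal, conf.level = 0.95)
      cbind(base, mean_diff = mean(x) - mean(ref),
            ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
            p_value = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  # reference row first, then groups in decreasing mean difference
  out <- out[order(out$group != reference, -out$mean_diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group risk-allele frequency table
#'
#' The risk-allele frequency (RAF) of a variant in a group is the mean
#' effect-allele dosage over the non-missing samples divided by 2,
#' i.e. (sum of dosages) / (2 x non-missing n). The RAF is unfolded:
#' it can exceed 0.5.
#'
#' @inheritParams compare_grb_groups
#' @param dosages a `dosage_matrix`.
#' @return a `data.frame` with columns `group`, `rsid`, `raf`,
#'   `n_chromosomes` (2 x non-missing samples). A variant entirely
#'   missing within a group gets `raf = NA` and `n_chromosomes = 0`.
#' @export
compute_group_raf <- function(dosages, panel,
                              grouping = c("super_population",
                                           "population", "sex")) {
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(panel, "sample_panel"))
  grouping <- match.arg(grouping)
  idx <- match(rownames(dosages), panel$sample_id)
  if (anyNA(idx))
    analysis_error("dosage matrix contains samples absent from the panel")
  glab <- panel[[grouping]][idx]
  rows <- lapply(sort(unique(glab)), function(g) {
    sub <- dosages[glab == g, , drop = FALSE]
    nobs <- colSums(!is.na(sub))
    tot  <- colSums(sub, na.rm = TRUE)
    data.frame(group = g, rsid = colnames(sub),
               raf = ifelse(nobs > 0, tot / (2 * nobs), NA_real_),
               n_chromosomes = 2L * nobs,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rare-variant proportions per group
#'
#' A variant is rare within a group iff its folded minor allele
#' frequency, `min(raf, 1 - raf)` computed in that group, is below
#' `maf_cut`. Per-group rare counts are compared against the reference
#' group with a two-sided Fisher exact test on the 2x2 rare/not-rare
#' table. Folding makes the classification invariant to globally
#' flipping effect and other alleles.
#'
#' @param freqs a frequency table from [compute_group_raf()].
#' @param maf_cut rare threshold on the folded MAF, in (0, 0.5);
#'   default 0.05.
#' @param reference reference group label.
#' @param annotations optional `variant_annotation`; when given, the
#'   frequency table is restricted to its rsids so the audited
#'   denominator matches the annotated panel.
#' @return a `data.frame` with per-group `n_rare`, `n_total`,
#'   `proportion` and `fisher_p` versus the reference (NA on the
#'   reference row). Variants with missing RAF are dropped from that
#'   group's denominator with a message.
#' @export
classify_rare <- function(freqs, maf_cut = 0.05, reference,
                          annotations = NULL) {
  if (!is.numeric(maf_cut) || maf_cut <= 0 || maf_cut >= 0.5)
    config_error("maf_cut must lie in (0, 0.5)")
  if (!is.null(annotations))
    freqs <- freqs[freqs$rsid %in% annotations$rsid, , drop = FALSE]
  if (!reference %in% freqs$group)
    analysis_error(sprintf("reference group '%s' not in frequency table",
                           reference))
  dropped <- sum(is.na(freqs$raf))
  if (dropped > 0)
    message(sprintf("classify_rare: dropping %d missing frequency cell(s)",
                    dropped))
  f <- freqs[!is.na(freqs$raf), , drop = FALSE]
  f$maf <- pmin(f$raf, 1 - f$raf)
  counts <- lapply(split(f, f$group), function(d)
    c(n_rare = sum(d$maf < maf_cut), n_total = nrow(d)))
  ref <- counts[[reference]]
  rows <- lapply(names(counts), function(g) {
    k <- counts[[g]]
    p <- if (g == reference) NA_real_ else {
      tab <- matrix(c(k["n_rare"], k["n_total"] - k["n_rare"],
                      ref["n_rare"], ref["n_total"] - ref["n_rare"]),
                    nrow = 2)
      fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(group = g, n_rare = unname(k["n_rare"]),
               n_total = unname(k["n_total"]),
               proportion = unname(k["n_rare"] / k["n_total"]),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variants fixed outside the reference group
#'
#' Reports variants whose risk-allele frequency reaches the fixation
#' cut (default 0.99, the operational definition of fixation) in at
#' least one non-reference group while the variant is still polymorphic
#' (RAF below the cut) in the reference group.
#'
#' @param freqs a frequency table from [compute_group_raf()].
#' @param fix_cut fixation threshold in (0, 1]; default 0.99.
#' @param reference reference group label.
#' @return a `data.frame` with `rsid`, `fixed_in` (comma-separated
#'   group labels) and `raf_reference`; zero rows when nothing
#'   qualifies.
#' @export
detect_fixed <- function(freqs, fix_cut = 0.99, reference) {
  if (!is.numeric(fix_cut) || fix_cut <= 0 || fix_cut > 1)
    config_error("fix_cut must lie in (0, 1]")
  if (!reference %in% freqs$group)
    analysis_error(sprintf("reference group '%s' not in frequency table",
                           reference))
  f <- freqs[!is.na(freqs$raf), , drop = FALSE]
  ref <- f[f$group == reference, c("rsid", "raf")]
  poly_ref <- ref$rsid[ref$raf < fix_cut]
  nonref <- f[f$group != reference & f$raf >= fix_cut &
                f$rsid %in% poly_ref, , drop = FALSE]
  if (nrow(nonref) == 0L)
    return(data.frame(rsid = character(0), fixed_in = character(0),
                      raf_reference = numeric(0), stringsAsFactors = FALSE))
  sp <- split(nonref$group, nonref$rsid)
  out <- data.frame(
    rsid = names(sp),
    fixed_in = vapply(sp, function(g) paste(sort(g), collapse = ","), ""),
    raf_reference = ref$raf[match(names(sp), ref$rsid)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$rsid), , drop = FALSE]
}

#' Exact test for an excess of rare risk alleles
#'
#' Under purifying selection against the trait-lowering allele, risk
#' alleles should pile up in the rare tail of the frequency spectrum.
#' For each group this test counts variants in the rare tail
#' (`raf < low`) and the reciprocal common tail (`raf > high`) and
#' applies a two-sided exact binomial test of equal tail proportions
#' restricted to the variants falling in either tail. With
#' `low = high = 0.5` the test switches to the half-split mode
#' comparing `raf < 0.5` against `raf >= 0.5` over all variants.
#'
#' @param freqs a frequency table from [compute_group_raf()].
#' @param low,high tail cut points; must satisfy `low + high == 1`
#'   (reciprocal tails, default 0.05/0.95) or `low == high == 0.5`
#'   (half-split).
#' @return a `data.frame` per group: `n_rare`, `n_common_reciprocal`,
#'   `p_value`, `conclusion` (`"excess_rare"` iff p < 0.05 with the
#'   rare count larger, else `"no_excess"`). With zero variants in both
#'   tails the p-value is `NA` and the conclusion `"no_excess"`.
#' @export
selection_test <- function(freqs, low = 0.05, high = 0.95) {
  if (!isTRUE(all.equal(low + high, 1)))
    config_error("tail cuts must be reciprocal (low + high = 1) or the 0.5/0.5 half-split")
  if (low <= 0 || low > 0.5)
    config_error("low tail cut must lie in (0, 0.5]")
  half_split <- isTRUE(all.equal(low, 0.5))
  f <- freqs[!is.na(freqs$raf), , drop = FALSE]
  rows <- lapply(sort(unique(f$group)), function(g) {
    raf <- f$raf[f$group == g]
    if (half_split) {
      n_rare <- sum(raf < 0.5); n_common <- sum(raf >= 0.5)
    } else {
      n_rare <- sum(raf < low); n_common <- sum(raf > high)
    }
    m <- n_rare + n_common
    if (m == 0L) {
      message(sprintf("selection_test: group %s has no variant in either tail", g))
      p <- NA_real_
    } else {
      p <- binom.test(n_rare, m, p = 0.5, alternative = "two.sided")$p.value
    }
    data.frame(group = g, n_rare = n_rare, n_common_reciprocal = n_common,
               p_value = p,
               conclusion = if (!is.na(p) && p < 0.05 && n_rare > n_common)
                 "excess_rare" else "no_excess",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired contrast between two score strata within groups
#'
#' Compares two burden score sets computed on the same samples (for
#' example the deleterious versus the benign variant stratum) with a
#' paired t-test on the per-individual differences, separately within
#' each group.
#'
#' @param scores_a,scores_b `score_set` objects over identical samples.
#' @inheritParams compare_grb_groups
#' @return a `data.frame` per group: `n`, `mean_diff` (a minus b),
#'   `p_value`. If the per-individual differences are constant the
#'   t-statistic is undefined: p is 1 when the constant is zero
#'   (identical scores) and `NA` otherwise.
#' @export
within_group_strata_contrast <- function(scores_a, scores_b, panel,
                                         grouping = c("super_population",
                                                      "population", "sex")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(scores_a, "score_set"), inherits(scores_b, "score_set"))
  if (!identical(sort(names(scores_a$scores)), sort(names(scores_b$scores))))
    analysis_error("the two score sets must cover the same samples")
  b <- scores_b$scores[names(scores_a$scores)]
  d <- scores_a$scores - b
  idx <- match(names(d), panel$sample_id)
  if (anyNA(idx))
    analysis_error("score set contains samples absent from the panel")
  df <- data.frame(sample_id = names(d), group = panel[[grouping]][idx],
                   score = as.numeric(d), stringsAsFactors = FALSE)
  rows <- lapply(sort(unique(df$group)), function(g) {
    x <- df$score[df$group == g]
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      return(data.frame(group = g, n = length(x), mean_diff = mean(x),
                        p_value = NA_real_, stringsAsFactors = FALSE))
    p <- if (sd(x) < .Machine$double.eps^0.5) {
      if (abs(mean(x)) < .Machine$double.eps^0.5) 1 else NA_real_
    } else t.test(x)$p.value
    data.frame(group = g, n = length(x), mean_diff = mean(x), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele frequency spectrum per group
#'
#' Summarises the distribution of risk-allele frequencies within each
#' group as a histogram on [0, 1] (right-open bins except the last,
#' which includes 1) plus a Gaussian-kernel density evaluated on a
#' fixed grid, and reports the modal bin.
#'
#' @param freqs a frequency table from [compute_group_raf()].
#' @param bins number of histogram bins (>= 2); default 10.
#' @param grid_n number of density grid points on [0, 1]; default 512.
#' @return a named list (one element per group) of lists with
#'   `counts`, `breaks`, `modal_bin` (index of the fullest bin,
#'   first on ties), and `density` (`data.frame` with `x`, `y`).
#' @export
frequency_spectrum <- function(freqs, bins = 10, grid_n = 512) {
  if (!is.numeric(bins) || bins < 2) config_error("bins must be >= 2")
  breaks <- seq(0, 1, length.out = bins + 1)
  f <- freqs[!is.na(freqs$raf), , drop = FALSE]
  out <- lapply(split(f$raf, f$group), function(raf) {
    h <- graphics::hist(raf, breaks = breaks, right = FALSE,
                        include.lowest = TRUE, plot = FALSE)
    dens <- tryCatch(
      density(raf, kernel = "gaussian", from = 0, to = 1, n = grid_n),
      error = function(e)
        density(raf, bw = 0.05, kernel = "gaussian", from = 0, to = 1,
                n = grid_n))
    list(counts = h$counts, breaks = breaks,
         modal_bin = which.max(h$counts),
         density = data.frame(x = dens$x, y = dens$y))
  })
  out
}
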