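# Group statistics: comparisons, frequencies, rare/fixed, selection test.

make_panel <- function(groups, prefix = "s") {
  # groups: named integer vector, e.g. c(A = 3, B = 3)
  df <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(sample_id = sprintf("%s_%s%03d", g, prefix, seq_len(groups[[g]])),
               population = g, super_population = g, sex = "unknown",
               stringsAsFactors = FALSE)))
  class(df) <- c("sample_panel", "data.frame")
  df
}

make_scores <- function(panel, values, label = "all", n_variants = 10L) {
  grburden:::new_score_set(label, n_variants,
                           setNames(values, panel$sample_id))
}

test_that("compare_grb_groups reproduces the Welch oracle", {
  pan <- make_panel(c(A = 3, B = 3))
  s <- make_scores(pan, c(1, 2, 3, 4, 5, 6))
  out <- compare_grb_groups(s, pan, "super_population", reference = "A")
  b <- out[out$group == "B", ]
  expect_equal(b$mean_diff, 3)
  orc <- oracle_welch(c(4, 5, 6), c(1, 2, 3))
  expect_equal(b$p_value, orc$p, tolerance = 1e-8)
  expect_equal(c(b$ci_low, b$ci_high), orc$ci, tolerance = 1e-8)

  # random instances against the textbook formula
  set.seed(202)
  for (rep in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    pan2 <- make_panel(c(A = n1, B = n2))
    x <- rnorm(n1, 10, 2); y <- rnorm(n2, 11, 3)
    s2 <- make_scores(pan2, c(x, y))
    out2 <- compare_grb_groups(s2, pan2, "super_population", "A")
    b2 <- out2[out2$group == "B", ]
    orc2 <- oracle_welch(y, x)
    expect_equal(b2$p_value, orc2$p, tolerance = 1e-8)
    expect_equal(c(b2$ci_low, b2$ci_high), orc2$ci, tolerance = 1e-8)
    expect_true(b2$ci_low <= b2$mean_diff && b2$mean_diff <= b2$ci_high)
  }
})

test_that("compare_grb_groups: null case, reference row, small groups", {
  pan <- make_panel(c(A = 4, B = 4, C = 1))
  vals <- c(1, 2, 3, 4, 1, 2, 3, 4, 9)  # identical multisets in A and B
  s <- make_scores(pan, vals)
  expect_warning(out <- compare_grb_groups(s, pan, "super_population", "A"),
                 "n < 2")
  expect_false("C" %in% out$group)
  b <- out[out$group == "B", ]
  expect_equal(b$mean_diff, 0)
  expect_equal(b$p_value, 1, tolerance = 1e-12)
  ref <- out[out$group == "A", ]
  expect_equal(ref$mean_diff, 0)
  expect_true(is.na(ref$p_value))
  expect_equal(ref$sd, sd(c(1, 2, 3, 4)))

  expect_error(compare_grb_groups(s, pan, "super_population", "ZZZ"),
               class = "grb_analysis_error")
})

test_that("compute_group_raf counts chromosomes correctly", {
  pan <- make_panel(c(G1 = 2, G2 = 2))
  d <- make_dosage_matrix(rbind(c(2, 0), c(2, 1), c(0, NA), c(1, NA)),
                          samples = pan$sample_id)
  f <- compute_group_raf(d, pan, "super_population")
  expect_equal(f$raf[f$group == "G1" & f$rsid == "v01"], 1.0)   # fixation
  expect_equal(f$raf[f$group == "G1" & f$rsid == "v02"], 0.25)
  expect_equal(f$raf[f$group == "G2" & f$rsid == "v01"], 0.25)
  # variant entirely missing in G2 -> NA cell, zero chromosomes
  expect_true(is.na(f$raf[f$group == "G2" & f$rsid == "v02"]))
  expect_equal(f$n_chromosomes[f$group == "G2" & f$rsid == "v02"], 0L)
  expect_equal(f$n_chromosomes[f$group == "G1" & f$rsid == "v02"], 4L)
})

test_that("classify_rare folds frequencies and matches the Fisher oracle", {
  f <- data.frame(group = rep(c("X", "R"), each = 3),
                  rsid = rep(c("a", "b", "c"), 2),
                  raf = c(0.01, 0.5, 0.97, 0.3, 0.4, 0.5),
                  n_chromosomes = 100L)
  out <- classify_rare(f, 0.05, reference = "R")
  # folding: 0.01 and 0.97 both rare at MAF < 0.05
  expect_equal(out$n_rare[out$group == "X"], 2)
  expect_equal(out$n_rare[out$group == "R"], 0)
  expect_true(is.na(out$fisher_p[out$group == "R"]))

  # identical tables -> p = 1
  f2 <- f; f2$raf <- rep(c(0.01, 0.5, 0.97), 2)
  out2 <- classify_rare(f2, 0.05, "R")
  expect_equal(out2$fisher_p[out2$group == "X"], 1)

  # spec 2x2 instance (16,44) vs (1,59) against exhaustive enumeration
  p_pkg <- fisher.test(matrix(c(16, 44, 1, 59), 2))$p.value
  expect_equal(p_pkg, oracle_fisher(16, 44, 1, 59), tolerance = 1e-10)

  # invariance to a global allele flip
  f3 <- f; f3$raf <- 1 - f3$raf
  expect_equal(classify_rare(f3, 0.05, "R")$n_rare, out$n_rare)
})

test_that("package Fisher p agrees with enumeration over random tables", {
  set.seed(303)
  for (rep in 1:200) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    c_ <- sample(0:40, 1); d <- sample(0:40, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    expect_equal(fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
                 oracle_fisher(a, b, c_, d), tolerance = 1e-9,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, c_, d))
  }
})

test_that("detect_fixed finds non-reference fixation only", {
  f <- data.frame(group = rep(c("EAS", "EUR"), each = 2),
                  rsid = rep(c("a", "b"), 2),
                  raf = c(1.0, 0.995, 0.74, 0.995),
                  n_chromosomes = 100L)
  out <- detect_fixed(f, 0.99, reference = "EUR")
  # a: fixed in EAS, polymorphic (0.74) in EUR -> reported
  # b: 0.995 everywhere -> reference not polymorphic -> not reported
  expect_equal(out$rsid, "a")
  expect_equal(out$fixed_in, "EAS")
  expect_equal(out$raf_reference, 0.74)

  expect_error(detect_fixed(f, 1.2, "EUR"), class = "grb_config_error")
})

test_that("selection_test uses the exact binomial tail construction", {
  mkf <- function(raf) data.frame(group = "G", rsid = seq_along(raf),
                                  raf = raf, n_chromosomes = 10L)
  # symmetric tails -> p = 1
  out <- selection_test(mkf(c(rep(0.01, 3), rep(0.99, 3), 0.5)))
  expect_equal(out$n_rare, 3); expect_equal(out$n_common_reciprocal, 3)
  expect_equal(out$p_value, 1)
  expect_equal(out$conclusion, "no_excess")

  # (8, 0) -> p = 2 * (1/2)^8, closed form
  out2 <- selection_test(mkf(c(rep(0.02, 8), rep(0.5, 4))))
  expect_equal(out2$n_rare, 8); expect_equal(out2$n_common_reciprocal, 0)
  expect_equal(out2$p_value, 2 * 0.5^8)
  expect_equal(out2$conclusion, "excess_rare")

  # empty tails -> NA p, logged, no_excess
  expect_message(out3 <- selection_test(mkf(c(0.3, 0.5, 0.6))),
                 "no variant in either tail")
  expect_true(is.na(out3$p_value))
  expect_equal(out3$conclusion, "no_excess")

  # half-split mode partitions all variants at 0.5
  out4 <- selection_test(mkf(c(0.1, 0.4, 0.5, 0.9)), low = 0.5, high = 0.5)
  expect_equal(out4$n_rare, 2)                  # < 0.5
  expect_equal(out4$n_common_reciprocal, 2)     # >= 0.5 (0.5 counts as common)

  # non-reciprocal cuts are a config error
  expect_error(selection_test(mkf(0.5), low = 0.05, high = 0.9),
               class = "grb_config_error")
})

test_that("within_group_strata_contrast handles paired and degenerate cases", {
  pan <- make_panel(c(A = 5, B = 4))
  base <- rnorm(9, 30, 3)
  sa <- make_scores(pan, base, "del", 30L)
  sb <- make_scores(pan, base, "ben", 30L)
  out <- within_group_strata_contrast(sa, sb, pan)
  expect_equal(out$mean_diff, c(0, 0))
  expect_equal(out$p_value, c(1, 1))

  # constant offset +2 -> exact mean difference
  sb2 <- make_scores(pan, base - 2, "ben", 30L)
  out2 <- within_group_strata_contrast(sa, sb2, pan)
  expect_equal(out2$mean_diff, c(2, 2))

  # genuine paired t-test against stats::t.test(paired)
  set.seed(9)
  d2 <- rnorm(9)
  sb3 <- make_scores(pan, base - d2, "ben", 30L)
  out3 <- within_group_strata_contrast(sa, sb3, pan)
  for (g in c("A", "B")) {
    idx <- pan$super_population == g
    ref <- t.test(base[idx], (base - d2)[idx], paired = TRUE)
    expect_equal(out3$mean_diff[out3$group == g], unname(ref$estimate))
    expect_equal(out3$p_value[out3$group == g], ref$p.value)
  }

  # mismatched samples -> error
  pan2 <- make_panel(c(A = 3))
  sc <- make_scores(pan2, 1:3)
  expect_error(within_group_strata_contrast(sa, sc, pan),
               class = "grb_analysis_error")
})

test_that("frequency_spectrum bins and conserves counts", {
  f <- data.frame(group = "G", rsid = sprintf("v%d", 1:5),
                  raf = rep(0.35, 5), n_chromosomes = 10L)
  sp <- frequency_spectrum(f, bins = 10)$G
  expect_equal(sum(sp$counts), 5)
  expect_equal(sp$counts[4], 5)           # all mass in [0.3, 0.4)
  expect_equal(sp$modal_bin, 4)

  # right-open convention: 0.3 falls in [0.3, 0.4), 1.0 in the last bin
  f2 <- data.frame(group = "G", rsid = 1:3, raf = c(0.3, 1.0, 0.999),
                   n_chromosomes = 10L)
  sp2 <- frequency_spectrum(f2, bins = 10)$G
  expect_equal(sp2$counts[4], 1)
  expect_equal(sp2$counts[10], 2)
  expect_equal(sum(sp2$counts), 3)

  # density grid covers [0, 1]
  expect_equal(range(sp$density$x), c(0, 1))
  expect_error(frequency_spectrum(f, bins = 1), class = "grb_config_error")

  # roughly flat histogram under uniform frequencies (aggregated reps)
  set.seed(404)
  tot <- rep(0, 5)
  for (r in 1:40) {
    fr <- data.frame(group = "G", rsid = 1:100, raf = runif(100),
                     n_chromosomes = 10L)
    tot <- tot + frequency_spectrum(fr, bins = 5)$G$counts
  }
  expect_gt(chisq.test(tot)$p.value, 1e-4)
})
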