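# Multi-population cohort simulator: Balding-Nichols differentiation,
# Hardy-Weinberg genotypes, and a matching annotation table with known
# ground truth.

#' Default population layout for simulated cohorts
#'
#' Mirrors the five continental super-populations of a reference
#' human cohort (sample sizes 661/347/504/503/489) with a typical
#' continental-scale differentiation of FST = 0.1 per population.
#' @return a `data.frame` with columns `label`, `super_label`,
#'   `n_samples`, `fst`.
#' @export
default_populations <- function() {
  data.frame(
    label       = c("AFR", "AMR", "EAS", "EUR", "SAS"),
    super_label = c("AFR", "AMR", "EAS", "EUR", "SAS"),
    n_samples   = c(661L, 347L, 504L, 503L, 489L),
    fst         = rep(0.1, 5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes a synthetic multi-population cohort: the variant panel
#' size, the populations with their sample sizes and differentiation
#' (FST), and the sampling distributions for ancestral risk-allele
#' frequencies, effect sizes and deleteriousness scores. The seed fixes
#' the complete output byte-for-byte.
#'
#' @param n_variants number of unlinked biallelic SNPs; default 59, the
#'   size of the birthweight variant panel.
#' @param populations `data.frame` with columns `label`, `super_label`,
#'   `n_samples` (>= 1) and `fst` (each in (0, 1));
#'   default [default_populations()].
#' @param ancestral_raf [dist_spec()] for the ancestral risk-allele
#'   frequency of each variant; default uniform on [0.05, 0.95].
#' @param beta [dist_spec()] for positive per-allele effect sizes;
#'   default uniform on [0.01, 0.09] (s.d.-of-trait units, the range of
#'   published birthweight effect sizes).
#' @param prop_ancestral_effect probability that a variant's effect
#'   allele is the ancestral one; default 33/59.
#' @param cadd [dist_spec()] for CADD phred scores; default
#'   exponential with rate 0.25 (median about 2.8).
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_variants = 59L,
                              populations = default_populations(),
                              ancestral_raf = dist_spec("uniform",
                                                        min = 0.05, max = 0.95),
                              beta = dist_spec("uniform",
                                               min = 0.01, max = 0.09),
                              prop_ancestral_effect = 33 / 59,
                              cadd = dist_spec("exponential", rate = 0.25),
                              seed = 1L) {
  if (!is.numeric(n_variants) || n_variants < 1)
    config_error("n_variants must be a positive integer")
  need <- c("label", "super_label", "n_samples", "fst")
  if (!is.data.frame(populations) || !all(need %in% names(populations)))
    config_error(sprintf("populations must be a data.frame with columns %s",
                         paste(need, collapse = ", ")))
  if (any(populations$n_samples < 1))
    config_error("every population needs n_samples >= 1")
  if (any(populations$fst <= 0 | populations$fst >= 1))
    config_error("every fst must lie in (0, 1)")
  if (anyDuplicated(populations$label))
    config_error("population labels must be unique")
  if (prop_ancestral_effect < 0 || prop_ancestral_effect > 1)
    config_error("prop_ancestral_effect must lie in [0, 1]")
  stopifnot(inherits(ancestral_raf, "dist_spec"), inherits(beta, "dist_spec"),
            inherits(cadd, "dist_spec"))
  structure(list(n_variants = as.integer(n_variants),
                 populations = populations,
                 ancestral_raf = ancestral_raf, beta = beta,
                 prop_ancestral_effect = prop_ancestral_effect,
                 cadd = cadd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d variants, %d populations (%s), seed %d\n",
              x$n_variants, nrow(x$populations),
              paste(x$populations$label, collapse = ", "), x$seed))
  invisible(x)
}

# Balding-Nichols draw: population RAF ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
# around ancestral frequency p; independent across variants and pops.
bn_frequencies <- function(p, fst) {
  sapply(seq_along(fst), function(k) {
    F <- fst[k]
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  })
}

#' Simulate population allele frequencies (Balding-Nichols)
#'
#' Draws, for each variant, an ancestral risk-allele frequency from the
#' configured distribution and then per-population frequencies from the
#' Balding-Nichols model: RAF ~ Beta(p(1-F)/F, (1-p)(1-F)/F) for a
#' population with differentiation F, independently across variants and
#' populations. The Beta has mean p and variance F p (1 - p), so F is
#' the expected FST relative to the ancestral pool.
#'
#' @param config a [simulation_config()].
#' @return a numeric matrix (variants x populations) of true RAFs with
#'   the ancestral frequencies attached as attribute `"ancestral_p"`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  p <- sample_dist(config$ancestral_raf, config$n_variants)
  raf <- bn_frequencies(p, config$populations$fst)
  dimnames(raf) <- list(sprintf("snp_%03d", seq_len(config$n_variants)),
                        config$populations$label)
  attr(raf, "ancestral_p") <- p
  raf
}

#' Simulate a cohort in memory
#'
#' Generates the full synthetic cohort without touching the file
#' system: the annotation table, the sample panel, true per-population
#' allele frequencies, Hardy-Weinberg genotype dosages, and the
#' analytic expected burden per population.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `annotations` (a `variant_annotation`),
#'   `panel` (a `sample_panel`), `dosages` (a `dosage_matrix` of
#'   effect-allele counts), `raf` (true variants x populations RAF
#'   matrix with `"ancestral_p"` attribute), `expected_grb` (named
#'   vector, the analytic expectation
#'   \eqn{N \sum_i 2 p_{ik}\beta_i / \sum_i \beta_i} per population)
#'   and `effect_is_alt` (logical per variant: whether the VCF writer
#'   will place the effect allele as ALT).
#' @details Genotypes are drawn Binomial(2, RAF) per sample, i.e.
#'   Hardy-Weinberg proportions within each population. Monomorphic
#'   draws (population RAF numerically 0 or 1) are retained on purpose
#'   so fixation and rare-variant edge cases are exercised downstream.
#' @export
simulate_dosages <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_variants
  pops <- config$populations

  p <- sample_dist(config$ancestral_raf, n)
  raf <- bn_frequencies(p, pops$fst)
  rsid <- sprintf("snp_%03d", seq_len(n))
  dimnames(raf) <- list(rsid, pops$label)
  attr(raf, "ancestral_p") <- p

  # annotation table
  bases <- c("A", "C", "G", "T")
  eff <- character(n); oth <- character(n)
  for (i in seq_len(n)) {
    pair <- sample(bases, 2)
    eff[i] <- pair[1]; oth[i] <- pair[2]
  }
  betas <- sample_dist(config$beta, n)
  state <- ifelse(runif(n) < config$prop_ancestral_effect,
                  "ancestral", "derived")
  cadd <- sample_dist(config$cadd, n)
  chrom <- rep(seq_len(22), each = ceiling(n / 22))[seq_len(n)]
  ann <- data.frame(rsid = rsid, chrom = as.character(chrom),
                    pos = 10000L * seq_len(n),
                    effect_allele = eff, other_allele = oth,
                    beta = betas, allele_state = state, cadd_phred = cadd,
                    stringsAsFactors = FALSE)
  ann <- validate_annotation(ann)

  # panel
  panel <- do.call(rbind, lapply(seq_len(nrow(pops)), function(k) {
    nk <- pops$n_samples[k]
    data.frame(sample_id = sprintf("%s%04d", pops$label[k], seq_len(nk)),
               population = pops$label[k],
               super_population = pops$super_label[k],
               sex = ifelse(runif(nk) < 0.5, "male", "female"),
               stringsAsFactors = FALSE)
  }))
  class(panel) <- c("sample_panel", "data.frame")

  # HWE genotypes: Binomial(2, raf) per sample
  dos <- matrix(NA_integer_, nrow = nrow(panel), ncol = n,
                dimnames = list(panel$sample_id, rsid))
  for (k in seq_len(nrow(pops))) {
    rows <- panel$population == pops$label[k]
    nk <- sum(rows)
    # vapply returns an nk x n matrix: one column of genotypes per variant
    dos[rows, ] <- vapply(seq_len(n),
                          function(i) rbinom(nk, 2L, raf[i, k]),
                          integer(nk))
  }
  dos_class <- structure(dos, class = c("dosage_matrix", class(dos)))

  # effect allele becomes ALT for a random half of the variants
  effect_is_alt <- rep(TRUE, n)
  effect_is_alt[sample(n, floor(n / 2))] <- FALSE

  expected <- apply(raf, 2, function(pk) n * sum(2 * pk * betas) / sum(betas))

  list(annotations = ann, panel = panel, dosages = dos_class, raf = raf,
       expected_grb = expected, effect_is_alt = effect_is_alt)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_dosages()] and materialises the cohort as the four
#' standard files consumed by the pipeline: a VCF 4.2 with GT
#' genotypes, a sample panel, an annotation TSV and a ground-truth TSV.
#' The same seed always reproduces the files byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of paths: `vcf`, `panel`,
#'   `annotations`, `truth`.
#' @details The VCF writer places the effect allele as ALT for a random
#'   half of the variants and as REF for the rest, so re-extraction
#'   exercises both orientation branches of [extract_dosages()]. The
#'   truth file is long-format TSV with columns `population`, `rsid`,
#'   `true_raf` and `expected_grb` (the per-population analytic
#'   expectation, repeated within a population).
#' @export
simulate_cohort <- function(config, outdir) {
  sim <- simulate_dosages(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list(vcf = file.path(outdir, "cohort.vcf"),
                panel = file.path(outdir, "cohort.panel"),
                annotations = file.path(outdir, "annotations.tsv"),
                truth = file.path(outdir, "truth.tsv"))

  write_cohort_vcf(sim, paths$vcf)

  pan <- data.frame(sample = sim$panel$sample_id, pop = sim$panel$population,
                    super_pop = sim$panel$super_population,
                    gender = sim$panel$sex, stringsAsFactors = FALSE)
  fwrite(pan, paths$panel, sep = "\t", quote = FALSE)

  ann_out <- as.data.frame(sim$annotations)
  ann_out$beta <- fmt_num(ann_out$beta)
  ann_out$cadd_phred <- fmt_num(ann_out$cadd_phred)
  fwrite(ann_out, paths$annotations, sep = "\t", quote = FALSE)

  truth <- do.call(rbind, lapply(colnames(sim$raf), function(k) {
    data.frame(population = k, rsid = rownames(sim$raf),
               true_raf = fmt_num(sim$raf[, k]),
               expected_grb = fmt_num(unname(sim$expected_grb[k])),
               stringsAsFactors = FALSE)
  }))
  fwrite(truth, paths$truth, sep = "\t", quote = FALSE)
  invisible(paths)
}

# minimal VCF 4.2 writer for the synthetic cohort (writer only; reading
# goes through VariantAnnotation)
write_cohort_vcf <- function(sim, path) {
  ann <- sim$annotations
  dos <- unclass(sim$dosages)
  n <- nrow(ann)
  samples <- rownames(dos)
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- character(n)
  for (i in seq_len(n)) {
    if (sim$effect_is_alt[i]) {
      ref <- ann$other_allele[i]; alt <- ann$effect_allele[i]
      alt_dos <- dos[, i]
    } else {
      ref <- ann$effect_allele[i]; alt <- ann$other_allele[i]
      alt_dos <- 2L - dos[, i]
    }
    gts <- ifelse(is.na(alt_dos), "./.", gt_codes[alt_dos + 1L])
    lines[i] <- paste(c(ann$chrom[i], ann$pos[i], ann$rsid[i], ref, alt,
                        ".", "PASS", ".", "GT", gts), collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grburden-synthetic-cohort",
    sprintf("##contig=<ID=%s>", unique(ann$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  invisible(path)
}
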