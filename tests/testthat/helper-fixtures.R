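# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; nothing is read from outside tempdir.

# ---- fixture builders -------------------------------------------------

make_dosage_matrix <- function(mat, samples = NULL, rsids = NULL) {
  samples <- samples %||% sprintf("s%02d", seq_len(nrow(mat)))
  rsids   <- rsids %||% sprintf("v%02d", seq_len(ncol(mat)))
  m <- matrix(as.integer(mat), nrow = nrow(mat),
              dimnames = list(samples, rsids))
  structure(m, class = c("dosage_matrix", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_annotation_df <- function(n = 4, betas = NULL, states = NULL,
                               cadd = NULL, effect = NULL, other = NULL) {
  data.frame(
    rsid = sprintf("v%02d", seq_len(n)),
    chrom = rep("1", n),
    pos = 1000L * seq_len(n),
    effect_allele = effect %||% rep("A", n),
    other_allele  = other %||% rep("G", n),
    beta = betas %||% seq(0.01, by = 0.01, length.out = n),
    allele_state = states %||% rep(c("ancestral", "derived"), length.out = n),
    cadd_phred = cadd %||% seq_len(n),
    stringsAsFactors = FALSE
  )
}

write_annotation_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_panel_file <- function(df, path = tempfile(fileext = ".panel"),
                             sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# hand-written tiny VCF; `records` is a data.frame with columns
# chrom, pos, id, ref, alt plus one column per sample holding GT strings
write_tiny_vcf <- function(records, samples,
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(records$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- apply(records, 1, function(r)
    paste(c(r[["chrom"]], r[["pos"]], r[["id"]], r[["ref"]], r[["alt"]],
            ".", "PASS", ".", "GT", r[samples]), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# a small two-population config used across tests
small_config <- function(seed = 7, n_variants = 12,
                         n1 = 40, n2 = 40, fst = c(0.05, 0.2)) {
  simulation_config(
    n_variants = n_variants,
    populations = data.frame(label = c("POPA", "POPB"),
                             super_label = c("SPA", "SPB"),
                             n_samples = c(n1, n2), fst = fst,
                             stringsAsFactors = FALSE),
    seed = seed)
}

# build a validated variant_annotation through the public reader
validate_fixture_annotation <- function(df) {
  read_annotation_table(write_annotation_tsv(df))
}

# ---- independent oracles ---------------------------------------------

# brute-force double-loop evaluation of the rescaled weighted burden
oracle_grb <- function(dosages, rsids, betas) {
  N <- length(rsids)
  out <- numeric(nrow(dosages))
  for (j in seq_len(nrow(dosages))) {
    num <- 0; den <- 0; seen <- FALSE
    for (i in seq_len(N)) {
      c_ij <- dosages[j, rsids[i]]
      if (!is.na(c_ij)) {
        num <- num + c_ij * betas[i]
        den <- den + betas[i]
        seen <- TRUE
      }
    }
    out[j] <- if (seen) N * num / den else NA_real_
  }
  names(out) <- rownames(dosages)
  out
}

# textbook Welch two-sample t: statistic, Welch-Satterthwaite df,
# two-sided p, and 95% CI of mean(x) - mean(y)
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  hw <- qt(0.975, df) * sqrt(se2)
  list(t = t, df = df, p = p,
       ci = c(mean(x) - mean(y) - hw, mean(x) - mean(y) + hw))
}

# exhaustive hypergeometric enumeration of the two-sided Fisher exact p
# for the 2x2 table rbind(c(a, b), c(c, d)); "two-sided" by the
# standard smaller-or-equal-probability rule used by fisher.test
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  ks <- lo:hi
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
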