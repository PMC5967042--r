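# Scoring layer: weighted and unweighted genetic risk burden.

#' Construct a weight vector
#'
#' Aligns positive per-allele effect sizes to variant identifiers for
#' use in [compute_grb()].
#'
#' @param rsids character vector of variant identifiers.
#' @param betas positive effect sizes, same length as `rsids`.
#' @return object of class `weight_vector`.
#' @export
weight_vector <- function(rsids, betas) {
  if (length(rsids) != length(betas))
    config_error("rsids and betas must have the same length")
  if (length(rsids) == 0L) config_error("weight vector must be non-empty")
  if (any(!is.finite(betas) | betas <= 0))
    config_error("all betas must be positive and finite")
  if (anyDuplicated(rsids)) config_error("duplicate rsids in weight vector")
  structure(list(rsids = as.character(rsids), betas = as.numeric(betas)),
            class = "weight_vector")
}

#' Compute the weighted genetic risk burden
#'
#' For individual *j* over a subset of *N* variants with effect-allele
#' counts \eqn{c_{ij}} and effect sizes \eqn{\beta_i}, the score is
#' \deqn{GRB_j = N \frac{\sum_i c_{ij}\beta_i}{\sum_i \beta_i},}
#' i.e. the effect-size-weighted allele count rescaled by the sum of the
#' effect sizes back onto the allele-count scale \eqn{[0, 2N]}. With all
#' weights equal it reduces exactly to the unweighted allele count.
#'
#' @param dosages a `dosage_matrix` (samples x variants, counts of the
#'   effect allele).
#' @param weights a `weight_vector` covering a subset of the matrix's
#'   variants.
#' @param subset_label label recorded on the returned score set.
#' @param scale_constant multiplier applied after weight-normalisation;
#'   defaults to *N*, the number of variants in the subset, which places
#'   scores on the 0--2N scale.
#' @return object of class `score_set`: a list with `subset_label`,
#'   `n_variants`, and a named numeric vector `scores` (one entry per
#'   sample; `NA` if every dosage for that sample is missing).
#' @details Missing dosages are handled by per-individual weight
#'   renormalisation: both sums run over the observed variants only
#'   while *N* stays the full subset size. An individual with no
#'   observed dosage in the subset gets a missing score.
#' @examples
#' d <- matrix(c(1L, 2L), nrow = 1, dimnames = list("s1", c("v1", "v2")))
#' class(d) <- c("dosage_matrix", class(d))
#' w <- weight_vector(c("v1", "v2"), c(0.1, 0.3))
#' compute_grb(d, w)$scores  # 2 * (0.1 + 0.6) / 0.4 = 3.5
#' @export
compute_grb <- function(dosages, weights, subset_label = "all",
                        scale_constant = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"),
            inherits(weights, "weight_vector"))
  keep <- weights$rsids %in% colnames(dosages)
  if (!any(keep))
    analysis_error("empty variant subset: no weighted variant present in the dosage matrix")
  if (any(!keep))
    warning(sprintf("compute_grb: %d weighted variant(s) absent from dosage matrix",
                    sum(!keep)), call. = FALSE)
  rsids <- weights$rsids[keep]
  betas <- weights$betas[keep]
  N <- length(rsids)
  scale_constant <- scale_constant %||% N

  C <- dosages[, rsids, drop = FALSE]
  obs <- !is.na(C)
  numer <- as.numeric((ifelse(obs, C, 0)) %*% betas)
  denom <- as.numeric(obs %*% betas)  # per-individual sum over observed betas
  scores <- ifelse(denom > 0, scale_constant * numer / denom, NA_real_)
  names(scores) <- rownames(dosages)
  new_score_set(subset_label, N, scores)
}

#' Compute the unweighted genetic risk burden
#'
#' The plain sum of effect-allele counts over the observed variants of
#' the subset: \eqn{GRB_j = \sum_i c_{ij}}. Unlike the weighted,
#' rescaled score, unweighted scores are exactly additive across a
#' partition of the variant set.
#'
#' @inheritParams compute_grb
#' @param rsids optional subset of variant ids; defaults to all columns.
#' @return object of class `score_set`.
#' @export
compute_unweighted_grb <- function(dosages, rsids = NULL, subset_label = "all") {
  stopifnot(inherits(dosages, "dosage_matrix"))
  rsids <- rsids %||% colnames(dosages)
  keep <- rsids %in% colnames(dosages)
  if (!any(keep)) analysis_error("empty variant subset")
  rsids <- rsids[keep]
  C <- dosages[, rsids, drop = FALSE]
  all_missing <- rowSums(!is.na(C)) == 0L
  scores <- rowSums(C, na.rm = TRUE)
  scores[all_missing] <- NA_real_
  names(scores) <- rownames(dosages)
  new_score_set(subset_label, length(rsids), scores)
}

new_score_set <- function(subset_label, n_variants, scores) {
  stopifnot(n_variants > 0)
  # floating-point headroom: rescaling can land an ulp outside [0, 2N]
  tol <- 1e-8 * max(1, 2 * n_variants)
  bad <- !is.na(scores) & (scores < -tol | scores > 2 * n_variants + tol)
  if (any(bad))
    analysis_error("internal: score outside [0, 2N]")
  structure(list(subset_label = subset_label,
                 n_variants = as.integer(n_variants),
                 scores = scores),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set> '%s': %d variants, %d samples, mean %.3f\n",
              x$subset_label, x$n_variants, length(x$scores),
              mean(x$scores, na.rm = TRUE)))
  invisible(x)
}

#' Partition variants into two labeled strata
#'
#' Splits the annotated variant panel either by the evolutionary state
#' of the effect allele (ancestral vs derived) or by deleteriousness
#' (CADD phred score above vs at-or-below a threshold).
#'
#' @param annotations a `variant_annotation` table.
#' @param criterion `"by_allele_state"` or `"by_deleteriousness"`.
#' @param threshold CADD cut point for `"by_deleteriousness"`; `NULL`
#'   (default) uses the median CADD of the input set. Classification is
#'   strict: `cadd > threshold` is deleterious, `cadd <= threshold`
#'   benign, so median-valued SNPs fall on the benign side.
#' @return a named list of two character vectors of rsids
#'   (`ancestral`/`derived` or `benign`/`deleterious`), together
#'   covering all input variants. For `"by_deleteriousness"` the
#'   threshold used is attached as attribute `"threshold"`. An empty
#'   stratum is allowed but flagged with a warning.
#' @export
stratify_variants <- function(annotations,
                              criterion = c("by_allele_state",
                                            "by_deleteriousness"),
                              threshold = NULL) {
  stopifnot(inherits(annotations, "variant_annotation"))
  criterion <- match.arg(criterion)
  if (criterion == "by_allele_state") {
    out <- list(
      ancestral = annotations$rsid[annotations$allele_state == "ancestral"],
      derived   = annotations$rsid[annotations$allele_state == "derived"]
    )
  } else {
    if (is.null(threshold)) threshold <- median(annotations$cadd_phred)
    out <- list(
      benign      = annotations$rsid[annotations$cadd_phred <= threshold],
      deleterious = annotations$rsid[annotations$cadd_phred > threshold]
    )
    attr(out, "threshold") <- threshold
  }
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty))
    warning(sprintf("stratify_variants: empty stratum '%s'",
                    paste(empty, collapse = "', '")), call. = FALSE)
  out
}

#' Write score sets to a TSV
#'
#' @param score_sets list of `score_set` objects.
#' @param panel a `sample_panel` supplying population labels.
#' @param path output TSV path.
#' @return the written path, invisibly.
#' @export
write_scores_tsv <- function(score_sets, panel, path) {
  stopifnot(inherits(panel, "sample_panel"))
  rows <- lapply(score_sets, function(s) {
    idx <- match(names(s$scores), panel$sample_id)
    data.table(
      sample_id        = names(s$scores),
      population       = panel$population[idx],
      super_population = panel$super_population[idx],
      subset_label     = s$subset_label,
      n_variants       = s$n_variants,
      grb              = fmt_num(s$scores)
    )
  })
  fwrite(rbindlist(rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}
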