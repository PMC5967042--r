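# Input layer: annotation table, sample panel, VCF genotype extraction.

ANNOT_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "allele_state", "cadd_phred")

#' Read a variant annotation table
#'
#' Reads the tab-delimited table describing the trait-lowering variant
#' panel: one row per SNP with its identifier, location, effect
#' (trait-lowering) and other allele, positive per-allele effect size,
#' ancestral/derived state of the effect allele, and CADD phred
#' deleteriousness score.
#'
#' @param path path to a TSV file with header. Required columns:
#'   `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `allele_state`, `cadd_phred`.
#' @return a `data.frame` (class `variant_annotation`) with the required
#'   columns validated; row order preserved.
#' @details Validation rules: every `beta` must be strictly positive
#'   (effect sizes enter the score as magnitudes of the lowering
#'   effect), `effect_allele` must differ from `other_allele`, `rsid`
#'   must be unique, and `allele_state` must be `"ancestral"` or
#'   `"derived"`. Violations raise a validation error naming the row;
#'   a missing column raises a format error naming the column.
#' @seealso [extract_dosages()], [stratify_variants()]
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("annotation file not found: %s", path))
  ann <- tryCatch(
    as.data.frame(fread(path, sep = "\t", header = TRUE,
                        colClasses = list(character = "chrom"))),
    error = function(e) format_error(sprintf("cannot parse annotation TSV: %s",
                                             conditionMessage(e))))
  missing <- setdiff(ANNOT_COLS, names(ann))
  if (length(missing))
    format_error(sprintf("annotation table missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann$rsid          <- as.character(ann$rsid)
  ann$chrom         <- as.character(ann$chrom)
  ann$pos           <- as.integer(ann$pos)
  ann$effect_allele <- toupper(as.character(ann$effect_allele))
  ann$other_allele  <- toupper(as.character(ann$other_allele))
  ann$allele_state  <- as.character(ann$allele_state)
  bad <- which(!is.finite(ann$beta) | ann$beta <= 0)
  if (length(bad))
    analysis_error(sprintf("beta must be > 0; offending row(s): %s (rsid %s)",
                           paste(bad, collapse = ", "),
                           paste(ann$rsid[bad], collapse = ", ")))
  dup <- which(duplicated(ann$rsid))
  if (length(dup))
    analysis_error(sprintf("duplicate rsid at row(s): %s (%s)",
                           paste(dup, collapse = ", "),
                           paste(unique(ann$rsid[dup]), collapse = ", ")))
  same <- which(ann$effect_allele == ann$other_allele)
  if (length(same))
    analysis_error(sprintf("effect_allele equals other_allele at row(s): %s",
                           paste(same, collapse = ", ")))
  badstate <- which(!ann$allele_state %in% c("ancestral", "derived"))
  if (length(badstate))
    analysis_error(sprintf(
      "allele_state must be 'ancestral' or 'derived'; offending row(s): %s",
      paste(badstate, collapse = ", ")))
  if (any(!is.finite(ann$cadd_phred) | ann$cadd_phred < 0))
    analysis_error("cadd_phred must be non-negative and finite")
  class(ann) <- c("variant_annotation", "data.frame")
  ann
}

#' Read a sample panel
#'
#' Reads a sample-to-population panel in the 1000 Genomes
#' `integrated_call_samples` dialect: whitespace- or tab-delimited with
#' header columns `sample`, `pop`, `super_pop` and optionally `gender`.
#'
#' @param path path to the panel file.
#' @return a `data.frame` (class `sample_panel`) with columns
#'   `sample_id`, `population`, `super_population`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`).
#' @details Duplicate sample identifiers and populations mapped to more
#'   than one super-population are validation errors. A missing gender
#'   column yields `sex = "unknown"` for every sample.
#' @export
read_sample_panel <- function(path) {
  if (!file.exists(path)) format_error(sprintf("panel file not found: %s", path))
  pan <- tryCatch(
    as.data.frame(fread(path, header = TRUE)),
    error = function(e) format_error(sprintf("cannot parse panel file: %s",
                                             conditionMessage(e))))
  need <- c("sample", "pop", "super_pop")
  missing <- setdiff(need, names(pan))
  if (length(missing))
    format_error(sprintf("panel missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  out <- data.frame(
    sample_id        = as.character(pan$sample),
    population       = as.character(pan$pop),
    super_population = as.character(pan$super_pop),
    stringsAsFactors = FALSE
  )
  if ("gender" %in% names(pan)) {
    g <- tolower(as.character(pan$gender))
    out$sex <- ifelse(g %in% c("male", "m", "1"), "male",
               ifelse(g %in% c("female", "f", "2"), "female", "unknown"))
  } else {
    out$sex <- "unknown"
  }
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup))
    analysis_error(sprintf("duplicate sample_id in panel: %s",
                           paste(unique(dup), collapse = ", ")))
  map <- unique(out[, c("population", "super_population")])
  multi <- map$population[duplicated(map$population)]
  if (length(multi))
    analysis_error(sprintf(
      "population(s) mapped to more than one super-population: %s",
      paste(unique(multi), collapse = ", ")))
  class(out) <- c("sample_panel", "data.frame")
  out
}

#' Extract effect-allele dosages from a VCF
#'
#' Locates each annotated variant in a VCF by chromosome and position,
#' checks that the VCF REF/ALT alleles match the annotation's allele
#' pair, and returns per-sample counts (0/1/2) of the effect
#' (trait-lowering) allele.
#'
#' @param vcf path to a VCF 4.x file (plain or bgzipped).
#' @param annotations a `variant_annotation` table
#'   (see [read_annotation_table()]).
#' @param panel a `sample_panel` (see [read_sample_panel()]); the
#'   returned matrix is restricted to samples present in both panel and
#'   VCF, and leftovers on either side are reported.
#' @return an integer matrix of class `dosage_matrix`, samples in rows
#'   and variants (rsid) in columns; entries are counts of the effect
#'   allele in \{0,1,2\} or `NA` for missing genotypes.
#' @details Alleles are compared literally to VCF REF/ALT -- no strand
#'   flipping is attempted. If the effect allele is the ALT, the dosage
#'   is the number of ALT alleles in the genotype; if it is the REF, the
#'   dosage is 2 minus that number. Multi-allelic records are
#'   decomposed per ALT allele and are usable iff one ALT together with
#'   REF equals the annotation allele pair. Variants absent from the
#'   VCF, or whose alleles do not match, are excluded with a warning;
#'   zero matching variants is a hard error. Missing genotypes (`./.`)
#'   are stored as `NA`, never as zero.
#' @examples
#' \dontrun{
#' ann <- read_annotation_table("annotations.tsv")
#' pan <- read_sample_panel("samples.panel")
#' dos <- extract_dosages("cohort.vcf", ann, pan)
#' }
#' @export
extract_dosages <- function(vcf, annotations, panel) {
  stopifnot(inherits(annotations, "variant_annotation"),
            inherits(panel, "sample_panel"))
  if (!file.exists(vcf)) format_error(sprintf("VCF not found: %s", vcf))

  v <- tryCatch(
    VariantAnnotation::readVcf(vcf, param = VariantAnnotation::ScanVcfParam(
      info = NA, geno = "GT")),
    error = function(e) format_error(sprintf("cannot read VCF: %s",
                                             conditionMessage(e))))
  rr   <- SummarizedExperiment::rowRanges(v)
  chrs <- as.character(GenomeInfoDb::seqnames(rr))
  pos  <- BiocGenerics::start(rr)
  ref  <- as.character(rr$REF)
  altl <- rr$ALT  # DNAStringSetList: possibly multi-allelic
  gt   <- VariantAnnotation::geno(v)$GT  # records x samples, character

  vcf_samples <- colnames(gt)
  keep_samples <- intersect(panel$sample_id, vcf_samples)
  if (length(keep_samples) == 0L)
    analysis_error("no overlap between panel samples and VCF samples")
  only_panel <- setdiff(panel$sample_id, vcf_samples)
  only_vcf   <- setdiff(vcf_samples, panel$sample_id)
  if (length(only_panel))
    message(sprintf("extract_dosages: %d panel sample(s) absent from VCF (e.g. %s)",
                    length(only_panel), paste(head(only_panel, 3), collapse = ", ")))
  if (length(only_vcf))
    message(sprintf("extract_dosages: %d VCF sample(s) absent from panel (e.g. %s)",
                    length(only_vcf), paste(head(only_vcf, 3), collapse = ", ")))

  key_vcf <- paste(sub("^chr", "", chrs), pos)
  key_ann <- paste(sub("^chr", "", annotations$chrom), annotations$pos)

  n_keep <- length(keep_samples)
  dos <- matrix(NA_integer_, nrow = n_keep, ncol = nrow(annotations),
                dimnames = list(keep_samples, annotations$rsid))
  excluded <- character(0)

  for (i in seq_len(nrow(annotations))) {
    hits <- which(key_vcf == key_ann[i])
    if (length(hits) == 0L) {
      excluded <- c(excluded, sprintf("%s (not in VCF)", annotations$rsid[i]))
      next
    }
    eff <- annotations$effect_allele[i]
    oth <- annotations$other_allele[i]
    matched <- FALSE
    for (h in hits) {
      alts <- as.character(altl[[h]])
      # decompose per ALT: usable iff {REF, one ALT} == {effect, other}
      j <- which((ref[h] == eff & alts == oth) | (ref[h] == oth & alts == eff))
      if (length(j) == 0L) next
      j <- j[1L]
      cnt <- count_allele(gt[h, keep_samples], allele_index = j)
      dos[, i] <- if (ref[h] == eff) 2L - cnt else cnt
      matched <- TRUE
      break
    }
    if (!matched)
      excluded <- c(excluded, sprintf("%s (allele mismatch: VCF %s/%s vs annotation %s/%s)",
                                      annotations$rsid[i], ref[hits[1]],
                                      paste(as.character(altl[[hits[1]]]), collapse = ","),
                                      eff, oth))
  }

  keep_var <- !annotations$rsid %in% sub(" .*$", "", excluded)
  if (length(excluded)) {
    warning(sprintf("extract_dosages: excluded %d variant(s): %s",
                    length(excluded), paste(excluded, collapse = "; ")),
            call. = FALSE)
  }
  if (!any(keep_var))
    analysis_error("no annotated variant could be matched in the VCF")
  dos <- dos[, keep_var, drop = FALSE]
  structure(dos, class = c("dosage_matrix", class(dos)))
}

# count occurrences of allele index `allele_index` in GT strings like
# "0|1", "1/1", "./."; any missing allele call makes the dosage NA
count_allele <- function(gt_strings, allele_index) {
  parts <- strsplit(gt_strings, "[/|]")
  vapply(parts, function(a) {
    if (any(a == ".") || length(a) == 0L) return(NA_integer_)
    sum(a == as.character(allele_index))
  }, integer(1))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants; %d missing entries\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}
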