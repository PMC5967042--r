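# Orchestration: run configuration, scoring runs, comparison runs.

#' Run configuration
#'
#' Bundles the paths and analysis parameters for an end-to-end run.
#'
#' @param vcf,panel,annotations input file paths.
#' @param outdir output directory (created if missing).
#' @param reference reference group label; default `"EUR"`.
#' @param maf_cut folded-MAF rare threshold, in (0, 0.5); default 0.05.
#' @param fix_cut fixation RAF threshold, in (0, 1]; default 0.99.
#' @param selection_low,selection_high RAF tail cuts for the selection
#'   test; defaults 0.05 / 0.95.
#' @param cadd_threshold numeric CADD cut, or `"median"` (default) for
#'   the median of the annotated panel.
#' @param grouping grouping level for all comparisons; default
#'   `"super_population"`.
#' @param seed integer seed for any resampling; default 1.
#' @return an object of class `run_config`.
#' @export
run_config <- function(vcf, panel, annotations, outdir,
                       reference = "EUR", maf_cut = 0.05, fix_cut = 0.99,
                       selection_low = 0.05, selection_high = 0.95,
                       cadd_threshold = "median",
                       grouping = c("super_population", "population", "sex"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  for (nm in c("maf_cut", "fix_cut", "selection_low", "selection_high")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      config_error(sprintf("%s must be a number in (0, 1]", nm))
  }
  if (maf_cut >= 0.5) config_error("maf_cut must be < 0.5")
  if (!identical(cadd_threshold, "median") && !is.numeric(cadd_threshold))
    config_error("cadd_threshold must be numeric or \"median\"")
  structure(list(vcf = vcf, panel = panel, annotations = annotations,
                 outdir = outdir, reference = reference, maf_cut = maf_cut,
                 fix_cut = fix_cut, selection_low = selection_low,
                 selection_high = selection_high,
                 cadd_threshold = cadd_threshold, grouping = grouping,
                 seed = as.integer(seed)),
            class = "run_config")
}

# read and validate the three inputs of a run
load_inputs <- function(config) {
  ann <- read_annotation_table(config$annotations)
  pan <- read_sample_panel(config$panel)
  dos <- extract_dosages(config$vcf, ann, pan)
  ann <- ann[ann$rsid %in% colnames(dos), , drop = FALSE]
  class(ann) <- c("variant_annotation", "data.frame")
  pan <- pan[pan$sample_id %in% rownames(dos), , drop = FALSE]
  class(pan) <- c("sample_panel", "data.frame")
  list(annotations = ann, panel = pan, dosages = dos)
}

# the five standard score strata: all, ancestral, derived, benign,
# deleterious; empty strata are skipped with a warning
score_strata <- function(inputs, cadd_threshold = "median") {
  ann <- inputs$annotations
  thr <- if (identical(cadd_threshold, "median")) NULL else cadd_threshold
  strata <- c(list(all = ann$rsid),
              suppressWarnings(stratify_variants(ann, "by_allele_state")),
              suppressWarnings(stratify_variants(ann, "by_deleteriousness",
                                                 threshold = thr)))
  empty <- names(strata)[lengths(strata) == 0L]
  if (length(empty))
    warning(sprintf("skipping empty stratum/strata: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  strata <- strata[lengths(strata) > 0L]
  sets <- lapply(names(strata), function(lbl) {
    w <- weight_vector(strata[[lbl]],
                       ann$beta[match(strata[[lbl]], ann$rsid)])
    compute_grb(inputs$dosages, w, subset_label = lbl)
  })
  names(sets) <- names(strata)
  sets
}

run_manifest <- function(config, inputs, extra = list()) {
  c(list(
    tool = "grburden",
    version = as.character(packageVersion("grburden")),
    inputs = list(
      vcf = unname(md5sum(config$vcf)),
      panel = unname(md5sum(config$panel)),
      annotations = unname(md5sum(config$annotations))
    ),
    parameters = unclass(config)[setdiff(names(unclass(config)), "outdir")],
    n_samples = nrow(inputs$panel),
    n_variants = ncol(inputs$dosages)
  ), extra)
}

#' Score an annotated cohort across the standard strata
#'
#' Reads the inputs named in the configuration, extracts effect-allele
#' dosages, and writes one weighted burden score TSV per stratum
#' (all / ancestral / derived / benign / deleterious) plus a JSON run
#' manifest recording input checksums, parameters, stratum sizes and
#' the tool version.
#'
#' @param config a [run_config()].
#' @param inputs optional pre-loaded inputs (internal reuse).
#' @return invisibly, a list with `score_sets`, `inputs` and `paths`.
#' @export
run_score <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  inputs <- inputs %||% load_inputs(config)
  sets <- score_strata(inputs, config$cadd_threshold)
  paths <- character(0)
  for (lbl in names(sets)) {
    p <- file.path(config$outdir, sprintf("grb_%s.tsv", lbl))
    write_scores_tsv(sets[lbl], inputs$panel, p)
    paths[lbl] <- p
  }
  manifest <- run_manifest(config, inputs, list(
    strata_sizes = lapply(sets, function(s) s$n_variants)))
  mpath <- file.path(config$outdir, "manifest_score.json")
  write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("run_score: wrote %d score sets to %s",
                  length(sets), config$outdir))
  invisible(list(score_sets = sets, inputs = inputs,
                 paths = c(as.list(paths), manifest = mpath)))
}

#' Run all group-level comparisons
#'
#' Produces the full set of comparison tables for a cohort: burden
#' comparisons per stratum versus the reference group, the per-group
#' risk-allele frequency table, rare-variant proportions with Fisher
#' tests, fixed-variant detection, the rare-vs-reciprocal-common
#' selection test (both the 0.05/0.95 tails and the half-split mode),
#' the within-group deleterious-minus-benign paired contrast, and the
#' frequency-spectrum density grid.
#'
#' @param config a [run_config()].
#' @param inputs optional pre-loaded inputs (internal reuse).
#' @return invisibly, a list of the computed tables and output paths.
#' @export
run_compare <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  inputs <- inputs %||% load_inputs(config)
  sets <- score_strata(inputs, config$cadd_threshold)
  grouping <- config$grouping
  ref <- config$reference

  num_fmt <- function(d) {
    num <- vapply(d, is.numeric, TRUE) & !names(d) %in% c("n", "n_rare",
      "n_total", "n_common_reciprocal", "n_chromosomes", "n_variants")
    d[num] <- lapply(d[num], fmt_num)
    d
  }
  out <- list()
  paths <- list()
  wr <- function(d, name) {
    p <- file.path(config$outdir, name)
    fwrite(num_fmt(as.data.frame(d)), p, sep = "\t", quote = FALSE)
    p
  }

  cmp <- rbindlist(lapply(intersect(c("all", "ancestral", "derived"),
                                    names(sets)), function(lbl)
    cbind(subset_label = lbl, n_variants = sets[[lbl]]$n_variants,
          compare_grb_groups(sets[[lbl]], inputs$panel, grouping, ref))))
  out$grb_comparison <- as.data.frame(cmp)
  paths$grb_comparison <- wr(cmp, "grb_comparison.tsv")

  del <- rbindlist(lapply(intersect(c("benign", "deleterious"),
                                    names(sets)), function(lbl)
    cbind(subset_label = lbl, n_variants = sets[[lbl]]$n_variants,
          compare_grb_groups(sets[[lbl]], inputs$panel, grouping, ref))))
  out$grb_by_deleteriousness <- as.data.frame(del)
  paths$grb_by_deleteriousness <- wr(del, "grb_by_deleteriousness.tsv")

  if (all(c("deleterious", "benign") %in% names(sets))) {
    out$strata_contrast <- within_group_strata_contrast(
      sets$deleterious, sets$benign, inputs$panel, grouping)
    paths$strata_contrast <- wr(out$strata_contrast, "strata_contrast.tsv")
  }

  freqs <- compute_group_raf(inputs$dosages, inputs$panel, grouping)
  out$raf_table <- freqs
  paths$raf_table <- wr(freqs, "raf_table.tsv")

  out$rare_proportions <- classify_rare(freqs, config$maf_cut, ref)
  paths$rare_proportions <- wr(out$rare_proportions, "rare_proportions.tsv")

  out$fixed_variants <- detect_fixed(freqs, config$fix_cut, ref)
  paths$fixed_variants <- wr(out$fixed_variants, "fixed_variants.tsv")

  sel_tails <- cbind(mode = "tails",
                     selection_test(freqs, config$selection_low,
                                    config$selection_high))
  sel_half <- cbind(mode = "half_split", selection_test(freqs, 0.5, 0.5))
  out$selection_test <- rbind(sel_tails, sel_half)
  paths$selection_test <- wr(out$selection_test, "selection_test.tsv")

  spec <- frequency_spectrum(freqs)
  dens <- rbindlist(lapply(names(spec), function(g)
    data.table(group = g, x = spec[[g]]$density$x, y = spec[[g]]$density$y)))
  out$frequency_spectrum <- spec
  paths$density_grid <- wr(dens, "density_grid.tsv")

  manifest <- run_manifest(config, inputs, list(
    strata_sizes = lapply(sets, function(s) s$n_variants)))
  mpath <- file.path(config$outdir, "manifest_compare.json")
  write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("run_compare: wrote %d tables to %s",
                  length(paths), config$outdir))
  invisible(list(tables = out, paths = c(paths, manifest = mpath),
                 score_sets = sets, inputs = inputs))
}
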