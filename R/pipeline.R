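# End-to-end orchestration: simulate (or accept) a cohort, preprocess,
# screen differential features per layer, remove tissue-confounded
# signatures against the paired reference, build the correlation network
# and ceRNA triads, integrate methylation in the nine-quadrant grid, and
# run enrichment.  Every stage writes a TSV when an output directory is
# given and the run manifest records per-stage counts for provenance.

#' Run the full ceRNA integration pipeline
#'
#' Executes the analysis end to end on a cohort (by default simulated from
#' `config` together with its paired reference and prediction table) and
#' returns a `cerna_run` object holding every stage result plus a manifest
#' of per-stage counts. With `outdir` set, all intermediate tables are
#' written as TSV and the manifest as JSON; identical config and seed give
#' byte-identical outputs.
#'
#' @param config A [sim_config()]; its `seed` drives every stochastic stage
#'   through fixed per-stage offsets.
#' @param cohort Optionally, a pre-built cohort list (as from
#'   [simulate_cohort()]); defaults to simulating from `config`.
#' @param outdir Optional output directory for TSV/JSON artifacts.
#' @param normalize Quantile-normalize the expression layers first? The
#'   default is `FALSE` because the synthetic generator emulates arrays that
#'   the vendor software has already normalized and log2-scaled (the form in
#'   which such data reaches the statistics); set `TRUE` for raw intensity
#'   input. Note that quantile normalization assumes most features are
#'   non-differential and compresses planted effects when a large fraction
#'   of rows truly differ between groups.
#' @param adj_p_max,min_fold_change DE call thresholds.
#' @param min_delta_beta Differential-methylation effect threshold.
#' @param moderated Use moderated (shrunken-variance) t statistics?
#' @param alpha_on Correlation significance on raw `"p"` or `"fdr"`.
#' @param decoy_fraction Decoy fraction for the simulated prediction table.
#' @param require_lncrna_mrna_edge Require the positive confirmation edge in
#'   triads?
#' @param collection Optional gene-set collection for ORA of the filtered DE
#'   mRNAs.
#' @param gba_hub Optional hub feature id for guilt-by-association GSEA;
#'   searched across the three expression layers.
#' @param n_perm Permutations for GSEA stages.
#' @return A list of class `cerna_run` with elements `cohort`, `de`
#'   (per-layer classified results), `filtered` (per-layer kept features),
#'   `pairs` (thresholded and intersected edge lists), `triads`, `quadrant`,
#'   `hypo_up`, `ora`, `gba`, and `manifest`.
#' @export
run_cerna_pipeline <- function(config = sim_config(), cohort = NULL,
                               outdir = NULL, normalize = FALSE,
                               adj_p_max = 0.05, min_fold_change = 2.0,
                               min_delta_beta = 0.2, moderated = FALSE,
                               alpha_on = "p", decoy_fraction = 0.3,
                               require_lncrna_mrna_edge = FALSE,
                               collection = NULL, gba_hub = NULL,
                               n_perm = 1000) {
  cohort <- cohort %||% simulate_cohort(config)
  reference <- simulate_reference_pairs(config)
  predictions <- simulate_target_database(cohort$truth, cohort$annotation,
                                          decoy_fraction = decoy_fraction,
                                          seed = config$seed)
  layers <- list(mRNA = cohort$mrna, miRNA = cohort$mirna, lncRNA = cohort$lncrna)

  # preprocess: sex-chromosome probe filter, optional quantile normalization
  layers <- map(layers, filter_probes, annotation = cohort$annotation)
  if (normalize) layers <- map(layers, quantile_normalize)

  # per-layer differential screening
  de <- map(layers, function(x) {
    classify_de(student_t_de(x, cohort$samples, moderated = moderated),
                adj_p_max = adj_p_max, min_fold_change = min_fold_change)
  })

  # reference tissue-confound filter
  ref_tests <- paired_reference_test(reference$reference, reference$samples)
  filtered <- map(de, filter_cohort_specific, reference_tests = ref_tests)

  # correlation network over the surviving differential features
  keep_rows <- function(x, ids) restore_omics(x[x$feature_id %in% ids, ], x)
  mir_kept <- keep_rows(layers$miRNA, filtered$miRNA$feature_id)
  mrna_kept <- keep_rows(layers$mRNA, filtered$mRNA$feature_id)
  lnc_kept <- keep_rows(layers$lncRNA, filtered$lncRNA$feature_id)
  empty_pairs <- tibble(source_id = character(), target_id = character(),
                        pair_type = character(), r = numeric(), p = numeric(),
                        fdr = numeric(), predicted = logical())
  mm_all <- if (nrow(mir_kept) && nrow(mrna_kept)) {
    pearson_pairs(mir_kept, mrna_kept, "mirna_mrna")
  } else empty_pairs
  ml_all <- if (nrow(mir_kept) && nrow(lnc_kept)) {
    pearson_pairs(mir_kept, lnc_kept, "mirna_lncrna")
  } else empty_pairs
  lm_all <- if (nrow(lnc_kept) && nrow(mrna_kept)) {
    pearson_pairs(lnc_kept, mrna_kept, "lncrna_mrna")
  } else empty_pairs
  mm_thr <- threshold_pairs(mm_all, alpha_on = alpha_on)
  ml_thr <- threshold_pairs(ml_all, alpha_on = alpha_on)
  lm_thr <- threshold_pairs(lm_all, alpha_on = alpha_on)
  mm_pred <- intersect_with_predictions(mm_thr, predictions)
  ml_pred <- intersect_with_predictions(ml_thr, predictions)
  triads <- assemble_cerna_triads(mm_pred, ml_pred, lm_thr,
                                  require_lncrna_mrna_edge = require_lncrna_mrna_edge)

  # nine-quadrant methylation integration
  dm <- differential_methylation(cohort$methylation, cohort$samples,
                                 adj_p_max = adj_p_max,
                                 min_delta_beta = min_delta_beta,
                                 moderated = moderated)
  quadrant <- nine_quadrant(dm, de$mRNA)
  hypo_up <- select_hypomethylated_upregulated(quadrant)

  # enrichment of the filtered DE mRNAs; guilt-by-association for a hub
  ora <- NULL
  if (!is.null(collection)) {
    ora <- ora_batch(filtered$mRNA$feature_id, collection,
                     universe = layers$mRNA$feature_id)
  }
  gba <- NULL
  if (!is.null(gba_hub)) {
    hub_matrix <- NULL
    for (x in layers) if (gba_hub %in% x$feature_id) hub_matrix <- x
    if (is.null(hub_matrix)) abort(sprintf("hub '%s' not found in any layer", gba_hub))
    gba <- guilt_by_association(gba_hub, hub_matrix, layers$mRNA,
                                collection %||% abort("guilt-by-association needs a collection"),
                                n_perm = n_perm, seed = config$seed + 17L)
  }

  manifest <- build_manifest(config, layers, de, filtered,
                             list(mm = mm_all, ml = ml_all, lm = lm_all),
                             list(mm = mm_thr, ml = ml_thr, lm = lm_thr),
                             list(mm = mm_pred, ml = ml_pred),
                             triads, dm, quadrant, hypo_up, ora)
  run <- structure(list(
    cohort = cohort, reference = reference, predictions = predictions,
    de = de, reference_tests = ref_tests, filtered = filtered,
    pairs = list(mirna_mrna = mm_pred, mirna_lncrna = ml_pred,
                 lncrna_mrna = lm_thr),
    triads = triads, dm = dm, quadrant = quadrant, hypo_up = hypo_up,
    ora = ora, gba = gba, manifest = manifest
  ), class = "cerna_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

build_manifest <- function(config, layers, de, filtered, pairs_all, pairs_thr,
                           pairs_pred, triads, dm, quadrant, hypo_up, ora) {
  n_calls <- function(tab) sum(tab$call %in% c("up", "down"))
  counts <- list(
    features_tested = map_int(layers, nrow),
    de_calls = map_int(de, n_calls),
    kept_after_reference_filter = map_int(filtered, nrow),
    pairs_computed = map_int(pairs_all, nrow),
    pairs_thresholded = map_int(pairs_thr, nrow),
    pairs_predicted = map_int(pairs_pred, nrow),
    triads = nrow(triads),
    dm_calls = n_calls(dm),
    quadrant_counts = as.list(table(factor(quadrant$quadrant, levels = 1:9))),
    hypo_up_genes = nrow(hypo_up),
    enriched_sets = if (is.null(ora)) NA_integer_ else sum(ora$adj_p < 0.05)
  )
  stopifnot(all(unlist(counts[c("features_tested", "de_calls",
                                "kept_after_reference_filter")]) >= 0),
            counts$de_calls <= counts$features_tested,
            counts$kept_after_reference_filter <= counts$de_calls,
            counts$pairs_thresholded <= counts$pairs_computed,
            counts$pairs_predicted <= counts$pairs_thresholded[c("mm", "ml")],
            sum(unlist(counts$quadrant_counts)) == nrow(quadrant))
  # named lists survive JSON round-trips with their names
  per_layer <- c("features_tested", "de_calls", "kept_after_reference_filter",
                 "pairs_computed", "pairs_thresholded", "pairs_predicted")
  counts[per_layer] <- lapply(counts[per_layer], as.list)
  list(config = unclass(config), seed = config$seed, counts = counts,
       version = as.character(utils::packageVersion("cernaflow")))
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outdir, name)
  for (layer in names(run$de)) {
    readr::write_tsv(as_tibble(run$de[[layer]]), out(sprintf("de_%s.tsv", layer)),
                     progress = FALSE)
    readr::write_tsv(run$filtered[[layer]], out(sprintf("filtered_%s.tsv", layer)),
                     progress = FALSE)
  }
  readr::write_tsv(run$reference_tests, out("reference_tests.tsv"), progress = FALSE)
  write_edge_list(dplyr::bind_rows(run$pairs), out("network_edges.tsv"))
  readr::write_tsv(as_tibble(run$triads), out("triads.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(run$dm), out("dm.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(run$quadrant), out("quadrant.tsv"), progress = FALSE)
  readr::write_tsv(run$hypo_up, out("hypo_up.tsv"), progress = FALSE)
  if (!is.null(run$ora)) readr::write_tsv(run$ora, out("ora.tsv"), progress = FALSE)
  if (!is.null(run$gba)) {
    gba <- dplyr::mutate(as_tibble(run$gba),
                         leading_edge = map_chr(.data$leading_edge, paste, collapse = ","))
    readr::write_tsv(gba, out("gba.tsv"), progress = FALSE)
  }
  jsonlite::write_json(run$manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.cerna_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("ceRNA pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  features tested:   ", paste(names(cts$features_tested),
                                     unlist(cts$features_tested), collapse = ", "), "\n")
  cat("  DE calls:          ", paste(names(cts$de_calls), unlist(cts$de_calls),
                                     collapse = ", "), "\n")
  cat("  after ref filter:  ", paste(names(cts$kept_after_reference_filter),
                                     unlist(cts$kept_after_reference_filter),
                                     collapse = ", "), "\n")
  cat("  predicted pairs:   ", paste(names(cts$pairs_predicted),
                                     unlist(cts$pairs_predicted), collapse = ", "), "\n")
  cat("  ceRNA triads:      ", cts$triads, "\n")
  cat("  hypo-up genes:     ", cts$hypo_up_genes, "\n")
  invisible(x)
}
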