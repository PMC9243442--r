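# Cross-layer Pearson correlation pairs, threshold rules, intersection
# with miRNA target predictions, and ceRNA triad assembly.

pair_types <- function() c("mirna_mrna", "mirna_lncrna", "lncrna_mrna")

#' All cross-layer Pearson correlation pairs
#'
#' Correlates every feature of `source` with every feature of `target`
#' across all shared samples (cases and controls pooled). The p-value comes
#' from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom, two-sided; the `fdr` column is the BH
#' adjustment over all pairs of the call. Constant feature rows (undefined
#' correlation) are skipped with a log line.
#'
#' @param source,target `omics_tbl`s sharing the same samples in the same
#'   order. For `pair_type` `"mirna_mrna"` and `"mirna_lncrna"` the source
#'   is the miRNA layer; for `"lncrna_mrna"` it is the lncRNA layer.
#' @param pair_type One of `"mirna_mrna"`, `"mirna_lncrna"`, `"lncrna_mrna"`.
#' @return A tibble with `source_id`, `target_id`, `pair_type`, `r`, `p`,
#'   `fdr`, `predicted` (`NA` until intersected with predictions).
#' @export
pearson_pairs <- function(source, target, pair_type) {
  pair_type <- match.arg(pair_type, pair_types())
  if (!identical(omics_samples(source), omics_samples(target))) {
    abort("source and target matrices must share the same samples in the same order")
  }
  n <- length(omics_samples(source))
  if (n < 3) abort("correlation needs at least 3 shared samples")
  ms <- omics_values(source); mt <- omics_values(target)
  sd_s <- apply(ms, 1, stats::sd); sd_t <- apply(mt, 1, stats::sd)
  n_const <- sum(sd_s == 0) + sum(sd_t == 0)
  if (n_const > 0) {
    log_info("pearson_pairs: skipped pairs involving %d constant feature row(s)", n_const)
  }
  ms <- ms[sd_s > 0, , drop = FALSE]; mt <- mt[sd_t > 0, , drop = FALSE]
  if (nrow(ms) == 0 || nrow(mt) == 0) {
    return(tibble(source_id = character(), target_id = character(),
                  pair_type = character(), r = numeric(), p = numeric(),
                  fdr = numeric(), predicted = logical()))
  }
  r <- cor(t(ms), t(mt))
  out <- tibble(
    source_id = rep(rownames(r), times = ncol(r)),
    target_id = rep(colnames(r), each = nrow(r)),
    pair_type = pair_type,
    r = as.vector(r)
  )
  out$r <- pmin(pmax(out$r, -1), 1)
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * pt(-abs(tstat), n - 2)
  out$p[abs(out$r) == 1] <- 0
  out$fdr <- bh_adjust(out$p)
  out$predicted <- NA
  out
}

#' Apply the correlation threshold rules per pair type
#'
#' miRNA--mRNA pairs keep a strong negative correlation (`r < -0.5`,
#' `p < 0.05`); miRNA--lncRNA pairs keep a strong correlation of either sign
#' (`|r| > 0.5`, `p < 0.05`); lncRNA--mRNA confirmation pairs keep a strong
#' positive correlation (`r > 0.5`, `p < 0.05`). Boundary values
#' (`r = +/-0.5` exactly) are excluded. `alpha_on = "fdr"` applies the 0.05
#' cutoff to the BH-adjusted column instead of the raw p-value.
#'
#' @param pairs Output of [pearson_pairs()].
#' @param alpha Significance cutoff (strict `<`).
#' @param alpha_on Apply `alpha` to `"p"` (default) or `"fdr"`.
#' @return The retained pairs.
#' @export
threshold_pairs <- function(pairs, alpha = 0.05, alpha_on = c("p", "fdr")) {
  alpha_on <- match.arg(alpha_on)
  if (!nrow(pairs)) return(pairs)
  type <- unique(pairs$pair_type)
  if (length(type) != 1 || !type %in% pair_types()) {
    abort("pairs must carry a single known pair_type")
  }
  pv <- pairs[[alpha_on]]
  keep <- switch(type,
    mirna_mrna = pairs$r < -0.5,
    mirna_lncrna = abs(pairs$r) > 0.5,
    lncrna_mrna = pairs$r > 0.5
  ) & pv < alpha
  pairs[keep, , drop = FALSE]
}

#' Intersect correlated miRNA pairs with target predictions
#'
#' Keeps only correlation pairs whose (miRNA, target) combination appears in
#' the prediction table, setting `predicted = TRUE`; the counts of
#' correlated-only, predicted-only and intersecting pairs (the Venn of the
#' two evidence circles) are logged.
#'
#' @param pairs Thresholded miRNA-source pairs.
#' @param predictions A prediction tibble (see [read_target_predictions()]).
#' @return The prediction-supported pairs.
#' @export
intersect_with_predictions <- function(pairs, predictions) {
  pred_keys <- paste(predictions$mirna_id, predictions$target_id, sep = "\r")
  pair_keys <- paste(pairs$source_id, pairs$target_id, sep = "\r")
  hit <- pair_keys %in% pred_keys
  log_info("prediction intersect: %d correlated-only, %d predicted-only, %d in both",
           sum(!hit), length(setdiff(pred_keys, pair_keys)), sum(hit))
  out <- pairs[hit, , drop = FALSE]
  out$predicted <- rep(TRUE, nrow(out))
  out
}

#' Assemble ceRNA triads from thresholded, prediction-supported pairs
#'
#' For every miRNA shared between the two edge lists, emits one
#' (lncRNA, miRNA, mRNA) triad per combination of a negatively correlated,
#' predicted sponge lncRNA and a negatively correlated, predicted target
#' mRNA. Positive-r miRNA--lncRNA edges, although retained by the
#' thresholding step, are not sponge candidates and never enter triads.
#' With `require_lncrna_mrna_edge = TRUE` a positive lncRNA--mRNA
#' confirmation edge must also exist.
#'
#' @param mm_pairs Prediction-supported miRNA--mRNA pairs.
#' @param ml_pairs Prediction-supported miRNA--lncRNA pairs.
#' @param lm_pairs Optional thresholded lncRNA--mRNA pairs.
#' @param require_lncrna_mrna_edge Require the confirmation edge?
#' @return A tibble sorted by (mirna_id, lncrna_id, mrna_id) with the two
#'   supporting edges' statistics, of class `cerna_triads`.
#' @export
assemble_cerna_triads <- function(mm_pairs, ml_pairs, lm_pairs = NULL,
                                  require_lncrna_mrna_edge = FALSE) {
  mm <- mm_pairs[mm_pairs$r < 0 & mm_pairs$predicted %in% TRUE, , drop = FALSE]
  ml <- ml_pairs[ml_pairs$r < 0 & ml_pairs$predicted %in% TRUE, , drop = FALSE]
  triads <- dplyr::inner_join(
    tibble(mirna_id = ml$source_id, lncrna_id = ml$target_id,
           r_mirna_lncrna = ml$r, p_mirna_lncrna = ml$p, fdr_mirna_lncrna = ml$fdr),
    tibble(mirna_id = mm$source_id, mrna_id = mm$target_id,
           r_mirna_mrna = mm$r, p_mirna_mrna = mm$p, fdr_mirna_mrna = mm$fdr),
    by = "mirna_id", relationship = "many-to-many"
  )
  if (require_lncrna_mrna_edge) {
    if (is.null(lm_pairs)) abort("confirmation requested but no lncRNA--mRNA pairs given")
    lm <- lm_pairs[lm_pairs$r > 0, , drop = FALSE]
    triads <- dplyr::inner_join(
      triads,
      tibble(lncrna_id = lm$source_id, mrna_id = lm$target_id,
             r_lncrna_mrna = lm$r, p_lncrna_mrna = lm$p, fdr_lncrna_mrna = lm$fdr),
      by = c("lncrna_id", "mrna_id")
    )
  }
  triads <- triads[order(triads$mirna_id, triads$lncrna_id, triads$mrna_id,
                         method = "radix"), , drop = FALSE]
  triads <- dplyr::relocate(triads, "lncrna_id", "mirna_id", "mrna_id")
  class(triads) <- c("cerna_triads", class(triads))
  triads
}
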