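# Two-group differential expression / differential methylation:
# pooled-variance Student t per feature (optionally with moderated,
# shrunken variances), Benjamini-Hochberg adjustment, and up/down calls
# from adjusted p and effect-size thresholds.

#' Per-feature two-sample Student t-test
#'
#' Equal-variance two-sided t-test of case versus control for every feature,
#' on the log2 scale. The effect is `mean(case) - mean(control)` (a log2
#' fold change for expression data, a delta-beta for methylation data).
#' With `moderated = TRUE` the per-feature variances are shrunk toward the
#' across-feature mean variance with a fixed prior degree of freedom before
#' forming the statistic — the empirical-Bayes style stabilization used by
#' microarray DE frameworks — and the t degrees of freedom grow by
#' `prior_df`. Features constant and equal in both groups get statistic 0
#' and p 1; otherwise a variance floor of 1e-12 guards against division by
#' zero.
#'
#' @param x An `omics_tbl`.
#' @param samples Sample sheet with groups `case`/`control` (at least two
#'   samples each).
#' @param moderated Shrink variances toward the common value?
#' @param prior_df Prior degrees of freedom for the shrinkage.
#' @return A tibble with `feature_id`, `effect`, `statistic`, `df`, `p` and
#'   BH-adjusted `adj_p`.
#' @export
student_t_de <- function(x, samples, moderated = FALSE, prior_df = 4) {
  samples <- validate_sample_sheet(samples, x)
  m <- omics_values(x)
  cases <- intersect(colnames(m), group_samples(samples, "case"))
  ctrls <- intersect(colnames(m), group_samples(samples, "control"))
  n1 <- length(cases); n2 <- length(ctrls)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")
  m1 <- m[, cases, drop = FALSE]; m2 <- m[, ctrls, drop = FALSE]
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  if (moderated) {
    s2 <- (prior_df * mean(s2) + df * s2) / (prior_df + df)
    df <- df + prior_df
  }
  effect <- mu1 - mu2
  denom <- sqrt(pmax(s2, 1e-12) * (1 / n1 + 1 / n2))
  statistic <- effect / denom
  # both groups constant with equal means: no evidence either way
  flat <- s2 == 0 & effect == 0
  statistic[flat] <- 0
  p <- 2 * pt(-abs(statistic), df)
  p[flat] <- 1
  tibble(feature_id = rownames(m), effect = unname(effect),
         statistic = unname(statistic), df = df, p = unname(p),
         adj_p = bh_adjust(unname(p)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1 and returned in the
#' input order. Equal p-values receive equal adjusted values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential results into up / down / not significant
#'
#' A feature is called `up` when its BH-adjusted p-value is below
#' `adj_p_max` (strict) and its effect is at least `log2(min_fold_change)`
#' (non-strict); `down` symmetrically; otherwise `not_significant`. For
#' methylation results pass the delta-beta threshold directly via
#' `min_effect`.
#'
#' @param results A tibble from [student_t_de()] carrying `effect` and `adj_p`.
#' @param adj_p_max Adjusted p-value cutoff (strict `<`).
#' @param min_fold_change Fold-change cutoff on the natural scale; the
#'   comparison is `|effect| >= log2(min_fold_change)`.
#' @param min_effect Effect cutoff on the log2 (or delta-beta) scale;
#'   overrides `min_fold_change` when given.
#' @return The input with a `call` column added.
#' @export
classify_de <- function(results, adj_p_max = 0.05, min_fold_change = 2.0,
                        min_effect = NULL) {
  if (!all(c("effect", "adj_p") %in% names(results))) {
    abort("results must carry `effect` and `adj_p`")
  }
  cut <- min_effect %||% log2(min_fold_change)
  results$call <- dplyr::case_when(
    results$adj_p < adj_p_max & results$effect >= cut ~ "up",
    results$adj_p < adj_p_max & results$effect <= -cut ~ "down",
    .default = "not_significant"
  )
  class(results) <- c("de_result", class(results))
  results
}

#' Differential methylation on beta values
#'
#' Applies the same two-group t machinery to beta values; the effect is the
#' delta-beta `mean(case) - mean(control)`, and calls use
#' `|delta-beta| >= min_delta_beta` together with the adjusted p cutoff.
#' Hypomethylated genes are the `down` calls.
#'
#' @param x A methylation `omics_tbl` (values in `[0, 1]`).
#' @inheritParams student_t_de
#' @param adj_p_max,min_delta_beta Call thresholds.
#' @return A tibble with `feature_id`, `effect` (delta-beta), `statistic`,
#'   `df`, `p`, `adj_p` and `call`.
#' @export
differential_methylation <- function(x, samples, adj_p_max = 0.05,
                                     min_delta_beta = 0.2,
                                     moderated = FALSE, prior_df = 4) {
  if (!identical(omics_layer(x), "methylation")) {
    abort("expected a methylation omics_tbl")
  }
  res <- student_t_de(x, samples, moderated = moderated, prior_df = prior_df)
  classify_de(res, adj_p_max = adj_p_max, min_effect = min_delta_beta)
}
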