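# Tissue-confound filtering against a paired reference cohort: a feature
# that differs between normal hippocampus and cortex is flagged, and
# cohort-differential features carrying such a flag are removed — their
# case-vs-control difference is explained by tissue site, not disease.

#' Paired tests of reference hippocampus-vs-cortex expression
#'
#' For every feature, computes the within-pair differences (first group
#' minus second, in sheet order), tests them for normality with
#' Shapiro-Wilk, and applies a two-sided paired t-test when the differences
#' look normal (`normality p >= normality_alpha`) or a two-sided Wilcoxon
#' signed-rank test otherwise (zero differences dropped; exact p for up to
#' 25 non-zero pairs, normal approximation with continuity correction
#' above). All-zero differences give p = 1 on the Wilcoxon branch.
#'
#' @param reference Data frame with `feature_id` plus one numeric column per
#'   reference sample.
#' @param samples Sheet with `sample_id`, `group` (two tissue labels) and
#'   `pair_id` mapping samples one-to-one across the tissues.
#' @param normality_alpha Shapiro-Wilk cutoff for choosing the t branch.
#' @param alpha Significance cutoff on the (raw) paired p-value.
#' @return A tibble with `feature_id`, `test_used`, `normality_p`, `p`,
#'   `significant`.
#' @export
paired_reference_test <- function(reference, samples, normality_alpha = 0.05,
                                  alpha = 0.05) {
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group", "pair_id") %in% names(samples))) {
    abort("reference sheet needs columns sample_id, group, pair_id")
  }
  tissues <- unique(samples$group)
  if (length(tissues) != 2) abort("reference sheet must contain exactly 2 tissues")
  a <- samples[samples$group == tissues[1], ]
  b <- samples[samples$group == tissues[2], ]
  b <- b[match(a$pair_id, b$pair_id), ]
  if (nrow(a) != nrow(b) || anyNA(b$sample_id) ||
      anyDuplicated(a$pair_id) || anyDuplicated(b$pair_id)) {
    abort("pair_id must map samples one-to-one across the two tissues")
  }
  if (nrow(a) < 3) abort("paired tests need at least 3 complete pairs")
  reference <- as_tibble(reference)
  m <- as.matrix(reference[, setdiff(names(reference), "feature_id")])
  rownames(m) <- reference$feature_id
  d <- m[, a$sample_id, drop = FALSE] - m[, b$sample_id, drop = FALSE]

  one <- function(di) {
    if (all(di == 0)) {
      return(list(test_used = "wilcoxon_signed_rank", normality_p = NA_real_, p = 1))
    }
    norm_p <- tryCatch(stats::shapiro.test(di)$p.value,
                       error = function(e) NA_real_)
    if (!is.na(norm_p) && norm_p >= normality_alpha) {
      list(test_used = "paired_t", normality_p = norm_p,
           p = stats::t.test(di)$p.value)
    } else {
      dnz <- di[di != 0]
      p <- suppressWarnings(stats::wilcox.test(
        dnz, exact = length(dnz) <= 25, correct = TRUE)$p.value)
      list(test_used = "wilcoxon_signed_rank", normality_p = norm_p, p = p)
    }
  }
  res <- apply(d, 1, one)
  n_zero <- sum(map_dbl(res, "p") == 1 & map_chr(res, "test_used") == "wilcoxon_signed_rank" &
                  is.na(map_dbl(res, "normality_p")))
  if (n_zero > 0) log_info("reference test: %d feature(s) with all-zero paired differences", n_zero)
  p_vec <- unname(map_dbl(res, "p"))
  tibble(
    feature_id = rownames(d),
    test_used = unname(map_chr(res, "test_used")),
    normality_p = unname(map_dbl(res, "normality_p")),
    p = p_vec,
    significant = p_vec < alpha
  )
}

#' Keep cohort-differential features not explained by tissue site
#'
#' Retains features called `up` or `down` in the study cohort whose paired
#' reference test was not significant. Features absent from the reference
#' are kept but flagged `unmeasured` when `keep_unmeasured = TRUE` (the
#' default), or dropped otherwise.
#'
#' @param cohort_de Classified DE results (see [classify_de()]).
#' @param reference_tests Output of [paired_reference_test()].
#' @param keep_unmeasured Keep cohort features missing from the reference?
#' @return A tibble of kept features with `feature_id`, `call`,
#'   `reference_p` and `reference_status` (`not_tissue_differential` or
#'   `unmeasured`).
#' @export
filter_cohort_specific <- function(cohort_de, reference_tests,
                                   keep_unmeasured = TRUE) {
  sig <- cohort_de[cohort_de$call %in% c("up", "down"),
                   c("feature_id", "effect", "call")]
  joined <- dplyr::left_join(
    sig,
    reference_tests[c("feature_id", "p", "significant")],
    by = "feature_id"
  )
  joined$reference_status <- dplyr::case_when(
    is.na(joined$significant) ~ "unmeasured",
    joined$significant ~ "tissue_differential",
    .default = "not_tissue_differential"
  )
  keep <- joined$reference_status == "not_tissue_differential" |
    (joined$reference_status == "unmeasured" & keep_unmeasured)
  log_info("reference filter: %d of %d cohort-differential feature(s) kept (%d tissue-confounded removed, %d unmeasured)",
           sum(keep), nrow(joined),
           sum(joined$reference_status == "tissue_differential"),
           sum(joined$reference_status == "unmeasured"))
  out <- joined[keep, c("feature_id", "effect", "call", "p", "reference_status")]
  names(out)[names(out) == "p"] <- "reference_p"
  as_tibble(out)
}
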