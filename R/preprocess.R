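# Probe filtering, quantile normalization and log2 transformation.

#' Filter probes by chromosome and detection rate
#'
#' Removes features annotated on a sex chromosome (`chrX`/`chrY`; features
#' with unknown or missing annotation are kept — the filter only removes
#' what is provably on a sex chromosome) and, when a detection matrix is
#' supplied, features detected in strictly less than `min_detection` of
#' samples. Row order is preserved and the operation is idempotent.
#'
#' @param x An `omics_tbl`.
#' @param annotation Feature annotation (see [validate_annotation()]);
#'   features absent from it are treated as chromosome `unknown`.
#' @param detection Optional logical/0-1 data frame with the same shape and
#'   ids as `x` (`feature_id` column plus one column per sample), `TRUE`
#'   where the probe was detected.
#' @param min_detection Detection-rate cutoff; comparison is strict (a
#'   feature detected in exactly `min_detection` of samples is kept).
#' @return The filtered `omics_tbl`.
#' @export
filter_probes <- function(x, annotation, detection = NULL, min_detection = 0.60) {
  annotation <- validate_annotation(annotation)
  chr <- annotation$chromosome[match(x$feature_id, annotation$feature_id)]
  chr[is.na(chr)] <- "unknown"
  drop_sex <- chr %in% c("chrX", "chrY")
  drop_det <- rep(FALSE, nrow(x))
  if (!is.null(detection)) {
    detection <- as_tibble(detection)
    if (!identical(detection$feature_id, x$feature_id) ||
        !identical(setdiff(names(detection), "feature_id"), omics_samples(x))) {
      abort("detection matrix must have the same feature and sample ids as the expression matrix")
    }
    d <- as.matrix(detection[omics_samples(x)])
    storage.mode(d) <- "double"
    drop_det <- rowMeans(d) < min_detection
  }
  log_info("probe filter: removed %d sex-chromosome and %d low-detection feature(s) of %d",
           sum(drop_sex), sum(drop_det & !drop_sex), nrow(x))
  restore_omics(x[!(drop_sex | drop_det), , drop = FALSE], x)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common reference distribution: the vector of
#' row-wise means of the sorted columns. After normalization each column's
#' sorted values equal that reference; tied values within a column receive
#' the mean of the reference values over their tied positions.
#'
#' Methylation beta matrices are not accepted — beta values are analyzed on
#' their natural `[0, 1]` scale.
#'
#' @param x An `omics_tbl` with at least two samples and no missing values.
#' @return The normalized `omics_tbl`.
#' @export
quantile_normalize <- function(x) {
  if (identical(omics_layer(x), "methylation")) {
    abort("methylation beta values are not quantile-normalized")
  }
  m <- omics_values(x)
  if (ncol(m) < 2) abort("quantile normalization needs at least 2 samples")
  if (anyNA(m)) abort("missing values are not allowed")
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    vals <- ref[rank(col, ties.method = "first")]
    # tied input values share the mean reference value over their positions
    stats::ave(vals, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  as_omics_tbl(out, omics_layer(x))
}

#' Log2-transform an expression matrix
#'
#' @param x An `omics_tbl`.
#' @param offset Added before taking logs (default 1); every value plus
#'   offset must be positive.
#' @param already_log2 When `TRUE` the input is declared to be on the log2
#'   scale already and is returned unchanged.
#' @return The transformed `omics_tbl`.
#' @export
log2_transform <- function(x, offset = 1.0, already_log2 = FALSE) {
  if (already_log2) return(x)
  m <- omics_values(x)
  if (any(m + offset <= 0)) {
    bad <- which(m + offset <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("value %g + offset %g is not positive (feature '%s', sample '%s')",
                  m[bad[1], bad[2]], offset, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  as_omics_tbl(log2(m + offset), omics_layer(x))
}
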