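#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom rlang abort warn inform .data %||%
#' @importFrom purrr map map_chr map_dbl map_int map2 imap pmap
#' @importFrom stats cor p.adjust pt phyper rnorm runif setNames
#' @importFrom utils head
NULL

# Molecular layers handled by the pipeline.  `methylation` carries beta
# values in [0, 1]; the three expression layers carry log2 intensities.
omics_layers <- function() c("mRNA", "miRNA", "lncRNA", "methylation")

# Closed chromosome vocabulary for feature annotations.
chromosome_levels <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY", "chrM", "unknown")
}

log_info <- function(...) message("INFO: ", sprintf(...))

#' Construct a feature-by-sample omics table
#'
#' An `omics_tbl` is a tibble whose first column, `feature_id`, holds unique
#' feature identifiers and whose remaining columns hold one numeric vector per
#' sample. The molecular layer (`mRNA`, `miRNA`, `lncRNA` or `methylation`)
#' travels with the table as an attribute; methylation tables must contain
#' beta values in `[0, 1]`.
#'
#' @param x A data frame with a `feature_id` column followed by one numeric
#'   column per sample, or a numeric matrix with feature row names and sample
#'   column names.
#' @param layer One of `"mRNA"`, `"miRNA"`, `"lncRNA"`, `"methylation"`.
#' @return A tibble of class `omics_tbl` with a `layer` attribute.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2, dimnames = list(paste0("g", 1:3), c("S1", "S2")))
#' x <- as_omics_tbl(m, layer = "mRNA")
#' omics_layer(x)
#' @export
as_omics_tbl <- function(x, layer) {
  layer <- match.arg(layer, omics_layers())
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs feature row names and sample column names")
    }
    x <- tibble::as_tibble(x, rownames = "feature_id")
  }
  x <- tibble::as_tibble(x)
  if (!identical(names(x)[1], "feature_id")) {
    abort("first column must be `feature_id`")
  }
  x$feature_id <- as.character(x$feature_id)
  out <- structure(x, layer = layer, class = c("omics_tbl", class(x)))
  validate_omics_tbl(out)
  out
}

#' @rdname as_omics_tbl
#' @export
omics_layer <- function(x) attr(x, "layer", exact = TRUE)

#' @rdname as_omics_tbl
#' @export
omics_features <- function(x) x$feature_id

#' @rdname as_omics_tbl
#' @export
omics_samples <- function(x) setdiff(names(x), "feature_id")

#' Extract the numeric value matrix of an omics table
#'
#' @param x An `omics_tbl` (or any data frame shaped like one).
#' @return A numeric matrix, features in rows (named), samples in columns.
#' @export
omics_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "feature_id"), drop = FALSE])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

validate_omics_tbl <- function(x, what = "expression matrix") {
  if (length(omics_samples(x)) == 0) {
    abort(sprintf("%s has no sample columns", what))
  }
  if (anyDuplicated(x$feature_id)) {
    dup <- unique(x$feature_id[duplicated(x$feature_id)])
    abort(sprintf("duplicate feature ids in %s: %s", what,
                  paste(head(dup, 5), collapse = ", ")))
  }
  smp <- omics_samples(x)
  if (anyDuplicated(smp)) {
    abort(sprintf("duplicate sample ids in %s", what))
  }
  vals <- x[smp]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric sample column(s) in %s: %s", what,
                  paste(smp[bad], collapse = ", ")))
  }
  if (anyNA(vals)) {
    abort(sprintf("missing values are not allowed in %s", what))
  }
  layer <- omics_layer(x)
  if (identical(layer, "methylation")) {
    m <- omics_values(x)
    out_of_range <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(out_of_range)) {
      i <- out_of_range[1, 1]; j <- out_of_range[1, 2]
      abort(sprintf(
        "methylation beta values must lie in [0, 1]; offending cell: feature '%s', sample '%s' (value %g)",
        rownames(m)[i], colnames(m)[j], m[i, j]))
    }
  }
  invisible(x)
}

# Rebuild the omics_tbl class/layer after dplyr verbs that strip attributes.
restore_omics <- function(x, template) {
  as_omics_tbl(as_tibble(x), layer = omics_layer(template))
}

#' Validate a sample sheet against one or more omics tables
#'
#' A sample sheet maps `sample_id` to `group` and, for paired reference
#' designs, a `pair_id` linking each sample to its partner in the other
#' group. For unpaired two-group tests both groups must have at least two
#' samples.
#'
#' @param samples A data frame with columns `sample_id`, `group` and
#'   optionally `pair_id`.
#' @param matrix Optional `omics_tbl` whose samples must all be covered.
#' @param groups Expected group labels (default `c("case", "control")`);
#'   `NULL` skips the check (paired reference sheets use tissue labels).
#' @param min_per_group Minimum samples per group.
#' @return The sheet as a tibble, invisibly validated.
#' @export
validate_sample_sheet <- function(samples, matrix = NULL,
                                  groups = c("case", "control"),
                                  min_per_group = 2) {
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("sample sheet needs columns `sample_id` and `group`")
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample ids in sample sheet")
  }
  if (!is.null(groups) && !all(samples$group %in% groups)) {
    abort(sprintf("sample groups must be in {%s}", paste(groups, collapse = ", ")))
  }
  tab <- table(samples$group)
  if (length(tab) < 2 || any(tab < min_per_group)) {
    abort(sprintf("need at least %d samples in each of two groups", min_per_group))
  }
  if (!is.null(matrix)) {
    missing <- setdiff(omics_samples(matrix), samples$sample_id)
    if (length(missing)) {
      abort(sprintf("samples missing from sheet: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  samples
}

# Split sample ids by group, preserving sheet order.
group_samples <- function(samples, group) {
  samples$sample_id[samples$group == group]
}
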