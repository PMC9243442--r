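# Readers and writers for the plain-text formats the pipeline exchanges:
# TSV feature-by-sample matrices, sample sheets, GMT gene-set collections,
# miRNA target-prediction tables and network edge lists.  All readers
# validate strictly; all writers produce byte-reproducible output.

#' Read a feature-by-sample expression or methylation matrix from TSV
#'
#' The file must be tab-separated with a header row of sample ids and the
#' feature id in the first column. Values are parsed as decimal numbers
#' (`NA` is rejected); methylation matrices must contain beta values in
#' `[0, 1]` and violations are reported by cell.
#'
#' @param path Path to a TSV file.
#' @param layer Molecular layer tag; see [as_omics_tbl()].
#' @return An [as_omics_tbl()] tibble.
#' @export
read_expression_matrix <- function(path, layer) {
  layer <- match.arg(layer, omics_layers())
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort(sprintf("'%s': no sample columns", path))
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("'%s': duplicate sample ids in header", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (nrow(raw) == 0) abort(sprintf("'%s': empty matrix", path))
  names(raw)[1] <- "feature_id"
  for (s in sample_ids) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("'%s': non-numeric value '%s' at feature '%s', sample '%s'",
                    path, raw[[s]][bad[1]], raw$feature_id[bad[1]], s))
    }
    raw[[s]] <- v
  }
  as_omics_tbl(raw, layer = layer)
}

#' Write an omics table to TSV
#'
#' Values round-trip at full double precision through
#' [read_expression_matrix()].
#'
#' @param x An `omics_tbl`.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Expected columns: `sample_id`, `group`, optional `pair_id`.
#'
#' @param path Path to a TSV file.
#' @param groups Passed to [validate_sample_sheet()].
#' @return A tibble.
#' @export
read_sample_sheet <- function(path, groups = c("case", "control")) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  validate_sample_sheet(sheet, groups = groups)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name TAB description TAB member...`. Duplicate members
#' within a line are removed with a warning; a line with fewer than three
#' fields is a format error reported with its line number.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description` and a list-column
#'   `genes`.
#' @seealso [gene_set_list()] to convert to a plain named list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("'%s': empty GMT file", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("'%s': line %d has %d field(s); GMT needs name, description and at least one member",
                  path, which(n_fields < 3)[1], n_fields[which(n_fields < 3)[1]]))
  }
  sets <- tibble(
    set_name = map_chr(fields, 1),
    description = map_chr(fields, 2),
    genes = map(fields, ~ .x[-(1:2)])
  )
  n_dup <- sum(map_int(sets$genes, ~ sum(duplicated(.x))))
  if (n_dup > 0) {
    warn(sprintf("'%s': removed %d duplicate member(s) within sets", path, n_dup))
    sets$genes <- map(sets$genes, unique)
  }
  if (anyDuplicated(sets$set_name)) {
    abort(sprintf("'%s': duplicate set names", path))
  }
  sets
}

#' @rdname read_gmt
#' @param collection A tibble as returned by [read_gmt()] (or a named list,
#'   returned unchanged).
#' @export
gene_set_list <- function(collection) {
  if (is.list(collection) && !is.data.frame(collection)) {
    if (length(collection) && is.null(names(collection))) {
      abort("gene-set list must be named")
    }
    return(collection)
  }
  setNames(collection$genes, collection$set_name)
}

#' Write a gene-set collection to GMT
#'
#' @param collection Tibble as from [read_gmt()] or a named list of members.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  sets <- gene_set_list(collection)
  desc <- if (is.data.frame(collection)) collection$description else rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA target-prediction table
#'
#' TSV with columns `mirna_id`, `target_id`, `target_layer` (`mRNA` or
#' `lncRNA`) and `n_sources` (number of prediction databases supporting the
#' pair, at least 1). Rows supported by fewer than `min_sources` databases
#' are dropped, with the count logged.
#'
#' @param path Path to a TSV file.
#' @param min_sources Minimum database support to keep a row.
#' @return A tibble with the four columns above.
#' @export
read_target_predictions <- function(path, min_sources = 1) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    target_id = readr::col_character(),
    target_layer = readr::col_character(),
    n_sources = readr::col_integer()
  ), progress = FALSE)
  validate_target_predictions(tab, min_sources = min_sources)
}

#' @rdname read_target_predictions
#' @param predictions A data frame to validate in place of a file.
#' @export
validate_target_predictions <- function(predictions, min_sources = 1) {
  tab <- as_tibble(predictions)
  need <- c("mirna_id", "target_id", "target_layer", "n_sources")
  if (!all(need %in% names(tab))) {
    abort(sprintf("prediction table needs columns: %s", paste(need, collapse = ", ")))
  }
  bad_layer <- setdiff(unique(tab$target_layer), c("mRNA", "lncRNA"))
  if (length(bad_layer)) {
    abort(sprintf("unknown target_layer value(s): %s", paste(bad_layer, collapse = ", ")))
  }
  if (any(tab$n_sources < 1)) abort("n_sources must be >= 1")
  if (anyDuplicated(tab[c("mirna_id", "target_id")])) {
    abort("duplicate (mirna_id, target_id) rows in prediction table")
  }
  n_drop <- sum(tab$n_sources < min_sources)
  if (n_drop > 0) {
    log_info("dropped %d prediction(s) with fewer than %d supporting sources",
             n_drop, min_sources)
    tab <- tab[tab$n_sources >= min_sources, ]
  }
  tab
}

#' Write a correlation-pair or triad edge list to TSV
#'
#' Output columns are `source`, `target`, `edge_type`, `r`, `p`, `fdr`,
#' `predicted_support`, ordered by decreasing `|r|` with lexicographic
#' (source, target) tie-breaking so repeated runs are byte-identical.
#' A triad table is expanded to its two supporting edges.
#'
#' @param edges A correlation-pair tibble (see [pearson_pairs()]) or a triad
#'   tibble (see [assemble_cerna_triads()]).
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as_tibble(edges)
  if (all(c("lncrna_id", "mirna_id", "mrna_id") %in% names(edges))) {
    edges <- triads_to_edges(edges)
  }
  out <- tibble(
    source = edges$source_id,
    target = edges$target_id,
    edge_type = edges$pair_type,
    r = edges$r,
    p = edges$p,
    fdr = edges$fdr,
    predicted_support = as.logical(edges$predicted %||% rep(NA, nrow(edges)))
  )
  out <- out[order(-abs(out$r), out$source, out$target, method = "radix"), ]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

triads_to_edges <- function(triads) {
  dplyr::bind_rows(
    tibble(source_id = triads$mirna_id, target_id = triads$mrna_id,
           pair_type = "mirna_mrna", r = triads$r_mirna_mrna,
           p = triads$p_mirna_mrna, fdr = triads$fdr_mirna_mrna,
           predicted = TRUE),
    tibble(source_id = triads$mirna_id, target_id = triads$lncrna_id,
           pair_type = "mirna_lncrna", r = triads$r_mirna_lncrna,
           p = triads$p_mirna_lncrna, fdr = triads$fdr_mirna_lncrna,
           predicted = TRUE)
  ) |> dplyr::distinct()
}

#' Validate a feature annotation table
#'
#' Columns `feature_id`, `chromosome`, `layer`. The chromosome vocabulary is
#' closed (`chr1`..`chr22`, `chrX`, `chrY`, `chrM`, `unknown`); features not
#' listed are treated as `unknown` by the probe filter.
#'
#' @param annotation A data frame.
#' @return A validated tibble.
#' @export
validate_annotation <- function(annotation) {
  ann <- as_tibble(annotation)
  need <- c("feature_id", "chromosome", "layer")
  if (!all(need %in% names(ann))) {
    abort(sprintf("annotation needs columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ann$feature_id)) abort("duplicate feature ids in annotation")
  bad <- setdiff(unique(ann$chromosome), chromosome_levels())
  if (length(bad)) {
    abort(sprintf("unknown chromosome value(s): %s", paste(bad, collapse = ", ")))
  }
  bad_layer <- setdiff(unique(ann$layer), omics_layers())
  if (length(bad_layer)) {
    abort(sprintf("unknown layer value(s): %s", paste(bad_layer, collapse = ", ")))
  }
  ann
}
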