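# Nine-quadrant integration of differential methylation with differential
# expression: genes are cross-classified by methylation state (hypo / none /
# hyper, rows) and expression state (down / none / up, columns) into a
# fixed 3x3 grid, quadrant = 3*row + column + 1.  The hypo-up cell
# (quadrant 3) flags candidate epigenetically activated genes.

#' Nine-quadrant methylation-expression classification
#'
#' Matches genes between the differential-methylation and
#' differential-expression results (intersection by id; mismatches are
#' logged), maps the methylation call to `hypo`/`none`/`hyper` and the
#' expression call to `down`/`none`/`up`, and assigns each matched gene its
#' quadrant in the fixed grid.
#'
#' @param dm Classified differential-methylation results
#'   ([differential_methylation()]).
#' @param de Classified differential-expression results ([classify_de()]).
#' @return A tibble of class `quadrant_result` with `gene_id`, `delta_beta`,
#'   `expr_effect`, `meth_state`, `expr_state`, `quadrant`.
#' @export
nine_quadrant <- function(dm, de) {
  for (tab in list(dm, de)) {
    if (!all(c("feature_id", "effect", "call") %in% names(tab))) {
      abort("both result tables must carry feature_id, effect and call")
    }
  }
  shared <- intersect(dm$feature_id, de$feature_id)
  n_only <- (nrow(dm) - length(shared)) + (nrow(de) - length(shared))
  if (n_only > 0) {
    log_info("nine_quadrant: %d gene(s) present in only one result table were excluded", n_only)
  }
  dm_i <- dm[match(shared, dm$feature_id), ]
  de_i <- de[match(shared, de$feature_id), ]
  meth_state <- dplyr::recode(dm_i$call, down = "hypo", up = "hyper",
                              not_significant = "none")
  expr_state <- dplyr::recode(de_i$call, not_significant = "none",
                              down = "down", up = "up")
  row_i <- match(meth_state, c("hypo", "none", "hyper")) - 1L
  col_i <- match(expr_state, c("down", "none", "up")) - 1L
  out <- tibble(
    gene_id = shared,
    delta_beta = dm_i$effect,
    expr_effect = de_i$effect,
    meth_state = meth_state,
    expr_state = expr_state,
    quadrant = 3L * row_i + col_i + 1L
  )
  class(out) <- c("quadrant_result", class(out))
  out
}

#' Select hypomethylated-upregulated candidate genes
#'
#' Returns the genes in the hypo-up quadrant, ordered by delta-beta
#' ascending so the most severely hypomethylated gene comes first.
#'
#' @param assignments Output of [nine_quadrant()].
#' @return A tibble with `gene_id`, `delta_beta`, `expr_effect`.
#' @export
select_hypomethylated_upregulated <- function(assignments) {
  hits <- assignments[assignments$meth_state == "hypo" &
                        assignments$expr_state == "up", , drop = FALSE]
  hits <- hits[order(hits$delta_beta, hits$gene_id, method = "radix"), ]
  as_tibble(hits[c("gene_id", "delta_beta", "expr_effect")])
}
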