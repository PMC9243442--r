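# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classified differential result
#'
#' @param x A `de_result` tibble.
#' @param ... Unused.
#' @return A plain tibble (one row per feature).
#' @export
tidy.de_result <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname tidy.de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         min_adj_p = min(x$adj_p))
}

#' Tidy a GSEA result
#'
#' @param x A `gsea_result` tibble.
#' @param ... Unused.
#' @return A tibble with the leading edge collapsed to a comma-separated
#'   string.
#' @export
tidy.gsea_result <- function(x, ...) {
  out <- as_tibble(unclass_result(x))
  out$leading_edge <- map_chr(out$leading_edge, paste, collapse = ",")
  out
}

#' @rdname tidy.gsea_result
#' @export
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_significant = sum(x$p < 0.05),
         n_perm = attr(x, "n_perm") %||% NA_integer_,
         weight_p = attr(x, "weight_p") %||% NA_real_)
}

#' Tidy a pipeline run
#'
#' @param x A `cerna_run`.
#' @param ... Unused.
#' @return One row per (stage, layer) count from the manifest.
#' @export
tidy.cerna_run <- function(x, ...) {
  cts <- x$manifest$counts
  per_layer <- c("features_tested", "de_calls", "kept_after_reference_filter",
                 "pairs_computed", "pairs_thresholded", "pairs_predicted")
  rows <- dplyr::bind_rows(lapply(per_layer, function(stage) {
    v <- unlist(cts[[stage]])
    tibble(stage = stage, unit = names(v), count = as.integer(v))
  }))
  dplyr::bind_rows(rows, tibble(
    stage = c("triads", "dm_calls", "hypo_up_genes"),
    unit = "total",
    count = as.integer(c(cts$triads, cts$dm_calls, cts$hypo_up_genes))
  ))
}

#' @rdname tidy.cerna_run
#' @export
glance.cerna_run <- function(x, ...) {
  cts <- x$manifest$counts
  tibble(seed = x$manifest$seed,
         triads = cts$triads,
         hypo_up_genes = cts$hypo_up_genes,
         de_mrna = cts$de_calls[["mRNA"]],
         de_mirna = cts$de_calls[["miRNA"]],
         de_lncrna = cts$de_calls[["lncRNA"]])
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("de_result", "gsea_result",
                                  "quadrant_result", "cerna_triads"))
  x
}

#' Volcano plot of a differential result
#'
#' @param object A classified `de_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(pmax(.data$adj_p, 1e-300)),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#27ae60",
                                            not_significant = "grey60")) +
    ggplot2::labs(x = "effect (log2 fold change or delta-beta)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Nine-quadrant methylation-expression plot
#'
#' @param object A `quadrant_result`.
#' @param ... Unused.
#' @return A ggplot of delta-beta against expression log2 fold change with
#'   the hypo-up quadrant highlighted.
#' @export
autoplot.quadrant_result <- function(object, ...) {
  df <- as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_beta, y = .data$expr_effect,
                                   colour = factor(.data$quadrant))) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "delta-beta (case - control)",
                  y = "expression log2 fold change", colour = "quadrant") +
    ggplot2::theme_minimal()
}

#' Normalized-enrichment-score bar chart of a GSEA result
#'
#' @param object A `gsea_result`.
#' @param top_n Number of sets to show, ordered by `|nes|`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gsea_result <- function(object, top_n = 20, ...) {
  df <- head(tidy(object), top_n)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set_name,
                                   fill = .data$p < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c3e50", `FALSE` = "grey70"),
                               labels = c(`TRUE` = "p < 0.05", `FALSE` = "ns")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one gene set
#'
#' @param ranked A [ranked_list()] tibble.
#' @param members Set members.
#' @param weight_p Weighting exponent.
#' @return A ggplot of the KS running sum with hit positions marked.
#' @export
plot_gsea_running_sum <- function(ranked, members, weight_p = 1.0) {
  es <- gsea_es(ranked, members, weight_p = weight_p)
  df <- tibble(rank = seq_len(nrow(ranked)), running = es$running_sum,
               hit = ranked$gene %in% members)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", colour = "#c0392b") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "rank", y = "running enrichment score") +
    ggplot2::theme_minimal()
}
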