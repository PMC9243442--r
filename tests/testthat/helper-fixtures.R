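# Shared fixture builders for the test suite.  Everything is constructed in
# code; no binary fixtures.

tiny_matrix <- function(values, layer = "mRNA", features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% paste0("f", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  as_omics_tbl(m, layer = layer)
}

two_group_sheet <- function(n_case, n_control,
                            ids = c(paste0("case", seq_len(n_case)),
                                    paste0("ctrl", seq_len(n_control)))) {
  tibble::tibble(sample_id = ids,
                 group = rep(c("case", "control"), c(n_case, n_control)))
}

# Independent step-up FDR computation, straight from the definition:
# sort ascending, q(i) = min_{j >= i} p(j) * m / j, cap at 1, input order.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# |query| genes from the universe and count draws with >= k set members.
hyper_by_enumeration <- function(universe, set_in_universe, query_size, k) {
  draws <- utils::combn(universe, query_size, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set_in_universe)) >= k,
              logical(1)))
}

triad_key <- function(tab) {
  paste(tab$lncrna_id, tab$mirna_id, tab$mrna_id, sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
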