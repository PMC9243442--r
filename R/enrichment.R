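# Enrichment analysis: hypergeometric over-representation, gene set
# enrichment with the weighted Kolmogorov-Smirnov running-sum statistic and
# a gene-label permutation null, and correlation-ranked guilt-by-association
# functional prediction for hub features.

#' Upper-tail hypergeometric over-representation test
#'
#' Probability of drawing at least the observed overlap when `|query|`
#' genes are drawn from the universe containing `|gene_set n universe|`
#' successes. The gene set is intersected with the universe before testing.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param gene_set Character vector of set members.
#' @param universe Character vector of background genes.
#' @return A one-row tibble with `overlap`, `set_size_in_universe`,
#'   `query_size`, `universe_size`, `p`.
#' @export
hypergeometric_ora <- function(query, gene_set, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query)) abort("query and universe must be non-empty")
  if (!all(query %in% universe)) abort("query genes must be a subset of the universe")
  set_u <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, set_u))
  p <- if (length(set_u) == 0) 1 else {
    phyper(k - 1, length(set_u), length(universe) - length(set_u),
           length(query), lower.tail = FALSE)
  }
  tibble(overlap = k, set_size_in_universe = length(set_u),
         query_size = length(query), universe_size = length(universe), p = p)
}

#' Over-representation analysis of a query list against a collection
#'
#' One hypergeometric test per set, BH-adjusted across the collection,
#' sorted by p ascending with set-name tie-breaking.
#'
#' @param query Character vector of query genes.
#' @param collection Gene sets ([read_gmt()] tibble or named list).
#' @param universe Background gene vector.
#' @return A tibble with `set_name`, the [hypergeometric_ora()] columns and
#'   `adj_p`.
#' @export
ora_batch <- function(query, collection, universe) {
  sets <- gene_set_list(collection)
  if (!length(sets)) {
    return(tibble(set_name = character(), overlap = integer(),
                  set_size_in_universe = integer(), query_size = integer(),
                  universe_size = integer(), p = numeric(), adj_p = numeric()))
  }
  out <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    dplyr::mutate(hypergeometric_ora(query, sets[[nm]], universe),
                  set_name = nm, .before = 1)
  }))
  out$adj_p <- bh_adjust(out$p)
  out[order(out$p, out$set_name, method = "radix"), ]
}

#' Build a ranked gene list
#'
#' Sorts genes by score descending; equal scores are ordered
#' lexicographically by id so the ranking is deterministic. Each gene may
#' appear only once.
#'
#' @param gene Character vector of gene ids.
#' @param score Numeric scores (e.g. correlation with a hub feature).
#' @return A tibble with `gene` and `score`, sorted.
#' @export
ranked_list <- function(gene, score) {
  if (length(gene) != length(score)) abort("gene and score lengths differ")
  if (anyDuplicated(gene)) abort("ranked list must contain each gene once")
  if (anyNA(score)) abort("ranked scores must not be missing")
  out <- tibble(gene = as.character(gene), score = as.numeric(score))
  out[order(-out$score, out$gene, method = "radix"), ]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight_p`, normalized over
#' the in-list set members, at every hit and `-1/(N - n_hits)` at every
#' miss. The enrichment score is the running-sum value of maximal absolute
#' deviation from zero (signed); the leading edge contains the members at
#' or before the extremum for a positive score, and at or after it for a
#' negative score.
#'
#' @param ranked A [ranked_list()] tibble.
#' @param members Character vector of set members.
#' @param weight_p Weighting exponent (0 = classic unweighted KS statistic).
#' @return A list with `es`, `running_sum`, `leading_edge`, `n_hits`.
#' @export
gsea_es <- function(ranked, members, weight_p = 1.0) {
  hit <- ranked$gene %in% members
  if (!any(hit)) abort("no set members present in the ranked list")
  N <- nrow(ranked)
  nh <- sum(hit)
  if (nh == N) abort("set covers the whole ranked list; misses are undefined")
  w <- abs(ranked$score)^weight_p
  step <- rep(-1 / (N - nh), N)
  denom <- sum(w[hit])
  step[hit] <- if (denom > 0) w[hit] / denom else 1 / nh
  running <- cumsum(step)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) {
    ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    ranked$gene[i_max:N][hit[i_max:N]]
  }
  list(es = es, running_sum = running, leading_edge = leading, n_hits = nh)
}

# ES only, for permutation draws: positions of hits in 1..N, weights fixed.
es_at <- function(w, hit_idx, N) {
  nh <- length(hit_idx)
  step <- rep(-1 / (N - nh), N)
  denom <- sum(w[hit_idx])
  step[hit_idx] <- if (denom > 0) w[hit_idx] / denom else 1 / nh
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' GSEA with a gene-label permutation null
#'
#' Computes the weighted KS enrichment score of every collection set
#' against the ranked list, then normalizes it against a gene-label
#' permutation null: set membership is resampled uniformly at the matched
#' in-list size `n_perm` times while the scores stay attached to their
#' positions. `nes = es / mean(|null es| of the same sign)`;
#' `p = (b + 1)/(m + 1)` where `m` counts same-sign null scores and `b`
#' those at least as extreme; `fdr` is the BH adjustment across reported
#' sets. Sets with fewer than two in-list members are skipped with a log
#' line; sets with no same-sign null draws get an undefined (NA) `nes` and
#' are flagged.
#'
#' @param ranked A [ranked_list()] tibble.
#' @param collection Gene sets ([read_gmt()] tibble or named list).
#' @param n_perm Number of permutation draws (a warning below 100).
#' @param weight_p Weighting exponent.
#' @param seed Integer seed for the permutation draws.
#' @return A tibble of class `gsea_result` with `set_name`, `es`, `nes`,
#'   `p`, `fdr`, `n_hits`, `leading_edge` (list-column), sorted by `|nes|`
#'   descending.
#' @export
gsea_permutation <- function(ranked, collection, n_perm = 1000,
                             weight_p = 1.0, seed = 1) {
  sets <- gene_set_list(collection)
  if (n_perm < 100) warn("fewer than 100 permutations gives a coarse null")
  N <- nrow(ranked)
  w <- abs(ranked$score)^weight_p
  usable <- map_int(sets, ~ sum(ranked$gene %in% .x)) >= 2
  if (any(!usable)) {
    log_info("gsea: skipped %d set(s) with fewer than 2 members in the ranked list",
             sum(!usable))
  }
  sets <- sets[usable]
  if (!length(sets)) {
    out <- tibble(set_name = character(), es = numeric(), nes = numeric(),
                  p = numeric(), fdr = numeric(), n_hits = integer(),
                  nes_defined = logical(), leading_edge = list())
    class(out) <- c("gsea_result", class(out))
    return(out)
  }
  rows <- with_seed(seed, {
    lapply(names(sets), function(nm) {
      obs <- gsea_es(ranked, sets[[nm]], weight_p = weight_p)
      k <- obs$n_hits
      null_es <- vapply(seq_len(n_perm), function(i) {
        es_at(w, sample.int(N, k), N)
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(obs$es)]
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
      tibble(set_name = nm, es = obs$es, nes = nes, p = p,
             n_hits = k, nes_defined = length(same) > 0,
             leading_edge = list(obs$leading_edge))
    })
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$nes_defined)) {
    log_info("gsea: %d set(s) had no same-sign null draws; nes undefined", sum(!out$nes_defined))
  }
  out$fdr <- bh_adjust(out$p)
  out <- dplyr::relocate(out, "fdr", .after = "p")
  out <- out[order(-abs(dplyr::coalesce(out$nes, 0)), out$set_name,
                   method = "radix"), ]
  attr(out, "n_perm") <- n_perm
  attr(out, "weight_p") <- weight_p
  class(out) <- c("gsea_result", class(out))
  out
}

#' Guilt-by-association functional prediction for a hub feature
#'
#' Ranks every mRNA by its Pearson correlation with the hub feature's
#' expression across samples (the hub itself is excluded when it is an
#' mRNA), then runs [gsea_permutation()] on that ranking. Sets
#' concentrating at the top of the ranking (positive NES) share the hub's
#' expression pattern; sets at the bottom (negative NES) anticorrelate with
#' it — for a miRNA hub, its repressed targets.
#'
#' @param hub_id Feature id of the hub.
#' @param hub_matrix `omics_tbl` containing the hub feature.
#' @param mrna_matrix mRNA `omics_tbl`, same samples in the same order.
#' @param collection Gene sets.
#' @inheritParams gsea_permutation
#' @return A `gsea_result` tibble sorted by `|nes|` descending.
#' @export
guilt_by_association <- function(hub_id, hub_matrix, mrna_matrix, collection,
                                 n_perm = 1000, weight_p = 1.0, seed = 1) {
  if (!hub_id %in% hub_matrix$feature_id) {
    abort(sprintf("hub feature '%s' not found in its matrix", hub_id))
  }
  if (!identical(omics_samples(hub_matrix), omics_samples(mrna_matrix))) {
    abort("hub and mRNA matrices must share the same samples in the same order")
  }
  hub <- as.numeric(omics_values(hub_matrix)[hub_id, ])
  if (stats::sd(hub) == 0) abort("hub expression is constant; correlation undefined")
  m <- omics_values(mrna_matrix)
  m <- m[rownames(m) != hub_id, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    log_info("guilt_by_association: dropped %d constant mRNA row(s)", sum(sds == 0))
    m <- m[sds > 0, , drop = FALSE]
  }
  r <- as.vector(cor(t(m), hub))
  ranked <- ranked_list(rownames(m), r)
  gsea_permutation(ranked, collection, n_perm = n_perm,
                   weight_p = weight_p, seed = seed)
}
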