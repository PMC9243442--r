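test_that("hypergeometric ORA equals exhaustive enumeration", {
  u <- paste0("g", 1:10)
  res <- hypergeometric_ora(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)
  # disjoint query and set: P(overlap >= 0) = 1
  expect_equal(hypergeometric_ora(u[1:3], u[4:6], u)$p, 1)
  # set disjoint from universe
  expect_equal(hypergeometric_ora(u[1:3], c("zz1", "zz2"), u)$p, 1)
  # random small cases against the enumeration oracle
  for (seed in 1:4) {
    set.seed(seed)
    universe <- paste0("g", 1:9)
    gene_set <- sample(universe, 4)
    query <- sample(universe, 3)
    k <- length(intersect(query, gene_set))
    expect_equal(hypergeometric_ora(query, gene_set, universe)$p,
                 hyper_by_enumeration(universe, gene_set, 3, k),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_ora(c("zz"), u[1:2], u), "subset")
  expect_error(hypergeometric_ora(character(0), u[1:2], u), "non-empty")
})

test_that("batch ORA adjusts across the collection and sorts by p", {
  u <- paste0("g", 1:20)
  single <- ora_batch(u[1:5], list(S1 = u[1:5]), u)
  expect_equal(single$adj_p, single$p)
  two <- ora_batch(u[1:6], list(A = u[1:6], B = c(u[1:3], u[10:16])), u)
  expect_equal(two$adj_p, bh_by_hand(two$p), tolerance = 1e-12)
  expect_true(!is.unsorted(two$p))
  empty <- ora_batch(u[1:3], list(), u)
  expect_equal(nrow(empty), 0)
})

test_that("enrichment scores reproduce the hand-walked KS sums", {
  ranked <- ranked_list(paste0("g", 1:4), c(4, 3, 2, 1))
  top <- gsea_es(ranked, "g1", weight_p = 0)
  expect_equal(top$running_sum, c(1, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(top$es, 1)
  expect_identical(top$leading_edge, "g1")
  bottom <- gsea_es(ranked, "g4", weight_p = 0)
  expect_equal(bottom$running_sum, c(-1/3, -2/3, -1, 0), tolerance = 1e-12)
  expect_equal(bottom$es, -1)
  expect_identical(bottom$leading_edge, "g4")
  weighted <- gsea_es(ranked, c("g1", "g2"), weight_p = 1)
  expect_equal(weighted$running_sum, c(4/7, 1, 1/2, 0), tolerance = 1e-12)
  expect_equal(weighted$es, 1)
  expect_identical(weighted$leading_edge, c("g1", "g2"))
  expect_error(gsea_es(ranked, "zz"), "no set members")
})

test_that("unweighted ES is antisymmetric and always bounded", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    ranked <- ranked_list(paste0("g", 1:n), rnorm(n))
    members <- sample(ranked$gene, sample(seq_len(n - 1), 1))
    es_s <- gsea_es(ranked, members, weight_p = 0)
    es_c <- gsea_es(ranked, setdiff(ranked$gene, members), weight_p = 0)
    expect_equal(es_s$running_sum, -es_c$running_sum, tolerance = 1e-12)
    expect_equal(es_s$es, -es_c$es, tolerance = 1e-12)
    # bounds hold for weighted scores too
    es_w <- gsea_es(ranked, members, weight_p = 1)
    expect_lte(abs(es_w$es), 1)
    expect_true(all(abs(es_w$running_sum) <= 1 + 1e-12))
  }
})

test_that("weighted ES agrees with the fgsea implementation", {
  set.seed(13)
  n <- 50
  stats <- sort(rnorm(n, 0, 2), decreasing = TRUE)
  ranked <- ranked_list(paste0("g", 1:n), stats)
  for (k in c(3, 10)) {
    members <- sample(ranked$gene, k)
    mine <- gsea_es(ranked, members, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(ranked$gene %in% members),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("permutation GSEA is deterministic and flags extreme sets", {
  set.seed(2)
  n <- 100
  ranked <- ranked_list(paste0("g", 1:n), seq(3, -3, length.out = n))
  coll <- list(top = ranked$gene[1:50], tiny = ranked$gene[1])
  r1 <- suppressMessages(gsea_permutation(ranked, coll, n_perm = 1000, seed = 7))
  r2 <- suppressMessages(gsea_permutation(ranked, coll, n_perm = 1000, seed = 7))
  expect_identical(r1, r2)
  expect_false("tiny" %in% r1$set_name) # <2 in-list members skipped
  top <- r1[r1$set_name == "top", ]
  expect_gt(top$nes, 1)
  expect_lte(top$p, 0.01)
  expect_warning(gsea_permutation(ranked, list(s = ranked$gene[1:10]),
                                  n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("guilt-by-association ranks by hub correlation and excludes the hub", {
  set.seed(4)
  m <- matrix(rnorm(10 * 20, 8, 1), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("S", 1:20)))
  m["g2", ] <- m["g1", ] + rnorm(20, 0, 0.1)   # strong positive partner
  m["g3", ] <- -m["g1", ] + rnorm(20, 0, 0.1)  # strong negative partner
  x <- as_omics_tbl(m, "mRNA")
  res <- suppressMessages(guilt_by_association(
    "g1", x, x, list(pos = c("g2", "g4"), neg = c("g3", "g5")),
    n_perm = 200, seed = 1))
  expect_false("g1" %in% unlist(res$leading_edge)) # hub excluded from ranking
  expect_gt(res$es[res$set_name == "pos"], 0)
  expect_lt(res$es[res$set_name == "neg"], 0)
  const <- x
  const[const$feature_id == "g1", -1] <- as.list(rep(5, 20))
  expect_error(guilt_by_association("g1", const, x, list(s = c("g2", "g3")),
                                    n_perm = 100),
               "constant")
  expect_error(guilt_by_association("nope", x, x, list(s = c("g2", "g3"))),
               "not found")
})

test_that("a planted miRNA hub's target set dominates guilt-by-association", {
  top_rank <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_mrna = 100, n_mirna = 20, n_lncrna = 20,
                      n_cpg_genes = 20, n_de_mrna = 0, n_de_mirna = 0,
                      n_de_lncrna = 0, n_planted_triads = 1,
                      targets_per_triad = 8, n_planted_dm = 0,
                      n_planted_hypo_up = 0, n_confounded = 0, seed = seed)
    co <- simulate_cohort(cfg)
    hub <- unique(co$truth$triads$mirna_id)
    targets <- co$truth$triads$mrna_id
    background <- setdiff(omics_features(co$mrna), targets)
    set.seed(seed + 500)
    coll <- c(list(planted_targets = targets),
              setNames(lapply(1:3, function(i) sample(background, 8)),
                       paste0("decoy", 1:3)))
    res <- suppressMessages(guilt_by_association(hub, co$mirna, co$mrna, coll,
                                                 n_perm = 200, seed = seed))
    # targets anticorrelate with the hub, so their set scores negative
    res$nes[res$set_name == "planted_targets"] < 0 &&
      res$set_name[1] == "planted_targets"
  }, logical(1))
  expect_gte(mean(top_rank), 0.8)
})
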