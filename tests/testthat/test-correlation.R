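pair_fixture <- function(mA, mB, type = "mirna_mrna") {
  a <- tiny_matrix(mA, layer = "miRNA",
                   features = paste0("m", seq_len(nrow(as.matrix(mA)))))
  b <- tiny_matrix(mB, layer = "mRNA",
                   features = paste0("g", seq_len(nrow(as.matrix(mB)))))
  pearson_pairs(a, b, type)
}

test_that("Pearson r and its t-transform p match the closed form", {
  out <- pair_fixture(rbind(c(1, 2, 3)), rbind(c(-1, -2, -3)))
  expect_equal(out$r, -1)
  expect_equal(out$p, 0)

  # hand computation: cov = 1, var = 5/4 each -> r = 1/(5/4) = 0.6
  out2 <- pair_fixture(rbind(c(1, 2, 3, 4)), rbind(c(2, 1, 4, 3)))
  expect_equal(out2$r, 0.6, tolerance = 1e-12)
  t_expect <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(out2$p, 2 * pt(-t_expect, 2), tolerance = 1e-12)
  # cross-check against cor.test
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out2$p, ct$p.value, tolerance = 1e-12)

  # constant rows are skipped with a log line
  expect_message(
    out3 <- pair_fixture(rbind(c(5, 5, 5, 5)), rbind(c(2, 1, 4, 3))),
    "constant")
  expect_equal(nrow(out3), 0)
})

test_that("pair orientation is symmetric in r", {
  set.seed(1)
  mA <- matrix(rnorm(20), 4, 5)
  mB <- matrix(rnorm(15), 3, 5)
  ab <- pair_fixture(mA, mB)
  ba <- pearson_pairs(tiny_matrix(mB, layer = "lncRNA",
                                  features = paste0("g", 1:3)),
                      tiny_matrix(mA, layer = "mRNA",
                                  features = paste0("m", 1:4)),
                      "lncrna_mrna")
  key_ab <- paste(ab$source_id, ab$target_id)
  key_ba <- paste(ba$target_id, ba$source_id)
  expect_equal(ab$r, ba$r[match(key_ab, key_ba)], tolerance = 1e-12)
})

test_that("threshold rules are sign- and boundary-exact per pair type", {
  base <- tibble::tibble(
    source_id = paste0("m", 1:4), target_id = paste0("t", 1:4),
    r = c(-0.6, -0.5, 0.7, -0.51), p = c(0.01, 0.01, 0.02, 0.3),
    fdr = c(0.04, 0.04, 0.06, 0.6), predicted = NA
  )
  mm <- dplyr::mutate(base, pair_type = "mirna_mrna")
  kept <- threshold_pairs(mm)
  # r = -0.5 exactly is excluded (strict), positive r excluded, p >= 0.05 excluded
  expect_identical(kept$source_id, "m1")
  ml <- dplyr::mutate(base, pair_type = "mirna_lncrna")
  # either sign passes for miRNA--lncRNA
  expect_setequal(threshold_pairs(ml)$source_id, c("m1", "m3"))
  lm <- dplyr::mutate(base, pair_type = "lncrna_mrna")
  expect_identical(threshold_pairs(lm)$source_id, "m3")
  # fdr-based significance is available
  expect_identical(threshold_pairs(mm, alpha_on = "fdr")$source_id, "m1")
  expect_error(threshold_pairs(dplyr::mutate(base, pair_type = "x")), "pair_type")
})

test_that("prediction intersection keeps only supported pairs", {
  pairs <- tibble::tibble(
    source_id = c("m1", "m1"), target_id = c("g1", "g2"),
    pair_type = "mirna_mrna", r = c(-0.7, -0.8), p = 0.01, fdr = 0.02,
    predicted = NA
  )
  preds <- tibble::tibble(mirna_id = "m1", target_id = "g1",
                          target_layer = "mRNA", n_sources = 2L)
  out <- suppressMessages(intersect_with_predictions(pairs, preds))
  expect_identical(out$target_id, "g1")
  expect_true(all(out$predicted))
  empty <- suppressMessages(intersect_with_predictions(pairs, preds[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("triad assembly is the cross product of negative predicted edges", {
  mk <- function(src, tgt, r, type) {
    tibble::tibble(source_id = src, target_id = tgt, pair_type = type,
                   r = r, p = 0.001, fdr = 0.004, predicted = TRUE)
  }
  mm <- mk("M1", c("G1", "G2", "G3"), c(-0.7, -0.6, -0.9), "mirna_mrna")
  ml <- mk("M1", c("L1", "L2"), c(-0.8, -0.6), "mirna_lncrna")
  triads <- assemble_cerna_triads(mm, ml)
  expect_equal(nrow(triads), 6) # brute-force cross product 2 x 3
  expect_identical(
    triad_key(triads),
    sort(triad_key(tidyr::expand_grid(lncrna_id = c("L1", "L2"), mirna_id = "M1",
                                      mrna_id = c("G1", "G2", "G3")))))
  # positive miRNA--lncRNA edges never seed triads
  ml_pos <- mk("M1", "L9", 0.9, "mirna_lncrna")
  expect_equal(nrow(assemble_cerna_triads(mm, ml_pos)), 0)
  # the optional confirmation edge restricts the cross product
  lm <- mk("L1", "G1", 0.8, "lncrna_mrna")
  confirmed <- assemble_cerna_triads(mm, ml, lm, require_lncrna_mrna_edge = TRUE)
  expect_identical(triad_key(confirmed), "L1|M1|G1")
})

test_that("network stages agree with an exhaustive brute-force oracle", {
  # tiny cohort, every pair recomputed independently with cor.test
  cfg <- sim_config(n_case = 10, n_control = 10, n_mrna = 8, n_mirna = 6,
                    n_lncrna = 6, n_cpg_genes = 8, n_de_mrna = 0,
                    n_de_mirna = 0, n_de_lncrna = 0, n_planted_triads = 2,
                    n_planted_dm = 0, n_planted_hypo_up = 0, n_confounded = 0,
                    n_sex_features = 0, seed = 5)
  co <- simulate_cohort(cfg)
  preds <- simulate_target_database(co$truth, co$annotation, 0.5, seed = 5)
  mm <- pearson_pairs(co$mirna, co$mrna, "mirna_mrna")
  ml <- pearson_pairs(co$mirna, co$lncrna, "mirna_lncrna")

  oracle_pairs <- function(A, B) {
    va <- omics_values(A); vb <- omics_values(B)
    out <- list()
    for (i in rownames(va)) for (j in rownames(vb)) {
      ct <- cor.test(va[i, ], vb[j, ])
      out[[paste(i, j)]] <- c(r = unname(ct$estimate), p = ct$p.value)
    }
    out
  }
  orc <- oracle_pairs(co$mirna, co$mrna)
  key <- paste(mm$source_id, mm$target_id)
  expect_equal(mm$r, vapply(orc[key], `[[`, numeric(1), "r"),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(mm$p, vapply(orc[key], `[[`, numeric(1), "p"),
               ignore_attr = TRUE, tolerance = 1e-10)

  # thresholded + intersected + assembled result equals the brute-force set
  mm_t <- suppressMessages(intersect_with_predictions(threshold_pairs(mm), preds))
  ml_t <- suppressMessages(intersect_with_predictions(threshold_pairs(ml), preds))
  triads <- assemble_cerna_triads(mm_t, ml_t)
  pred_key <- paste(preds$mirna_id, preds$target_id)
  brute <- list()
  for (m in omics_features(co$mirna)) {
    gs <- mm_t$target_id[mm_t$source_id == m]
    ls <- ml_t$target_id[ml_t$source_id == m & ml_t$r < 0]
    for (l in ls) for (g in gs) brute[[paste(l, m, g, sep = "|")]] <- TRUE
  }
  expect_setequal(triad_key(triads), names(brute))
  # referential integrity: every triad edge exists in its pair list
  expect_true(all(paste(triads$mirna_id, triads$mrna_id) %in%
                    paste(mm_t$source_id, mm_t$target_id)))
  expect_true(all(paste(triads$mirna_id, triads$lncrna_id) %in%
                    paste(ml_t$source_id, ml_t$target_id)))
})
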