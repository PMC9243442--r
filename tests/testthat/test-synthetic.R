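test_that("identical configs give identical cohorts, references and predictions", {
  cfg <- sim_config(n_case = 5, n_control = 5, n_mrna = 30, n_mirna = 20,
                    n_lncrna = 20, n_cpg_genes = 20, n_de_mrna = 4,
                    n_de_mirna = 4, n_de_lncrna = 4, n_planted_triads = 2,
                    n_planted_dm = 3, n_planted_hypo_up = 1, n_confounded = 3,
                    seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_reference_pairs(cfg), simulate_reference_pairs(cfg))
  expect_identical(
    simulate_target_database(a$truth, a$annotation, 0.3, seed = 5),
    simulate_target_database(b$truth, b$annotation, 0.3, seed = 5)
  )
  # the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted triads carry the ceRNA correlation sign pattern", {
  cfg <- sim_config(n_case = 20, n_control = 20, n_mrna = 40, n_mirna = 20,
                    n_lncrna = 20, n_cpg_genes = 20, n_de_mrna = 0,
                    n_de_mirna = 0, n_de_lncrna = 0, n_planted_triads = 1,
                    n_planted_dm = 0, n_planted_hypo_up = 0, n_confounded = 0,
                    triad_coupling = 0.8, noise_sd = 0.5, seed = 3)
  co <- simulate_cohort(cfg)
  tri <- co$truth$triads
  mir <- omics_values(co$mirna)[tri$mirna_id, ]
  gene <- omics_values(co$mrna)[tri$mrna_id, ]
  lnc <- omics_values(co$lncrna)[tri$lncrna_id, ]
  expect_lt(cor(mir, gene), 0)
  expect_lt(cor(mir, lnc), 0)
  expect_gt(cor(lnc, gene), 0)
  # direction in cases: miRNA down, sponge and target up
  case <- co$samples$group == "case"
  expect_lt(mean(mir[case]) - mean(mir[!case]), 0)
  expect_gt(mean(gene[case]) - mean(gene[!case]), 0)
  expect_gt(mean(lnc[case]) - mean(lnc[!case]), 0)
})

test_that("a signal-free cohort yields (almost) no BH discoveries", {
  # Monte-Carlo over 50 seeds: expected count of adjusted-p discoveries
  # under the global null is ~0 because BH controls the FDR.
  frac <- vapply(1:50, function(seed) {
    cfg <- sim_config(n_case = 6, n_control = 6, n_mrna = 40, n_mirna = 4,
                      n_lncrna = 4, n_cpg_genes = 4, n_de_mrna = 0,
                      n_de_mirna = 0, n_de_lncrna = 0, n_planted_triads = 0,
                      n_planted_dm = 0, n_planted_hypo_up = 0,
                      n_confounded = 0, n_sex_features = 0, seed = seed)
    co <- simulate_cohort(cfg)
    de <- classify_de(student_t_de(co$mrna, co$samples))
    mean(de$call != "not_significant")
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("confounded features are detectable in the paired reference", {
  cfg <- sim_config(n_mrna = 30, n_mirna = 12, n_lncrna = 12, n_cpg_genes = 12,
                    n_de_mrna = 2, n_de_mirna = 2, n_de_lncrna = 2,
                    n_planted_triads = 1, n_planted_dm = 2,
                    n_planted_hypo_up = 1, n_confounded = 6,
                    n_ref_pairs = 10, confound_offset = 2.0, noise_sd = 0.5,
                    seed = 21)
  ref <- simulate_reference_pairs(cfg)
  co <- simulate_cohort(cfg)
  tests <- paired_reference_test(ref$reference, ref$samples)
  conf <- co$truth$confounded_features$feature_id
  # closed-form power of the paired t at effect size offset/sd(diff) =
  # 2.0 / (0.5 * sqrt(2)) = 2.83 per pair, 10 pairs: essentially 1
  expect_true(all(tests$significant[tests$feature_id %in% conf]))
  not_conf <- setdiff(tests$feature_id, conf)
  expect_lt(mean(tests$significant[tests$feature_id %in% not_conf]), 0.15)
})

test_that("reference generator refuses fewer than 3 pairs", {
  expect_error(simulate_reference_pairs(sim_config(n_ref_pairs = 2)),
               "at least 3")
})

test_that("the prediction table contains planted edges plus seeded decoys", {
  cfg <- sim_config(n_mrna = 30, n_mirna = 10, n_lncrna = 10, n_cpg_genes = 10,
                    n_planted_triads = 2, n_de_mrna = 0, n_de_mirna = 0,
                    n_de_lncrna = 0, n_planted_dm = 0, n_planted_hypo_up = 0,
                    n_confounded = 0, seed = 2)
  co <- simulate_cohort(cfg)
  tri <- co$truth$triads
  pure <- simulate_target_database(co$truth, co$annotation, decoy_fraction = 0)
  expect_setequal(paste(pure$mirna_id, pure$target_id),
                  c(paste(tri$mirna_id, tri$mrna_id),
                    paste(tri$mirna_id, tri$lncrna_id)))
  with_decoys <- simulate_target_database(co$truth, co$annotation, 0.5, seed = 4)
  expect_gt(nrow(with_decoys), nrow(pure))
  # planted edges always survive; decoys never touch planted triad members
  expect_true(all(paste(pure$mirna_id, pure$target_id) %in%
                    paste(with_decoys$mirna_id, with_decoys$target_id)))
  decoys <- dplyr::anti_join(with_decoys, pure, by = c("mirna_id", "target_id"))
  planted_feats <- unique(c(tri$mirna_id, tri$mrna_id, tri$lncrna_id))
  expect_false(any(decoys$mirna_id %in% planted_feats))
  expect_false(any(decoys$target_id %in% planted_feats))
  expect_identical(with_decoys,
                   simulate_target_database(co$truth, co$annotation, 0.5, seed = 4))
  expect_error(simulate_target_database(co$truth, co$annotation, 1.2),
               "decoy_fraction")
})

test_that("impossible planted counts are rejected", {
  expect_error(sim_config(n_mrna = 10, n_de_mrna = 20), "exceed")
  expect_error(sim_config(n_planted_hypo_up = 7, n_planted_dm = 6),
               "n_planted_hypo_up")
  expect_error(sim_config(noise_sd = 0), "noise")
})
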