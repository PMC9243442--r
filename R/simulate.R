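# Synthetic two-group multi-omics cohort with planted ground truth.
#
# The generator emulates a case/control brain-tissue cohort profiled on
# three expression layers (mRNA, miRNA, lncRNA) plus gene-level DNA
# methylation, together with a paired reference cohort (hippocampus vs
# cortex from healthy donors) and a miRNA target-prediction table.  Planted
# signals: ordinary differentially expressed features, ceRNA triads driven
# by a latent per-sample miRNA activity (lncRNA up, miRNA down, mRNA up in
# cases, with the sponge correlation signs), hypomethylated genes of which
# a subset is also upregulated, and tissue-confounded decoys that appear
# differential in the cohort only because case and control tissue sites
# differ; the paired reference cohort carries the same tissue offset so the
# reference filter can remove them.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale cohort with enough power for the planted
#' signals to be recoverable: 20 cases vs 20 controls, 200 features per
#' layer, residual noise SD 0.5 on the log2 scale. Planted differential
#' features are shifted by `de_log2fc` in cases; each planted ceRNA triad is
#' driven by a latent per-sample miRNA activity with SD `activity_sd`,
#' shifted down by `activity_shift` in cases, coupled into its mRNA and
#' lncRNA rows with weight `-triad_coupling`. Methylation is simulated as
#' gene-level beta values around per-gene baselines, with planted
#' hypomethylated genes shifted by `beta_shift` in cases and clipped to
#' `[0.01, 0.99]`.
#'
#' @param n_case,n_control Samples per group.
#' @param n_mrna,n_mirna,n_lncrna Features per expression layer.
#' @param n_cpg_genes Genes with methylation rows (first `n_cpg_genes` mRNA ids).
#' @param n_de_mrna,n_de_mirna,n_de_lncrna Planted ordinary DE features per
#'   layer (half up, half down).
#' @param n_planted_triads Planted ceRNA triad groups.
#' @param targets_per_triad mRNA targets coupled to each triad miRNA; each
#'   target contributes one (lncRNA, miRNA, mRNA) triad to the ground truth.
#' @param n_planted_dm Planted hypomethylated genes.
#' @param n_planted_hypo_up How many of those are also upregulated
#'   (candidate epigenetically activated genes); must be `<= n_planted_dm`.
#' @param n_confounded Tissue-confounded decoy features, split evenly across
#'   the three expression layers.
#' @param n_sex_features Background features placed on chrX per layer (the
#'   probe filter removes them).
#' @param de_log2fc Planted case shift, log2 units.
#' @param triad_coupling Latent-activity coupling weight in (0, 1].
#' @param activity_sd,activity_shift SD of the latent miRNA activity and its
#'   downward shift in cases.
#' @param noise_sd Residual SD of expression values (log2 scale).
#' @param beta_shift Planted case shift of methylation beta (negative =
#'   hypomethylation).
#' @param beta_noise_sd Residual SD of beta values.
#' @param n_ref_pairs Hippocampus/cortex pairs in the reference cohort.
#' @param confound_offset Between-tissue offset (log2) of confounded features.
#' @param pair_sd SD of the shared per-pair random effect in the reference.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 20, n_control = 20,
                       n_mrna = 200, n_mirna = 200, n_lncrna = 200,
                       n_cpg_genes = 200,
                       n_de_mrna = 20, n_de_mirna = 20, n_de_lncrna = 20,
                       n_planted_triads = 5, targets_per_triad = 1,
                       n_planted_dm = 6, n_planted_hypo_up = 1,
                       n_confounded = 18, n_sex_features = 5,
                       de_log2fc = 1.5, triad_coupling = 0.8,
                       activity_sd = 1.0, activity_shift = 2.0,
                       noise_sd = 0.5, beta_shift = -0.25,
                       beta_noise_sd = 0.05,
                       n_ref_pairs = 10, confound_offset = 2.0,
                       pair_sd = 1.0, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_case", "n_control", "n_mrna", "n_mirna", "n_lncrna",
              "n_cpg_genes", "n_de_mrna", "n_de_mirna", "n_de_lncrna",
              "n_planted_triads", "targets_per_triad", "n_planted_dm",
              "n_planted_hypo_up", "n_confounded", "n_sex_features",
              "n_ref_pairs")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(sprintf("config field '%s' must be a non-negative count", f))
    }
  }
  if (cfg$noise_sd <= 0 || cfg$beta_noise_sd <= 0) abort("noise SDs must be > 0")
  if (cfg$triad_coupling <= 0 || cfg$triad_coupling > 1) {
    abort("triad_coupling must lie in (0, 1]")
  }
  if (cfg$n_planted_hypo_up > cfg$n_planted_dm) {
    abort("n_planted_hypo_up cannot exceed n_planted_dm")
  }
  if (cfg$n_cpg_genes > cfg$n_mrna) abort("n_cpg_genes cannot exceed n_mrna")
  if (cfg$n_planted_dm > cfg$n_cpg_genes) {
    abort("n_planted_dm cannot exceed n_cpg_genes")
  }
  alloc <- try(feature_allocation(cfg), silent = TRUE)
  if (inherits(alloc, "try-error")) {
    abort(sprintf("planted feature counts exceed layer sizes (%s)",
                  attr(alloc, "condition")$message))
  }
  invisible(cfg)
}

# Deterministic block allocation of feature ids to roles.  Because it uses
# no random draws, the reference and prediction generators can re-derive
# the same ids from the config alone.
feature_allocation <- function(cfg) {
  n_triad_mrna <- cfg$n_planted_triads * cfg$targets_per_triad
  conf <- split_confounded(cfg$n_confounded)
  alloc_layer <- function(prefix, n, blocks) {
    used <- sum(lengths(blocks))
    if (used > n) stop(sprintf("layer %s: %d planted > %d features", prefix, used, n))
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    role <- rep("background", n)
    grp <- rep(NA_integer_, n)
    at <- 0L
    for (b in names(blocks)) {
      k <- length(blocks[[b]])
      if (k) {
        role[at + seq_len(k)] <- b
        grp[at + seq_len(k)] <- blocks[[b]]
      }
      at <- at + k
    }
    tibble(feature_id = ids, role = role, triad_group = grp)
  }
  de_split <- function(n) c(rep("up", ceiling(n / 2)), rep("down", floor(n / 2)))
  blocks_mrna <- list(
    hypo_up = rep(0L, cfg$n_planted_hypo_up),
    dm_only = rep(0L, cfg$n_planted_dm - cfg$n_planted_hypo_up),
    de = rep(0L, cfg$n_de_mrna),
    confounded = rep(0L, conf["mRNA"]),
    triad_mrna = rep(seq_len(cfg$n_planted_triads), each = cfg$targets_per_triad),
    sex = rep(0L, cfg$n_sex_features)
  )
  blocks_mirna <- list(
    de = rep(0L, cfg$n_de_mirna),
    confounded = rep(0L, conf["miRNA"]),
    triad_mirna = seq_len(cfg$n_planted_triads),
    sex = rep(0L, cfg$n_sex_features)
  )
  blocks_lncrna <- list(
    de = rep(0L, cfg$n_de_lncrna),
    confounded = rep(0L, conf["lncRNA"]),
    triad_lncrna = seq_len(cfg$n_planted_triads),
    sex = rep(0L, cfg$n_sex_features)
  )
  mrna <- alloc_layer("gene", cfg$n_mrna, blocks_mrna)
  mirna <- alloc_layer("mir", cfg$n_mirna, blocks_mirna)
  lncrna <- alloc_layer("lnc", cfg$n_lncrna, blocks_lncrna)
  # mark DE direction
  mark_de <- function(tab, n_de) {
    i <- which(tab$role == "de")
    tab$direction <- NA_character_
    tab$direction[i] <- de_split(n_de)
    tab
  }
  mrna <- mark_de(mrna, cfg$n_de_mrna)
  mirna <- mark_de(mirna, cfg$n_de_mirna)
  lncrna <- mark_de(lncrna, cfg$n_de_lncrna)
  mrna$direction[mrna$role == "hypo_up"] <- "up"
  mrna$direction[mrna$role == "triad_mrna"] <- "up"
  mirna$direction[mirna$role == "triad_mirna"] <- "down"
  lncrna$direction[lncrna$role == "triad_lncrna"] <- "up"
  list(mRNA = mrna, miRNA = mirna, lncRNA = lncrna)
}

split_confounded <- function(n) {
  base <- n %/% 3L
  extra <- n %% 3L
  out <- c(mRNA = base, miRNA = base, lncRNA = base)
  if (extra >= 1) out["mRNA"] <- out["mRNA"] + 1L
  if (extra >= 2) out["miRNA"] <- out["miRNA"] + 1L
  out
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a two-group multi-omics cohort with planted ground truth
#'
#' Background expression values are i.i.d. Normal(8, `noise_sd`) on the log2
#' scale. Planted DE features are shifted by `+/- de_log2fc` in cases.
#' Each planted triad group draws a latent per-sample activity
#' `a ~ Normal(-activity_shift * is_case, activity_sd)`; its miRNA row is
#' `8 + a + noise` and each coupled mRNA/lncRNA row is
#' `8 - triad_coupling * a + noise`, so in cases the miRNA falls while its
#' sponge lncRNA and target mRNA rise, and across samples the pairwise
#' correlations carry the ceRNA sign pattern (miRNA--mRNA < 0,
#' miRNA--lncRNA < 0, lncRNA--mRNA > 0). Tissue-confounded features are
#' shifted by `confound_offset` in cases (emulating a hippocampus-vs-cortex
#' difference rather than disease). Methylation rows are beta values around
#' per-gene baselines drawn in (0.2, 0.8) — (0.4, 0.75) for planted
#' hypomethylated genes so the planted shift is realised away from the
#' clipping boundary — with cases shifted by `beta_shift` for planted genes
#' and all values clipped to `[0.01, 0.99]`.
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_cohort` with elements `mrna`, `mirna`,
#'   `lncrna`, `methylation` (omics tables), `samples`, `annotation`,
#'   `truth` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_case + cfg$n_control
    sample_ids <- c(sprintf("case%02d", seq_len(cfg$n_case)),
                    sprintf("ctrl%02d", seq_len(cfg$n_control)))
    is_case <- rep(c(TRUE, FALSE), c(cfg$n_case, cfg$n_control))
    samples <- tibble(sample_id = sample_ids,
                      group = ifelse(is_case, "case", "control"),
                      pair_id = NA_character_)
    alloc <- feature_allocation(cfg)

    layer_matrix <- function(tab) {
      m <- matrix(rnorm(nrow(tab) * n, mean = 8, sd = cfg$noise_sd),
                  nrow = nrow(tab), dimnames = list(tab$feature_id, sample_ids))
      shift <- dplyr::case_when(
        tab$role %in% c("de", "hypo_up") & tab$direction %in% "up" ~ cfg$de_log2fc,
        tab$role == "de" & tab$direction %in% "down" ~ -cfg$de_log2fc,
        tab$role == "confounded" ~ cfg$confound_offset,
        .default = 0
      )
      m[, is_case] <- m[, is_case] + shift
      m
    }
    m_mrna <- layer_matrix(alloc$mRNA)
    m_mirna <- layer_matrix(alloc$miRNA)
    m_lncrna <- layer_matrix(alloc$lncRNA)

    # latent miRNA activity per triad group
    for (g in seq_len(cfg$n_planted_triads)) {
      a <- rnorm(n, 0, cfg$activity_sd) - cfg$activity_shift * is_case
      i_mir <- which(alloc$miRNA$triad_group == g & alloc$miRNA$role == "triad_mirna")
      i_lnc <- which(alloc$lncRNA$triad_group == g & alloc$lncRNA$role == "triad_lncrna")
      i_gen <- which(alloc$mRNA$triad_group == g & alloc$mRNA$role == "triad_mrna")
      m_mirna[i_mir, ] <- 8 + a + rnorm(n, 0, cfg$noise_sd)
      m_lncrna[i_lnc, ] <- 8 - cfg$triad_coupling * a + rnorm(n, 0, cfg$noise_sd)
      for (i in i_gen) {
        m_mrna[i, ] <- 8 - cfg$triad_coupling * a + rnorm(n, 0, cfg$noise_sd)
      }
    }

    # gene-level methylation over the first n_cpg_genes mRNA ids
    cpg_tab <- alloc$mRNA[seq_len(cfg$n_cpg_genes), ]
    is_dm <- cpg_tab$role %in% c("hypo_up", "dm_only")
    baseline <- runif(cfg$n_cpg_genes, 0.2, 0.8)
    baseline[is_dm] <- runif(sum(is_dm), 0.4, 0.75)
    m_beta <- baseline +
      matrix(rnorm(cfg$n_cpg_genes * n, 0, cfg$beta_noise_sd),
             nrow = cfg$n_cpg_genes,
             dimnames = list(cpg_tab$feature_id, sample_ids))
    m_beta[is_dm, is_case] <- m_beta[is_dm, is_case] + cfg$beta_shift
    m_beta <- pmin(pmax(m_beta, 0.01), 0.99)

    annotation <- dplyr::bind_rows(c(
      imap(alloc, function(tab, layer) {
        tibble(feature_id = tab$feature_id,
               chromosome = ifelse(tab$role == "sex", "chrX",
                                   paste0("chr", (seq_len(nrow(tab)) %% 22L) + 1L)),
               layer = layer)
      }),
      list(tibble(feature_id = cpg_tab$feature_id,
                  chromosome = paste0("chr", (seq_len(nrow(cpg_tab)) %% 22L) + 1L),
                  layer = "methylation"))
    ))
    # methylation rows reuse gene ids; keep one annotation row per id
    annotation <- annotation[!duplicated(annotation$feature_id), ]

    truth <- build_truth(alloc, cpg_tab, cfg)

    structure(list(
      mrna = as_omics_tbl(m_mrna, "mRNA"),
      mirna = as_omics_tbl(m_mirna, "miRNA"),
      lncrna = as_omics_tbl(m_lncrna, "lncRNA"),
      methylation = as_omics_tbl(m_beta, "methylation"),
      samples = samples,
      annotation = validate_annotation(annotation),
      truth = truth,
      config = cfg
    ), class = "cerna_cohort")
  })
}

build_truth <- function(alloc, cpg_tab, cfg) {
  de_layer <- function(tab) {
    de <- tab[tab$role %in% c("de", "hypo_up", "triad_mrna", "triad_mirna",
                              "triad_lncrna"), c("feature_id", "direction")]
    as_tibble(de)
  }
  triads <- tibble(lncrna_id = character(), mirna_id = character(),
                   mrna_id = character())
  triads <- dplyr::bind_rows(c(list(triads), lapply(seq_len(cfg$n_planted_triads), function(g) {
    tibble(
      lncrna_id = alloc$lncRNA$feature_id[alloc$lncRNA$triad_group %in% g &
                                            alloc$lncRNA$role == "triad_lncrna"],
      mirna_id = alloc$miRNA$feature_id[alloc$miRNA$triad_group %in% g &
                                          alloc$miRNA$role == "triad_mirna"],
      mrna_id = alloc$mRNA$feature_id[alloc$mRNA$triad_group %in% g &
                                        alloc$mRNA$role == "triad_mrna"]
    )
  })))
  list(
    de_features = list(mRNA = de_layer(alloc$mRNA),
                       miRNA = de_layer(alloc$miRNA),
                       lncRNA = de_layer(alloc$lncRNA)),
    dm_features = tibble(feature_id = cpg_tab$feature_id[cpg_tab$role %in%
                                                           c("hypo_up", "dm_only")],
                         direction = "down"),
    hypo_up_genes = cpg_tab$feature_id[cpg_tab$role == "hypo_up"],
    confounded_features = dplyr::bind_rows(imap(alloc, function(tab, layer) {
      tibble(feature_id = tab$feature_id[tab$role == "confounded"], layer = layer)
    })),
    triads = triads
  )
}

#' Simulate a paired reference cohort (hippocampus vs cortex)
#'
#' Emulates paired expression of all cohort features in two healthy brain
#' regions. Each feature's value is `8 + pair effect + noise`; features the
#' cohort generator marked tissue-confounded additionally carry a
#' `confound_offset` shift on the hippocampus side, so a paired test flags
#' them, while all other features have zero expected paired difference.
#'
#' @param config A [sim_config()]; feature identities and the confounded set
#'   are re-derived deterministically from it, so the reference matches the
#'   cohort produced by [simulate_cohort()] with the same config.
#' @return A list with `reference` (tibble, `feature_id` + one column per
#'   sample) and `samples` (sheet with `group` in {hippocampus, cortex} and
#'   `pair_id`).
#' @export
simulate_reference_pairs <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  if (cfg$n_ref_pairs < 3) abort("paired tests need at least 3 reference pairs")
  with_seed(cfg$seed + 1000003L, {
    alloc <- feature_allocation(cfg)
    feats <- dplyr::bind_rows(imap(alloc, function(tab, layer) {
      tibble(feature_id = tab$feature_id, confounded = tab$role == "confounded")
    }))
    k <- cfg$n_ref_pairs
    hip_ids <- sprintf("hip%02d", seq_len(k))
    ctx_ids <- sprintf("ctx%02d", seq_len(k))
    samples <- tibble(
      sample_id = c(hip_ids, ctx_ids),
      group = rep(c("hippocampus", "cortex"), each = k),
      pair_id = rep(sprintf("P%02d", seq_len(k)), 2)
    )
    nf <- nrow(feats)
    pair_eff <- matrix(rnorm(nf * k, 0, cfg$pair_sd), nf, k)
    hip <- 8 + pair_eff + matrix(rnorm(nf * k, 0, cfg$noise_sd), nf, k) +
      cfg$confound_offset * feats$confounded
    ctx <- 8 + pair_eff + matrix(rnorm(nf * k, 0, cfg$noise_sd), nf, k)
    m <- cbind(hip, ctx)
    dimnames(m) <- list(feats$feature_id, c(hip_ids, ctx_ids))
    list(reference = tibble::as_tibble(m, rownames = "feature_id"),
         samples = samples)
  })
}

#' Simulate a miRNA target-prediction table
#'
#' Contains every planted triad's miRNA-to-mRNA and miRNA-to-lncRNA edge
#' (support drawn from 1--3 databases) plus decoy predictions sampled among
#' features never planted into any triad, at `decoy_fraction` of all such
#' candidate pairs. Deterministic under `seed`.
#'
#' @param truth Ground truth from [simulate_cohort()].
#' @param annotation Feature annotation from the same cohort.
#' @param decoy_fraction Fraction of candidate decoy (miRNA, target) pairs to
#'   include, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A prediction tibble (see [read_target_predictions()]).
#' @export
simulate_target_database <- function(truth, annotation, decoy_fraction = 0.3,
                                     seed = 1) {
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    abort("decoy_fraction must lie in [0, 1]")
  }
  with_seed(seed + 2000029L, {
    planted <- dplyr::bind_rows(
      tibble(mirna_id = truth$triads$mirna_id, target_id = truth$triads$mrna_id,
             target_layer = "mRNA"),
      tibble(mirna_id = truth$triads$mirna_id, target_id = truth$triads$lncrna_id,
             target_layer = "lncRNA")
    ) |> dplyr::distinct()
    planted$n_sources <- sample(1:3, nrow(planted), replace = TRUE)

    mirnas <- annotation$feature_id[annotation$layer == "miRNA"]
    targets <- annotation[annotation$layer %in% c("mRNA", "lncRNA"),
                          c("feature_id", "layer")]
    in_triad <- unique(c(truth$triads$mirna_id, truth$triads$mrna_id,
                         truth$triads$lncrna_id))
    mirnas <- setdiff(mirnas, in_triad)
    targets <- targets[!targets$feature_id %in% in_triad, ]
    n_cand <- length(mirnas) * nrow(targets)
    n_decoy <- round(decoy_fraction * n_cand)
    decoys <- NULL
    if (n_decoy > 0) {
      idx <- sort(sample.int(n_cand, n_decoy))
      i_mir <- ((idx - 1L) %/% nrow(targets)) + 1L
      i_tgt <- ((idx - 1L) %% nrow(targets)) + 1L
      decoys <- tibble(
        mirna_id = mirnas[i_mir],
        target_id = targets$feature_id[i_tgt],
        target_layer = targets$layer[i_tgt],
        n_sources = sample(1:3, n_decoy, replace = TRUE)
      )
    }
    validate_target_predictions(dplyr::bind_rows(planted, decoys))
  })
}

#' A paper-scale preset of the simulation config
#'
#' Six cases versus nine controls — the size of the motivating cohort. At
#' this size the planted signals are only marginally recoverable; the preset
#' exists for demonstration, not for the recovery guarantees quoted for the
#' defaults.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_paper_scale <- function(...) {
  sim_config(n_case = 6, n_control = 9, ...)
}
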