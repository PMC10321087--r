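# Synthetic cohort generator: AIRR-style sequence tables plus a clinical
# table for a paired muscle/blood cohort (muscle + blood at baseline, blood
# at week 9), with a ground-truth ledger recording every planted quantity so
# each pipeline stage can be tested against known parameters.

ighv_pool <- c(
  "IGHV1-2", "IGHV1-18", "IGHV1-69", "IGHV2-5", "IGHV3-7", "IGHV3-9",
  "IGHV3-11", "IGHV3-15", "IGHV3-21", "IGHV3-23", "IGHV3-3", "IGHV3-30",
  "IGHV3-33", "IGHV3-48", "IGHV3-74", "IGHV4-31", "IGHV4-34", "IGHV4-39",
  "IGHV4-59", "IGHV5-51", "IGHV6-1"
)
ighj_pool <- c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6")
muscle_biased_v <- c("IGHV4-31", "IGHV3-23", "IGHV3-3", "IGHV3-74")
blood_biased_v <- c("IGHV1-2", "IGHV3-3")
aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 19-patient myositis-like cohort treated with IVIG:
#' paired muscle and blood repertoires at baseline plus blood at week 9,
#' power-law clone sizes with a minority (5/19) of blood baselines lacking
#' dominant clones, partial muscle-to-blood clone sharing with three patients
#' sharing a dominant clone across compartments, near-complete (95%)
#' turnover of dominant blood clones by week 9, higher mutation load in
#' muscle than blood, V-gene usage biased toward IGHV4-31/IGHV3-23/IGHV3-3/
#' IGHV3-74 in muscle, and clinical couplings: baseline dominant-clone
#' impact positively rank-correlated with CK and with responder status, and
#' a *decrease* in impact over treatment coupled to improvement in MMT and
#' TIS (negative correlations with the week9-minus-baseline impact delta).
#'
#' @param n_patients Number of patients (default 19).
#' @param subtype_mix Named probabilities over DM, NM/OM, IMNM, ASS
#'   (default 8/19, 5/19, 5/19, 1/19).
#' @param antibody_mix Named probabilities over MSA, MAA, seronegative.
#' @param clones_per_sample Integer range (min, max) of clones per sample.
#' @param clone_size_law Power-law tail exponent of the clone-size
#'   distribution (default 1.5); sizes are truncated per sample (see
#'   `clonality_cap`).
#' @param clonality_cap Range of the per-sample cap on the largest clone's
#'   frequency for samples designated to carry dominant clones; controls how
#'   clonal those samples are.
#' @param frac_blood_without_dominant Fraction of patients whose blood
#'   baseline (and week-9) repertoire carries no dominant clone (default
#'   5/19); such samples are capped below the dominance threshold.
#' @param muscle_blood_sharing_rate Fraction of blood-baseline clones whose
#'   identities are seeded from the patient's muscle repertoire (default
#'   0.1). When 0, compartments share nothing and no dominant sharing is
#'   planted.
#' @param dominant_sharing_patients Number of patients given exactly one
#'   clone dominant in both muscle and blood (default 3).
#' @param turnover Probability that a baseline-dominant blood clone is no
#'   longer dominant at week 9 (default 0.95); each baseline dominant clone
#'   is an independent Bernoulli trial.
#' @param de_novo_dominant_rate Expected number of new dominant clones at
#'   week 9; `NULL` (default) lets the count emerge from the clone-size law,
#'   a number forces `rpois()` counts by promoting/demoting edge clones.
#' @param persistence_rate Fraction of week-9 subthreshold clones re-using
#'   baseline (non-dominant) clone identities, for repertoire continuity.
#' @param mutation_rate_muscle,mutation_rate_blood Mean somatic mutation
#'   rates (mutations per aligned V base pair); muscle defaults higher
#'   (0.05 vs 0.02), reflecting matured tissue-infiltrating B cells.
#' @param v_gene_bias Multiplicative weight applied to the muscle-favoured V
#'   genes in muscle samples (and mildly to IGHV1-2/IGHV3-3 in blood).
#' @param impact_ck_coupling Latent Gaussian-copula correlation between
#'   baseline blood impact and CK (default 0.5).
#' @param impact_response_coupling Latent correlation between baseline blood
#'   impact and the TIS scale driving responder status (default 0.85).
#' @param dimpact_tis_coupling Latent correlation between the impact delta
#'   (week9 - baseline) and TIS (default -0.35: impact decrease, better TIS).
#' @param dimpact_mmt_coupling Latent correlation between the impact delta
#'   and the MMT change (default -0.5: impact decrease, better strength).
#' @param hec_threshold Dominance threshold used for planting (default 0.005).
#' @param seed Default RNG seed used by [generate_cohort()] when no seed is
#'   passed explicitly.
#' @return A `bcr_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 19,
                          subtype_mix = c("DM" = 8 / 19, "NM/OM" = 5 / 19,
                                          "IMNM" = 5 / 19, "ASS" = 1 / 19),
                          antibody_mix = c("MSA" = 12 / 19, "MAA" = 2 / 19,
                                           "seronegative" = 5 / 19),
                          clones_per_sample = c(300L, 800L),
                          clone_size_law = 1.5,
                          clonality_cap = c(0.012, 0.10),
                          frac_blood_without_dominant = 5 / 19,
                          muscle_blood_sharing_rate = 0.1,
                          dominant_sharing_patients = 3,
                          turnover = 0.95,
                          de_novo_dominant_rate = NULL,
                          persistence_rate = 0.2,
                          mutation_rate_muscle = 0.05,
                          mutation_rate_blood = 0.02,
                          v_gene_bias = 2.5,
                          impact_ck_coupling = 0.5,
                          impact_response_coupling = 0.85,
                          dimpact_tis_coupling = -0.35,
                          dimpact_mmt_coupling = -0.5,
                          hec_threshold = 0.005,
                          seed = 42L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    subtype_mix = subtype_mix,
    antibody_mix = antibody_mix,
    clones_per_sample = as.integer(clones_per_sample),
    clone_size_law = clone_size_law,
    clonality_cap = clonality_cap,
    frac_blood_without_dominant = frac_blood_without_dominant,
    muscle_blood_sharing_rate = muscle_blood_sharing_rate,
    dominant_sharing_patients = as.integer(dominant_sharing_patients),
    turnover = turnover,
    de_novo_dominant_rate = de_novo_dominant_rate,
    persistence_rate = persistence_rate,
    mutation_rate_muscle = mutation_rate_muscle,
    mutation_rate_blood = mutation_rate_blood,
    v_gene_bias = v_gene_bias,
    impact_ck_coupling = impact_ck_coupling,
    impact_response_coupling = impact_response_coupling,
    dimpact_tis_coupling = dimpact_tis_coupling,
    dimpact_mmt_coupling = dimpact_mmt_coupling,
    hec_threshold = hec_threshold,
    seed = as.integer(seed)
  )
  probs <- c(cfg$subtype_mix, cfg$antibody_mix,
             frac_blood_without_dominant, muscle_blood_sharing_rate,
             turnover, persistence_rate)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1]",
                 class = "bcr_parameter_error")
  }
  if (abs(sum(cfg$subtype_mix) - 1) > 1e-9) {
    rlang::abort("subtype_mix must sum to 1", class = "bcr_parameter_error")
  }
  if (cfg$n_patients < 1 || cfg$clones_per_sample[1] < 10 ||
      cfg$clones_per_sample[2] < cfg$clones_per_sample[1]) {
    rlang::abort("infeasible cohort size settings",
                 class = "bcr_parameter_error")
  }
  if (cfg$clone_size_law <= 1) {
    rlang::abort("clone_size_law must exceed 1", class = "bcr_parameter_error")
  }
  rsq <- cfg$impact_response_coupling^2 + cfg$dimpact_tis_coupling^2
  if (rsq > 1) {
    rlang::abort("impact_response_coupling^2 + dimpact_tis_coupling^2 must be <= 1",
                 class = "bcr_parameter_error")
  }
  structure(cfg, class = "bcr_cohort_config")
}

#' @export
print.bcr_cohort_config <- function(x, ...) {
  cat(sprintf(
    "<bcr_cohort_config> %d patients, %d-%d clones/sample, tail exponent %.2f, turnover %.2f, seed %d\n",
    x$n_patients, x$clones_per_sample[1], x$clones_per_sample[2],
    x$clone_size_law, x$turnover, x$seed
  ))
  invisible(x)
}

# Truncated power-law clone sizes: discrete Pareto with survival exponent
# `alpha` (P(S >= x) ~ x^-alpha) via inverse CDF, winsorised so no clone
# exceeds cap_freq of the sample total; then scaled to a realistic UMI depth
# (integer scaling preserves frequencies exactly).
sample_clone_sizes <- function(n, alpha, cap_freq, min_depth = 2e4) {
  s <- floor(runif(n)^(-1 / alpha))
  s <- pmin(s, 1e7)
  # scale to depth before winsorising so the integer cap resolves
  # frequencies well below the dominance threshold
  s <- s * max(1, ceiling(min_depth / sum(s)))
  repeat {
    cap <- max(1, floor(cap_freq * sum(s)))
    if (max(s) <= cap) break
    s[s > cap] <- cap
  }
  as.integer(s)
}

# ensure the k largest clones are dominant (used for samples designated
# HEC-positive when the truncated draw happens to produce none)
boost_dominant <- function(s, k, threshold) {
  ord <- order(s, decreasing = TRUE)
  for (i in seq_len(min(k, length(s)))) {
    need <- ceiling(threshold * 1.15 * sum(s))
    if (s[ord[i]] < need) s[ord[i]] <- need
  }
  as.integer(s)
}

# random clone identities: V/J calls and CDR3 aa + nt sequences
# (vectorised: one long random character stream cut into per-clone pieces)
make_clone_ids <- function(n, v_weights, j_weights) {
  len <- as.integer(pmin(pmax(round(rnorm(n, 15, 2)), 8), 28))
  inner_len <- len - 2L
  aa_stream <- intToUtf8(sample(utf8ToInt(paste(aa_alphabet, collapse = "")),
                                sum(inner_len), replace = TRUE))
  aa_stop <- cumsum(inner_len)
  cdr3_aa <- paste0("C",
                    substring(aa_stream, aa_stop - inner_len + 1L, aa_stop),
                    "W")
  nt_len <- 3L * len
  nt_stream <- intToUtf8(sample(utf8ToInt("ACGT"), sum(nt_len),
                                replace = TRUE))
  nt_stop <- cumsum(nt_len)
  cdr3_nt <- substring(nt_stream, nt_stop - nt_len + 1L, nt_stop)
  tibble::tibble(
    v_call = sample(ighv_pool, n, replace = TRUE, prob = v_weights),
    j_call = sample(ighj_pool, n, replace = TRUE, prob = j_weights),
    cdr3_aa = cdr3_aa,
    cdr3_nt = cdr3_nt
  )
}

v_weights_for <- function(compartment, bias) {
  w <- rep(1, length(ighv_pool))
  names(w) <- ighv_pool
  if (compartment == "muscle") {
    w[muscle_biased_v] <- bias
  } else {
    w[blood_biased_v] <- 1 + (bias - 1) / 3
  }
  w / sum(w)
}

j_weights_default <- local({
  w <- rep(1, length(ighj_pool))
  names(w) <- ighj_pool
  w["IGHJ4"] <- 3
  w / sum(w)
})

# one sample's clone-level table (identities + sizes + mutation rates)
simulate_sample <- function(cfg, patient_id, compartment, timepoint,
                            allow_dominant, ids = NULL) {
  n <- sample(cfg$clones_per_sample[1]:cfg$clones_per_sample[2], 1)
  cap <- if (allow_dominant) {
    runif(1, cfg$clonality_cap[1], cfg$clonality_cap[2])
  } else {
    runif(1, 0.5 * cfg$hec_threshold, 0.9 * cfg$hec_threshold)
  }
  s <- sample_clone_sizes(n, cfg$clone_size_law, cap)
  if (allow_dominant) {
    k <- if (compartment == "muscle") 2L else 1L
    s <- boost_dominant(s, k, cfg$hec_threshold)
  }
  if (is.null(ids)) {
    ids <- make_clone_ids(n, v_weights_for(compartment, cfg$v_gene_bias),
                          j_weights_default)
  }
  rate_mean <- if (compartment == "muscle") {
    cfg$mutation_rate_muscle
  } else {
    cfg$mutation_rate_blood
  }
  dplyr::mutate(
    ids,
    sample_id = sprintf("%s_%s_%s", patient_id, compartment, timepoint),
    patient_id = patient_id,
    compartment = compartment,
    timepoint = timepoint,
    size = s,
    mut_rate = stats::rgamma(n, shape = 4, rate = 4 / rate_mean)
  )
}

# expand clone-level rows into sequence records; ~10% of clones are split
# into two records carrying distinct CDR3 nucleotide variants
clones_to_records <- function(clones) {
  split_idx <- which(clones$size >= 4 &
                       runif(nrow(clones)) < 0.1)
  base <- clones
  base$rec_umi <- base$size
  if (length(split_idx) > 0) {
    part <- pmax(1L, floor(base$size[split_idx] / 3))
    base$rec_umi[split_idx] <- base$size[split_idx] - part
    extra <- base[split_idx, ]
    extra$rec_umi <- part
    # synonymous-variant stand-in: mutate the last nucleotide
    extra$cdr3_nt <- paste0(
      substr(extra$cdr3_nt, 1, nchar(extra$cdr3_nt) - 1),
      ifelse(substr(extra$cdr3_nt, nchar(extra$cdr3_nt),
                    nchar(extra$cdr3_nt)) == "A", "G", "A")
    )
    base <- dplyr::bind_rows(base, extra)
  }
  bp <- sample(280:300, nrow(base), replace = TRUE)
  tibble::tibble(
    sample_id = base$sample_id,
    patient_id = base$patient_id,
    compartment = base$compartment,
    timepoint = base$timepoint,
    v_call = base$v_call,
    j_call = base$j_call,
    cdr3_nt = base$cdr3_nt,
    cdr3_aa = base$cdr3_aa,
    umi_count = as.integer(base$rec_umi),
    v_mutation_count = rbinom(nrow(base), bp, pmin(base$mut_rate, 0.5)),
    v_aligned_bp = as.integer(bp)
  )
}

#' Generate a synthetic paired muscle/blood cohort
#'
#' Emits, for each patient, a muscle-baseline, blood-baseline and blood-week9
#' sequence table plus a clinical table, with every planted truth recorded in
#' a ground-truth ledger. See [cohort_config()] for the emulated structure.
#' Fully reproducible: the same config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `bcr_cohort` list: `sequences` (record tibble over all samples),
#'   `clinical` (one row per patient), `truth` (ground-truth ledger: planted
#'   sharing/turnover/coupling structure), `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  withr::with_seed(seed, generate_cohort_impl(config))
}

#' Generate a cohort with all clinical couplings zeroed
#'
#' Identical to [generate_cohort()] except that impact-CK, impact-response
#' and delta-impact couplings are all zero — the null model for type-I error
#' testing of the association layer. Repertoire structure (sharing,
#' turnover, mutation load, V bias) is unchanged.
#'
#' @inheritParams generate_cohort
#' @return A `bcr_cohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(config = cohort_config(),
                                 seed = config$seed) {
  config$impact_ck_coupling <- 0
  config$impact_response_coupling <- 0
  config$dimpact_tis_coupling <- 0
  config$dimpact_mmt_coupling <- 0
  generate_cohort(config, seed = seed)
}

generate_cohort_impl <- function(cfg) {
  np <- cfg$n_patients
  patients <- sprintf("P%02d", seq_len(np))
  thr <- cfg$hec_threshold

  n_no_dom <- round(cfg$frac_blood_without_dominant * np)
  no_dom_patients <- sample(patients, n_no_dom)
  hec_pos <- setdiff(patients, no_dom_patients)
  share_dom_patients <- character(0)
  if (cfg$muscle_blood_sharing_rate > 0 && cfg$dominant_sharing_patients > 0) {
    if (cfg$dominant_sharing_patients > length(hec_pos)) {
      rlang::abort("dominant_sharing_patients exceeds HEC-positive patients",
                   class = "bcr_parameter_error")
    }
    share_dom_patients <- sample(hec_pos,
                                 cfg$dominant_sharing_patients)
  }

  all_clones <- vector("list", np)
  truth_pat <- vector("list", np)

  for (i in seq_len(np)) {
    pid <- patients[i]
    blood_dom_ok <- !(pid %in% no_dom_patients)

    muscle <- simulate_sample(cfg, pid, "muscle", "baseline",
                              allow_dominant = TRUE)
    blood <- simulate_sample(cfg, pid, "blood", "baseline",
                             allow_dominant = blood_dom_ok)

    # --- muscle -> blood sharing ------------------------------------------
    n_blood <- nrow(blood)
    n_share <- round(cfg$muscle_blood_sharing_rate * n_blood)
    if (n_share > nrow(muscle)) {
      rlang::abort("sharing rate demands more clones than muscle contains",
                   class = "bcr_parameter_error")
    }
    shared_keys <- character(0)
    planted_dom_shared <- character(0)
    if (n_share > 0) {
      blood_freq <- blood$size / sum(blood$size)
      blood_dom_idx <- which(blood_freq >= thr)
      blood_sub_idx <- setdiff(seq_len(n_blood), blood_dom_idx)
      # shared identities land in subthreshold slots only, so dominant-in-
      # both sharing occurs exactly where planted below
      if (pid %in% share_dom_patients) {
        mfreq <- muscle$size / sum(muscle$size)
        mdom <- which(mfreq >= thr)
        donor1 <- mdom[which.max(muscle$size[mdom])]
        n_extra <- min(max(0, n_share - 1), length(blood_sub_idx),
                       nrow(muscle) - 1)
        donors <- c(donor1,
                    sample_vec(setdiff(seq_len(nrow(muscle)), donor1),
                               n_extra))
        slots <- c(blood_dom_idx[which.max(blood$size[blood_dom_idx])],
                   sample_vec(blood_sub_idx, n_extra))
        n_share <- n_extra + 1L
      } else {
        n_share <- min(n_share, length(blood_sub_idx))
        donors <- sample.int(nrow(muscle), n_share)
        slots <- sample_vec(blood_sub_idx, n_share)
      }
      id_cols <- c("v_call", "j_call", "cdr3_aa", "cdr3_nt")
      blood[slots, id_cols] <- muscle[donors, id_cols]
      shared_keys <- clone_key(muscle$v_call[donors], muscle$j_call[donors],
                               muscle$cdr3_aa[donors])
      if (pid %in% share_dom_patients) {
        planted_dom_shared <- shared_keys[1]
      }
    }

    # --- week-9 blood with dominant-clone turnover ------------------------
    week9 <- simulate_sample(cfg, pid, "blood", "week9",
                             allow_dominant = blood_dom_ok)
    bfreq <- blood$size / sum(blood$size)
    base_dom <- which(bfreq >= thr)
    keep <- base_dom[runif(length(base_dom)) > cfg$turnover]
    lost <- setdiff(base_dom, keep)
    lost_present <- lost[runif(length(lost)) < 0.5]

    wfreq <- week9$size / sum(week9$size)
    w_dom <- order(week9$size, decreasing = TRUE)[
      seq_len(sum(wfreq >= thr))]
    w_sub <- setdiff(seq_len(nrow(week9)), w_dom)
    id_cols <- c("v_call", "j_call", "cdr3_aa", "cdr3_nt")

    used <- integer(0)
    if (length(keep) > 0) {
      k <- length(keep)
      tgt <- utils::head(w_dom, k)
      if (length(tgt) < k) {
        extra <- utils::head(
          setdiff(order(week9$size, decreasing = TRUE), tgt),
          k - length(tgt)
        )
        tgt <- c(tgt, extra)
      }
      week9[tgt, id_cols] <- blood[keep, id_cols]
      # kept clones must stay dominant after all size adjustments
      # (preserves the per-clone Bernoulli turnover bookkeeping)
      repeat {
        need <- ceiling(thr * 1.2 * sum(week9$size))
        if (all(week9$size[tgt] >= need)) break
        week9$size[tgt] <- pmax(week9$size[tgt], need)
      }
      used <- tgt
    }
    if (length(lost_present) > 0) {
      wfreq <- week9$size / sum(week9$size)
      safe <- setdiff(which(wfreq < 0.8 * thr), used)
      tgt <- sample_vec(safe, min(length(lost_present), length(safe)))
      lost_present <- lost_present[seq_along(tgt)]
      week9[tgt, id_cols] <- blood[lost_present, id_cols]
      used <- c(used, tgt)
    }
    # low-frequency repertoire continuity between the timepoints
    n_persist <- round(cfg$persistence_rate * length(w_sub))
    cand <- setdiff(w_sub, used)
    base_sub <- setdiff(seq_len(nrow(blood)), base_dom)
    n_persist <- min(n_persist, length(cand), length(base_sub))
    if (n_persist > 0) {
      tgt <- sample_vec(cand, n_persist)
      src <- sample_vec(base_sub, n_persist)
      week9[tgt, id_cols] <- blood[src, id_cols]
    }
    # optional forcing of the de novo dominant count
    if (!is.null(cfg$de_novo_dominant_rate)) {
      week9 <- force_de_novo_count(week9, used, thr,
                                   stats::rpois(1, cfg$de_novo_dominant_rate))
    }

    key_of <- function(df, idx) {
      clone_key(df$v_call[idx], df$j_call[idx], df$cdr3_aa[idx])
    }
    truth_pat[[i]] <- list(
      patient_id = pid,
      blood_has_dominant = blood_dom_ok,
      shared_keys = shared_keys,
      planted_dominant_shared = planted_dom_shared,
      baseline_dominant_keys = key_of(blood, base_dom),
      kept_keys = key_of(blood, keep),
      lost_keys = key_of(blood, lost),
      lost_present_keys = key_of(blood, lost_present),
      n_turnover_trials = length(base_dom),
      n_lost = length(lost)
    )
    all_clones[[i]] <- dplyr::bind_rows(muscle, blood, week9)
  }

  clone_tbl <- dplyr::bind_rows(all_clones)
  sequences <- clones_to_records(clone_tbl)

  # --- clinical table with configured couplings ---------------------------
  blood_base <- clone_tbl |>
    dplyr::filter(.data$compartment == "blood") |>
    dplyr::group_by(.data$patient_id, .data$timepoint) |>
    dplyr::summarise(
      impact = {
        f <- .data$size / sum(.data$size)
        sum(f[f >= thr])
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "impact")
  impact_base <- blood_base$baseline[match(patients, blood_base$patient_id)]
  dimpact <- (blood_base$week9 - blood_base$baseline)[
    match(patients, blood_base$patient_id)]

  z_i <- normal_scores(impact_base)
  z_d <- normal_scores(dimpact)
  clinical <- tibble::tibble(
    patient_id = patients,
    subtype = sample(names(cfg$subtype_mix), np, replace = TRUE,
                     prob = cfg$subtype_mix),
    antibody_class = sample(names(cfg$antibody_mix), np, replace = TRUE,
                            prob = cfg$antibody_mix),
    ck_baseline = stats::qlnorm(
      stats::pnorm(cfg$impact_ck_coupling * z_i +
                     sqrt(1 - cfg$impact_ck_coupling^2) * rnorm(np)),
      meanlog = log(1199), sdlog = 1.3
    ),
    mmt_baseline = pmin(pmax(round(rnorm(np, 60, 6)), 20), 78)
  )
  resid <- sqrt(1 - cfg$impact_response_coupling^2 -
                  cfg$dimpact_tis_coupling^2)
  u_tis <- cfg$impact_response_coupling * z_i +
    cfg$dimpact_tis_coupling * z_d + resid * rnorm(np)
  clinical$tis <- pmin(pmax(round(36 + 18 * u_tis), 0), 100)
  dmmt <- 5 + 4 * (cfg$dimpact_mmt_coupling * z_d +
                     sqrt(1 - cfg$dimpact_mmt_coupling^2) * rnorm(np))
  clinical$mmt_followup <- pmin(pmax(round(clinical$mmt_baseline + dmmt),
                                     0), 80)
  clinical$weeks_observed <- ifelse(runif(np) < 12 / 19, 9L,
                                    sample(4:8, np, replace = TRUE))

  truth <- list(
    patients = truth_pat,
    no_dominant_blood_patients = sort(no_dom_patients),
    dominant_sharing_patients = sort(share_dom_patients),
    impact_baseline = stats::setNames(impact_base, patients),
    delta_impact = stats::setNames(dimpact, patients),
    couplings = cfg[c("impact_ck_coupling", "impact_response_coupling",
                      "dimpact_tis_coupling", "dimpact_mmt_coupling")],
    turnover = cfg$turnover,
    hec_threshold = thr
  )
  structure(
    list(sequences = sequences, clinical = clinical, truth = truth,
         config = cfg),
    class = "bcr_cohort"
  )
}

# size-safe index sampling (avoids R's scalar sample() expansion)
sample_vec <- function(x, n) x[sample.int(length(x), n)]

# Blom normal scores of ranks (average ranks for ties) — the rank-coupling
# device behind the Gaussian copula used for clinical variables
normal_scores <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 0.375) / (length(x) + 0.25))
}

# promote/demote week-9 clones so the number of *new* dominant clones equals
# a forced count (slots in `used` hold planted baseline identities)
force_de_novo_count <- function(week9, used, thr, target) {
  total <- sum(week9$size)
  freq <- week9$size / total
  new_dom <- setdiff(which(freq >= thr), used)
  excess <- length(new_dom) - target
  if (excess > 0) {
    demote <- new_dom[order(week9$size[new_dom])][seq_len(excess)]
    week9$size[demote] <- floor(0.8 * thr * total)
  } else if (excess < 0) {
    cand <- setdiff(order(week9$size, decreasing = TRUE),
                    c(used, new_dom))
    promote <- head(cand, -excess)
    week9$size[promote] <- ceiling(thr * 1.2 * total)
  }
  week9
}

#' @export
print.bcr_cohort <- function(x, ...) {
  cat(sprintf(
    "<bcr_cohort> %d patients, %d samples, %d sequence records (seed %d)\n",
    x$config$n_patients, length(unique(x$sequences$sample_id)),
    nrow(x$sequences), x$config$seed
  ))
  invisible(x)
}

#' Write a generated cohort to disk
#'
#' Writes one AIRR-style sequence TSV per sample, the clinical TSV, and the
#' ground-truth ledger as JSON.
#'
#' @param cohort A `bcr_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(cohort$sequences$sample_id)) {
    readr::write_tsv(
      dplyr::filter(cohort$sequences, .data$sample_id == sid),
      file.path(dir, paste0(sid, ".tsv")), progress = FALSE
    )
  }
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  bcr_log("wrote cohort (%d samples) to %s",
          length(unique(cohort$sequences$sample_id)), dir)
  invisible(dir)
}
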