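#' Configuration for the synthetic multi-plate generator
#'
#' Builds the configuration object consumed by [generate_dataset()] and
#' [generate_paired_spun_unspun()]. Defaults emulate a single 22-plate
#' SomaScan-style run of synovial fluid: each 96-well plate carries 83
#' participant study samples, one pooled OA and one pooled knee-injury
#' replicate, five plasma calibrators, three plasma QC wells and three
#' buffer-only blanks. Technical structure is planted on the log scale:
#' a latent intracellular factor with per-SOMAmer loadings that increase as
#' baseline abundance decreases, a processing-batch-linked bimodal
#' high/low artefact, per-plate and per-(plate, SOMAmer) scale effects, a
#' well-position hybridisation gradient, blood-staining, sample-age and
#' freeze-thaw covariate effects, and deliberately planted bad samples and
#' bad SOMAmers for every filter in the battery.
#'
#' @param seed integer seed (mandatory); all randomness derives from it via
#'   fixed-offset sub-streams, so toggling one effect leaves the others'
#'   draws unchanged.
#' @param n_plates number of 96-well plates.
#' @param n_proteins number of human protein SOMAmers.
#' @param n_hyb_controls number of spiked-in hybridisation control SOMAmers.
#' @param n_nonhuman,n_control_somamers planted non-human and
#'   control-type (spuriomer, deprecated, non-biotin, non-cleavable)
#'   SOMAmers; together these are the control-filter truth set.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of
#'   per-protein baseline RFU.
#' @param intracellular_sdlog log-normal scale parameter of the per-sample
#'   latent intracellular score.
#' @param ips_loading_scale scale of the per-SOMAmer intracellular loadings
#'   (log-RFU units per unit score); loadings decrease with abundance.
#' @param bimodal_fraction fraction of protein SOMAmers affected by the
#'   bimodal artefact.
#' @param bimodal_effect total high-minus-low log-RFU gap on affected
#'   SOMAmers (applied as +/- effect/2 with a random per-SOMAmer sign).
#' @param bimodal_flip_prob probability that the high/low status flips
#'   between consecutive processing batches.
#' @param plates_per_batch plates per laboratory processing batch.
#' @param plate_effect_sd SD of per-plate log scale factors.
#' @param plate_factors optional explicit per-plate linear scale factors
#'   (length `n_plates`), overriding the random draw.
#' @param plate_somamer_sd SD of per-(plate, SOMAmer) calibration residuals.
#' @param well_gradient_amplitude,well_sd amplitude of the systematic
#'   column-wise well gradient and SD of the random per-well factor (log).
#' @param bio_sd per-sample-per-SOMAmer biological variation SD (log),
#'   present in study samples only (pooled wells are replicates).
#' @param noise_sd technical replicate noise SD (log).
#' @param n_lowr2,lowr2_noise_multiplier planted low-repeatability SOMAmers
#'   and their technical-noise inflation factor.
#' @param n_age_proteins,age_effect planted sample-age-associated SOMAmers
#'   and slope (log RFU per year).
#' @param n_freezethaw_proteins,freezethaw_effect planted freeze-thaw
#'   associated SOMAmers and slope (log RFU per cycle).
#' @param n_blood_proteins,blood_effect_hba,blood_effect_other blood-linked
#'   SOMAmers; HBA gets its own, larger slope (log RFU per grade step).
#' @param blood_grade_probs distribution of visual blood grades 1-4.
#' @param blood_grade_missing fraction of study samples without a grade.
#' @param n_lod_fail,lod_fail_fraction,lod_fail_depth planted
#'   limit-of-detection failures: in each bad sample, `lod_fail_fraction` of
#'   protein SOMAmers (the lowest-abundance ones) read `lod_fail_depth` log
#'   units below the blank floor.
#' @param n_pc_outlier,pc_outlier_shift planted PC-space outliers; each is
#'   shifted by +/- `pc_outlier_shift` log units along its own random
#'   direction over the lower-abundance half of the proteome.
#' @param n_total_outlier,total_outlier_factor planted total-intensity
#'   outliers (whole-well multiplicative factor on protein SOMAmers).
#' @param n_vendor_flag planted vendor-QC-flagged samples.
#' @param blank_floor,blank_sdlog blank (buffer) noise floor in RFU and its
#'   log-normal spread.
#' @param pool_offset_sd per-SOMAmer SD of the fixed pooled-mixture offsets.
#' @param spun_increment added to the latent intracellular score of the
#'   unspun member of each pair in [generate_paired_spun_unspun()].
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_plates = 22,
                         n_proteins = 400,
                         n_hyb_controls = 6,
                         n_nonhuman = 4,
                         n_control_somamers = 8,
                         baseline_meanlog = log(2000),
                         baseline_sdlog = 0.9,
                         intracellular_sdlog = 0.4,
                         ips_loading_scale = 0.8,
                         bimodal_fraction = 0.35,
                         bimodal_effect = 0.8,
                         bimodal_flip_prob = 0.5,
                         plates_per_batch = 2,
                         plate_effect_sd = 0.1,
                         plate_factors = NULL,
                         plate_somamer_sd = 0.12,
                         well_gradient_amplitude = 0.1,
                         well_sd = 0.15,
                         bio_sd = 0.3,
                         noise_sd = 0.1,
                         n_lowr2 = 30,
                         lowr2_noise_multiplier = 5,
                         n_age_proteins = 30,
                         age_effect = 0.065,
                         n_freezethaw_proteins = 20,
                         freezethaw_effect = 0.15,
                         n_blood_proteins = 10,
                         blood_effect_hba = 0.8,
                         blood_effect_other = 0.25,
                         blood_grade_probs = c(0.70, 0.15, 0.10, 0.05),
                         blood_grade_missing = 0.3,
                         n_lod_fail = 10,
                         lod_fail_fraction = 0.35,
                         lod_fail_depth = 1.0,
                         n_pc_outlier = 5,
                         pc_outlier_shift = 2.0,
                         n_total_outlier = 3,
                         total_outlier_factor = 8,
                         n_vendor_flag = 2,
                         blank_floor = 100,
                         blank_sdlog = 0.25,
                         pool_offset_sd = 0.2,
                         spun_increment = 1.0) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed is mandatory and must be a single finite integer")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("all counts must be nonnegative")
  structure(cfg, class = "synth_config")
}

WELLS_96 <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))

## Role layout of one 96-well plate (counts fixed by the assay design).
PLATE_ROLES <- c(rep("study", 83), "pooled_oa", "pooled_injury",
                 rep("calibrator", 5), rep("plasma_qc", 3), rep("blank", 3))

## ---------------------------------------------------------------------------

#' Generate a synthetic multi-plate dataset with planted ground truth
#'
#' Raw-scale RFU is built as
#' `exp(baseline_p + u_i * lambda_p + bimodal_ip + plate_q + well_w +
#' covariate terms + bio_ip + eps_ip)`. Pooled wells are replicates of a
#' fixed per-group mixture plus technical terms; calibrator wells are drawn
#' around the annotated calibrator reference; blanks are drawn from a
#' log-normal noise floor. Identical seeds give identical output.
#'
#' @param config a [synth_config].
#' @return A list with elements `dataset` (a [soma_dataset], scale
#'   `"raw"`) and `truth` (the planted ground-truth record: per-sample
#'   latent intracellular scores and bimodal statuses, per-plate and
#'   per-well log factors, planted bad-sample and bad-SOMAmer IDs by
#'   failure mode, loadings and effect assignments, and the per-SOMAmer
#'   technical and biological variance components).
#' @export
generate_dataset <- function(config) {
  build_synth(config, paired = FALSE)
}

#' Generate a paired spun/unspun dataset
#'
#' Pairs share every latent term (intracellular score apart), with the
#' unspun member's intracellular score inflated by `config$spun_increment`.
#' Pairing is recorded in the sample table via `participant_id` and `spun`.
#'
#' @param config a [synth_config].
#' @param n_pairs number of participant pairs (>= 2; the paired Cohen's d
#'   needs at least two pairs).
#' @return As [generate_dataset()].
#' @export
generate_paired_spun_unspun <- function(config, n_pairs = 18) {
  if (n_pairs < 2) stop("n_pairs must be >= 2 (paired Cohen's d needs >= 2 pairs)")
  build_synth(config, paired = TRUE, n_pairs = n_pairs)
}

## Core builder shared by the two public generators.
build_synth <- function(config, paired = FALSE, n_pairs = 0L) {
  cfg <- config
  if (!inherits(cfg, "synth_config")) stop("config must be a synth_config")
  s <- derive_seeds(cfg$seed, 24)

  if (paired) {
    n_plates <- max(1L, ceiling(2 * n_pairs / 83))
    ## paired acquisition run: no planted failures
    cfg$n_lod_fail <- cfg$n_pc_outlier <- cfg$n_total_outlier <- cfg$n_vendor_flag <- 0L
  } else n_plates <- cfg$n_plates

  P <- cfg$n_proteins
  n_hyb <- cfg$n_hyb_controls
  n_ctrl <- cfg$n_nonhuman + cfg$n_control_somamers

  ## --- SOMAmer annotation and per-protein parameters -----------------------
  somamers <- with_seed(s[1], {
    baseline <- stats::rnorm(P, cfg$baseline_meanlog, cfg$baseline_sdlog)
    cal_baseline <- baseline + stats::rnorm(P, 0, 0.3)
    rank01 <- (rank(baseline) - 0.5) / P            # 1 = highest abundance
    bins <- ifelse(rank01 > 0.90, 0.00005, ifelse(rank01 > 0.65, 0.005, 0.20))
    list(baseline = baseline, cal_baseline = cal_baseline, bins = bins)
  })
  baseline <- somamers$baseline

  lambda <- with_seed(s[2], {
    rank01 <- (rank(baseline) - 0.5) / P
    lam <- 2 * cfg$ips_loading_scale * stats::plogis(-(rank01 - 0.5) * 6)
    pmax(0, lam + stats::rnorm(P, 0, 0.05 * cfg$ips_loading_scale))
  })

  ## planted SOMAmer subsets (disjoint among proteins)
  planted <- with_seed(s[3], {
    need <- cfg$n_lowr2 + cfg$n_age_proteins + cfg$n_freezethaw_proteins +
      cfg$n_blood_proteins + 1L
    if (need > P) stop("more planted bad SOMAmers requested than proteins available")
    idx <- sample.int(P, need)
    sizes <- c(cfg$n_lowr2, cfg$n_age_proteins, cfg$n_freezethaw_proteins,
               cfg$n_blood_proteins, 1L)
    ends <- cumsum(sizes)
    seg <- function(k) if (sizes[k] > 0) idx[(ends[k] - sizes[k] + 1):ends[k]] else integer()
    list(lowr2 = seg(1), age = seg(2), freezethaw = seg(3), blood = seg(4),
         hba = idx[ends[5]],
         age_sign = sample(c(-1, 1), cfg$n_age_proteins, replace = TRUE),
         ft_sign = sample(c(-1, 1), cfg$n_freezethaw_proteins, replace = TRUE))
  })
  ## low-repeatability SOMAmers are purely technical: no biology, no loading
  lambda[planted$lowr2] <- 0
  noise_mult <- rep(1, P)
  noise_mult[planted$lowr2] <- cfg$lowr2_noise_multiplier

  secretion <- with_seed(s[4], {
    r <- (rank(lambda) - 0.5) / P                   # 1 = highest loading
    cls <- character(P)
    for (i in seq_len(P)) {
      pr <- c(secreted = 0.6 - 0.4 * r[i], nuclear_not_secreted = 0.1 + 0.4 * r[i],
              not_secreted_other = 0.2, unknown = 0.1)
      cls[i] <- sample(names(pr), 1, prob = pr)
    }
    cls
  })

  prot_ids <- sprintf("seq-P%04d", seq_len(P))
  target <- sprintf("TGT%04d", seq_len(P))
  target[planted$hba] <- "HBA"
  ctrl_types <- c(rep("spuriomer", ceiling(cfg$n_control_somamers / 4)),
                  rep("deprecated", ceiling(cfg$n_control_somamers / 4)),
                  rep("non_biotin", ceiling(cfg$n_control_somamers / 4)),
                  rep("non_cleavable", cfg$n_control_somamers))[seq_len(cfg$n_control_somamers)]
  som_tab <- data.frame(
    seq_id = c(prot_ids,
               sprintf("seq-N%03d", seq_len(cfg$n_nonhuman)),
               sprintf("seq-C%03d", seq_len(cfg$n_control_somamers)),
               sprintf("seq-H%03d", seq_len(n_hyb))),
    target_name = c(target,
                    sprintf("MOUSE%03d", seq_len(cfg$n_nonhuman)),
                    sprintf("CTRL%03d", seq_len(cfg$n_control_somamers)),
                    sprintf("HCE%03d", seq_len(n_hyb))),
    dilution_bin = c(somamers$bins, rep(0.005, n_ctrl + n_hyb)),
    organism = c(rep("human", P), rep("mouse", cfg$n_nonhuman),
                 rep("synthetic", cfg$n_control_somamers + n_hyb)),
    somamer_type = c(rep("protein", P + cfg$n_nonhuman), ctrl_types,
                     rep("hyb_control_elution", n_hyb)),
    secretion_class = c(secretion, rep("unknown", n_ctrl + n_hyb)),
    calibrator_reference = c(exp(somamers$cal_baseline), rep(NA_real_, n_ctrl + n_hyb)),
    is_hyb_control = c(rep(FALSE, P + n_ctrl), rep(TRUE, n_hyb)),
    stringsAsFactors = FALSE)
  Ptot <- nrow(som_tab)
  iprot <- seq_len(P)
  inh <- P + seq_len(cfg$n_nonhuman)
  ictl <- P + cfg$n_nonhuman + seq_len(cfg$n_control_somamers)
  ihyb <- P + n_ctrl + seq_len(n_hyb)

  extra_baseline <- with_seed(s[5], list(
    nonhuman = stats::rnorm(cfg$n_nonhuman, log(400), 0.5),
    ctrl = stats::rnorm(cfg$n_control_somamers, log(400), 0.5),
    hyb = stats::rnorm(n_hyb, log(3000), 0.3)))

  ## --- plate / well layout --------------------------------------------------
  n_wells <- 96L * n_plates
  plate_id <- rep(sprintf("P%02d", seq_len(n_plates)), each = 96L)
  well <- rep(WELLS_96, n_plates)
  roles <- with_seed(s[6], {
    unlist(lapply(seq_len(n_plates), function(q) sample(PLATE_ROLES)))
  })
  batch <- rep(ceiling(seq_len(n_plates) / cfg$plates_per_batch), each = 96L)
  n_batches <- max(batch)

  sample_id <- sprintf("S%05d", seq_len(n_wells))
  is_study <- roles == "study"
  n_study <- sum(is_study)

  ## --- per-sample covariates and latent scores -----------------------------
  cov <- with_seed(s[7], {
    g <- sample(1:4, n_wells, replace = TRUE, prob = cfg$blood_grade_probs)
    g[stats::runif(n_wells) < cfg$blood_grade_missing] <- NA
    list(age = stats::runif(n_wells, 0, 8),
         ft = pmin(stats::rpois(n_wells, 1), 4),
         vol = round(stats::runif(n_wells, 0.5, 5), 2),
         grade = g,
         disease = sample(c("oa", "injury", "healthy", "inflammatory"),
                          n_wells, replace = TRUE,
                          prob = c(0.5, 0.35, 0.10, 0.05)))
  })

  u <- with_seed(s[8], stats::rlnorm(n_wells, 0, cfg$intracellular_sdlog))

  ## pairing overrides for the spun/unspun design
  participant <- sprintf("PT%05d", seq_len(n_wells))
  spun <- rep(TRUE, n_wells)
  if (paired) {
    study_pos <- which(is_study)
    if (length(study_pos) < 2 * n_pairs) stop("not enough study wells for pairs")
    keep <- study_pos[seq_len(2 * n_pairs)]
    drop_wells <- setdiff(study_pos, keep)
    pair_of <- rep(seq_len(n_pairs), each = 2)
    participant[keep] <- sprintf("PAIR%03d", pair_of)
    spun[keep] <- rep(c(TRUE, FALSE), n_pairs)
    u_base <- with_seed(s[9], stats::rlnorm(n_pairs, 0, cfg$intracellular_sdlog))
    u[keep] <- u_base[pair_of] + ifelse(spun[keep], 0, cfg$spun_increment)
    ## shared biology within a pair: both members carry the first's covariates
    first <- keep[seq(1, 2 * n_pairs, by = 2)]
    for (f in c("age", "ft", "vol", "grade", "disease"))
      cov[[f]][keep] <- cov[[f]][first][pair_of]
    pair_keep <- keep; pair_first <- first; pair_map <- pair_of
  } else drop_wells <- integer()

  ## --- bimodal batch artefact ----------------------------------------------
  bim <- with_seed(s[10], {
    aff <- sample(setdiff(iprot, planted$lowr2),
                  round(cfg$bimodal_fraction * P))
    sgn <- sample(c(-1, 1), length(aff), replace = TRUE)
    st <- logical(n_batches)
    st[1] <- stats::runif(1) < 0.5
    if (n_batches > 1)
      for (b in 2:n_batches)
        st[b] <- if (stats::runif(1) < cfg$bimodal_flip_prob) !st[b - 1] else st[b - 1]
    list(affected = aff, sign = sgn, batch_high = st)
  })
  status_high <- bim$batch_high[batch]

  ## --- plate, well factors --------------------------------------------------
  plate_log <- with_seed(s[11], {
    if (!is.null(cfg$plate_factors)) {
      if (length(cfg$plate_factors) != n_plates && !paired)
        stop("plate_factors must have length n_plates")
      log(rep_len(cfg$plate_factors, n_plates))
    } else stats::rnorm(n_plates, 0, cfg$plate_effect_sd)
  })
  plate_dev <- with_seed(s[12],
    matrix(stats::rnorm(n_plates * Ptot, 0, cfg$plate_somamer_sd), n_plates, Ptot))
  well_log <- with_seed(s[13], {
    colpos <- as.integer(sub("^[A-H]", "", WELLS_96))
    grad <- cfg$well_gradient_amplitude * (colpos - 6.5) / 11
    rep(grad, n_plates) + stats::rnorm(n_wells, 0, cfg$well_sd)
  })

  ## --- planted bad samples --------------------------------------------------
  badsel <- with_seed(s[14], {
    need <- cfg$n_lod_fail + cfg$n_pc_outlier + cfg$n_total_outlier + cfg$n_vendor_flag
    avail <- setdiff(which(is_study), drop_wells)
    if (need > length(avail))
      stop("more planted bad samples requested than study samples available")
    idx <- sample(avail, need)
    splits <- cumsum(c(cfg$n_lod_fail, cfg$n_pc_outlier, cfg$n_total_outlier,
                       cfg$n_vendor_flag))
    list(lod = idx[seq_len(splits[1])],
         pc = if (cfg$n_pc_outlier) idx[(splits[1] + 1):splits[2]] else integer(),
         total = if (cfg$n_total_outlier) idx[(splits[2] + 1):splits[3]] else integer(),
         vendor = if (cfg$n_vendor_flag) idx[(splits[3] + 1):splits[4]] else integer())
  })

  ## --- assemble log-RFU matrix ---------------------------------------------
  Y <- matrix(NA_real_, n_wells, Ptot)

  pool_prof <- with_seed(s[15], {
    u_pool <- stats::rlnorm(2, 0, cfg$intracellular_sdlog)
    list(oa = baseline + lambda * u_pool[1] + stats::rnorm(P, 0, cfg$pool_offset_sd),
         injury = baseline + lambda * u_pool[2] + stats::rnorm(P, 0, cfg$pool_offset_sd),
         qc = somamers$cal_baseline + stats::rnorm(P, 0, cfg$pool_offset_sd),
         u_pool = u_pool)
  })
  ## the pooled wells' latent score is the mixture's, not the well draw;
  ## control wells carry no intracellular score at all
  u[roles == "pooled_oa"] <- pool_prof$u_pool[1]
  u[roles == "pooled_injury"] <- pool_prof$u_pool[2]
  u[roles %in% c("calibrator", "plasma_qc", "blank")] <- NA_real_

  bio <- with_seed(s[16], matrix(stats::rnorm(n_wells * P, 0, cfg$bio_sd), n_wells, P))
  if (paired)  # pairs share every latent term except the intracellular score
    bio[pair_keep, ] <- bio[pair_first, , drop = FALSE][pair_map, , drop = FALSE]
  eps <- with_seed(s[17], {
    e <- matrix(stats::rnorm(n_wells * Ptot, 0, cfg$noise_sd), n_wells, Ptot)
    e[, iprot] <- sweep(e[, iprot, drop = FALSE], 2, noise_mult, `*`)
    e[, ihyb] <- with_seed(s[18], matrix(stats::rnorm(n_wells * n_hyb, 0, 0.01),
                                         n_wells, n_hyb))
    e
  })

  ## protein columns, study wells
  st <- which(is_study)
  base_m <- matrix(baseline, n_wells, P, byrow = TRUE)
  Ys <- base_m[st, , drop = FALSE] + outer(u[st], lambda) + bio[st, , drop = FALSE]
  ## covariate effects on study samples
  add_eff <- function(M, cols, slope, x) {
    if (length(cols)) M[, cols] <- M[, cols] +
        outer(ifelse(is.na(x), 0, x), rep(1, length(cols))) *
        matrix(slope, length(x), length(cols), byrow = TRUE)
    M
  }
  Ys <- add_eff(Ys, planted$age, planted$age_sign * cfg$age_effect, cov$age[st])
  Ys <- add_eff(Ys, planted$freezethaw, planted$ft_sign * cfg$freezethaw_effect, cov$ft[st])
  gr <- ifelse(is.na(cov$grade[st]), 1, cov$grade[st]) - 1
  Ys <- add_eff(Ys, planted$blood, rep(cfg$blood_effect_other, length(planted$blood)), gr)
  Ys <- add_eff(Ys, planted$hba, cfg$blood_effect_hba, gr)
  Y[st, iprot] <- Ys

  ## pooled wells
  for (g in c("pooled_oa", "pooled_injury")) {
    w <- which(roles == g)
    prof <- if (g == "pooled_oa") pool_prof$oa else pool_prof$injury
    Y[w, iprot] <- matrix(prof, length(w), P, byrow = TRUE)
  }
  ## calibrators and plasma QC
  w <- which(roles == "calibrator")
  Y[w, iprot] <- matrix(somamers$cal_baseline, length(w), P, byrow = TRUE)
  w <- which(roles == "plasma_qc")
  Y[w, iprot] <- matrix(pool_prof$qc, length(w), P, byrow = TRUE)
  ## blanks: buffer floor
  blanks <- with_seed(s[19], {
    w <- which(roles == "blank")
    matrix(log(cfg$blank_floor) + stats::rnorm(length(w) * P, 0, cfg$blank_sdlog),
           length(w), P)
  })
  Y[which(roles == "blank"), iprot] <- blanks

  ## bimodal artefact applies to study + pooled wells of the batch
  sp <- which(roles %in% c("study", "pooled_oa", "pooled_injury"))
  if (length(bim$affected) && cfg$bimodal_effect != 0) {
    shift <- outer(ifelse(status_high[sp], 0.5, -0.5) * cfg$bimodal_effect, bim$sign)
    Y[sp, bim$affected] <- Y[sp, bim$affected] + shift
  }

  ## non-protein columns (flat baselines everywhere; blanks read floor)
  Y[, inh] <- matrix(extra_baseline$nonhuman, n_wells, cfg$n_nonhuman, byrow = TRUE)
  Y[, ictl] <- matrix(extra_baseline$ctrl, n_wells, cfg$n_control_somamers, byrow = TRUE)
  Y[, ihyb] <- matrix(extra_baseline$hyb, n_wells, n_hyb, byrow = TRUE)

  ## planted failures ---------------------------------------------------------
  lod_targets <- order(baseline)[seq_len(round(cfg$lod_fail_fraction * P))]
  if (length(badsel$lod)) {
    lodvals <- with_seed(s[20],
      matrix(log(cfg$blank_floor) - cfg$lod_fail_depth +
               stats::rnorm(length(badsel$lod) * length(lod_targets), 0, cfg$blank_sdlog),
             length(badsel$lod), length(lod_targets)))
    Y[badsel$lod, lod_targets] <- lodvals
  }
  if (length(badsel$pc)) {
    low_half <- order(baseline)[seq_len(floor(P / 2))]
    dirs <- with_seed(s[21],
      matrix(sample(c(-1, 1), length(badsel$pc) * length(low_half), TRUE),
             length(badsel$pc), length(low_half)))
    Y[badsel$pc, low_half] <- Y[badsel$pc, low_half] + cfg$pc_outlier_shift * dirs
  }
  if (length(badsel$total))
    Y[badsel$total, c(iprot, inh, ictl)] <-
      Y[badsel$total, c(iprot, inh, ictl)] + log(cfg$total_outlier_factor)

  ## plate / well / residual technical terms (scanner-level: all columns)
  qidx <- rep(seq_len(n_plates), each = 96L)
  Y <- Y + plate_log[qidx] + plate_dev[qidx, , drop = FALSE] + well_log + eps

  ## --- sample table ----------------------------------------------------------
  disease <- ifelse(roles == "study", cov$disease,
             ifelse(roles == "pooled_oa", "oa",
             ifelse(roles == "pooled_injury", "injury", "none")))
  samp_tab <- data.frame(
    sample_id = sample_id,
    participant_id = ifelse(is_study, participant, ""),
    role = roles,
    plate_id = plate_id,
    well = well,
    processing_batch = batch,
    processing_order = seq_len(n_wells),
    cohort = "synthetic",
    disease_group = disease,
    spun = ifelse(is_study, spun, NA),
    blood_grade = ifelse(is_study, cov$grade, NA),
    volume_ml = ifelse(is_study, cov$vol, NA),
    sample_age_years = ifelse(is_study, round(cov$age, 2), NA),
    freeze_thaw_count = ifelse(is_study, cov$ft, NA),
    vendor_flag = seq_len(n_wells) %in% badsel$vendor,
    stringsAsFactors = FALSE)

  keep_rows <- setdiff(seq_len(n_wells), drop_wells)
  dataset <- soma_dataset(exp(Y[keep_rows, , drop = FALSE]),
                          som_tab, samp_tab[keep_rows, , drop = FALSE],
                          scale_state = "raw",
                          provenance = list(list(op = "generate_dataset",
                                                 params = list(seed = cfg$seed))))

  keep_id <- function(ix) sample_id[intersect(ix, keep_rows)]
  truth <- list(
    intracellular_score = stats::setNames(u[keep_rows], sample_id[keep_rows]),
    bimodal_high = stats::setNames(status_high[keep_rows], sample_id[keep_rows]),
    batch_high = bim$batch_high,
    plate_log_factors = stats::setNames(plate_log, sprintf("P%02d", seq_len(n_plates))),
    well_log_factors = stats::setNames(well_log[keep_rows], sample_id[keep_rows]),
    lambda = stats::setNames(lambda, prot_ids),
    baseline_log = stats::setNames(baseline, prot_ids),
    bimodal_somamers = prot_ids[bim$affected],
    bimodal_signs = stats::setNames(bim$sign, prot_ids[bim$affected]),
    bad_samples = list(lod = keep_id(badsel$lod), pc_outlier = keep_id(badsel$pc),
                       total_rfu = keep_id(badsel$total), vendor_flag = keep_id(badsel$vendor)),
    bad_somamers = list(
      control = som_tab$seq_id[c(inh, ictl, ihyb)],
      confounder = prot_ids[c(planted$age, planted$freezethaw)],
      low_r2 = prot_ids[planted$lowr2]),
    age_somamers = prot_ids[planted$age],
    age_slopes = stats::setNames(planted$age_sign * cfg$age_effect, prot_ids[planted$age]),
    freezethaw_somamers = prot_ids[planted$freezethaw],
    blood_somamers = prot_ids[planted$blood],
    hba_seq_id = prot_ids[planted$hba],
    technical_var = stats::setNames((cfg$noise_sd * noise_mult)^2, prot_ids),
    biological_var = stats::setNames(rep(cfg$bio_sd^2, P) + lambda^2 *
                                       stats::var(u[intersect(st, keep_rows)]), prot_ids),
    pool_profiles = pool_prof,
    lod_fail_somamers = prot_ids[lod_targets])
  list(dataset = dataset, truth = truth)
}
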