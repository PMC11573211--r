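test_that("identical seeds give bitwise-identical datasets", {
  a <- generate_dataset(synth_config(seed = 7, n_plates = 2))
  b <- generate_dataset(synth_config(seed = 7, n_plates = 2))
  expect_identical(a$dataset$rfu, b$dataset$rfu)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(synth_config(seed = 8, n_plates = 2))
  expect_false(identical(a$dataset$rfu, c$dataset$rfu))
})

test_that("with all effects and noise at zero, study wells equal baseline exactly", {
  cfg <- synth_config(seed = 3, n_plates = 1,
                      ips_loading_scale = 0, bimodal_effect = 0,
                      plate_effect_sd = 0, plate_somamer_sd = 0,
                      well_gradient_amplitude = 0, well_sd = 0,
                      bio_sd = 0, noise_sd = 0,
                      age_effect = 0, freezethaw_effect = 0,
                      blood_effect_hba = 0, blood_effect_other = 0,
                      n_lowr2 = 0, n_lod_fail = 0, n_pc_outlier = 0,
                      n_total_outlier = 0, n_vendor_flag = 0)
  g <- generate_dataset(cfg)
  st <- which(g$dataset$samples$role == "study")
  prot <- names(g$truth$baseline_log)
  expected <- matrix(exp(g$truth$baseline_log), length(st), length(prot),
                     byrow = TRUE)
  expect_equal(unname(g$dataset$rfu[st, prot]), expected, tolerance = 1e-12)
})

test_that("the plate design matches the assay layout", {
  g <- fx_small()
  tab <- table(g$dataset$samples$plate_id, g$dataset$samples$role)
  expect_true(all(tab[, "study"] == 83))
  expect_true(all(tab[, "pooled_oa"] == 1))
  expect_true(all(tab[, "pooled_injury"] == 1))
  expect_true(all(tab[, "calibrator"] == 5))
  expect_true(all(tab[, "plasma_qc"] == 3))
  expect_true(all(tab[, "blank"] == 3))
  ## (plate, well) unique, wells within A1-H12
  expect_false(anyDuplicated(paste(g$dataset$samples$plate_id,
                                   g$dataset$samples$well)) > 0)
  expect_true(all(g$dataset$samples$well %in%
                    paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))))
})

test_that("planted truth IDs exist in the dataset and counts match config", {
  g <- fx_small()
  tr <- g$truth
  ids <- g$dataset$samples$sample_id
  for (b in tr$bad_samples) expect_true(all(b %in% ids))
  expect_length(tr$bad_samples$lod, 10)
  expect_length(tr$bad_samples$pc_outlier, 5)
  expect_length(tr$bad_samples$total_rfu, 3)
  expect_length(tr$bad_samples$vendor_flag, 2)
  expect_length(tr$bad_somamers$confounder, 50)
  expect_length(tr$bad_somamers$low_r2, 30)
  expect_length(tr$bad_somamers$control, 18)  # 4 nonhuman + 8 controls + 6 hyb
  expect_true(all(unlist(tr$bad_somamers) %in% g$dataset$somamers$seq_id))
  ## vendor flags set on exactly the planted samples
  flagged <- g$dataset$samples$sample_id[g$dataset$samples$vendor_flag]
  expect_setequal(flagged, tr$bad_samples$vendor_flag)
})

test_that("requesting more bad entities than available is an error", {
  expect_error(generate_dataset(synth_config(seed = 1, n_plates = 1,
                                             n_lod_fail = 100)),
               "more planted bad samples")
  expect_error(generate_dataset(synth_config(seed = 1, n_proteins = 50)),
               "more planted bad SOMAmers")
  expect_error(synth_config(seed = 1, n_lod_fail = -1), "nonnegative")
  expect_error(synth_config(), "seed is mandatory")
})

test_that("marginal log-RFU noise matches the configured scale", {
  ## single-effect config: only replicate noise on study wells
  cfg <- synth_config(seed = 9, n_plates = 2,
                      ips_loading_scale = 0, bimodal_effect = 0,
                      plate_effect_sd = 0, plate_somamer_sd = 0,
                      well_gradient_amplitude = 0, well_sd = 0,
                      bio_sd = 0, noise_sd = 0.2,
                      age_effect = 0, freezethaw_effect = 0,
                      blood_effect_hba = 0, blood_effect_other = 0,
                      n_lowr2 = 0, n_lod_fail = 0, n_pc_outlier = 0,
                      n_total_outlier = 0, n_vendor_flag = 0)
  g <- generate_dataset(cfg)
  st <- which(g$dataset$samples$role == "study")
  prot <- names(g$truth$baseline_log)
  resid <- log(g$dataset$rfu[st, prot]) -
    matrix(g$truth$baseline_log, length(st), length(prot), byrow = TRUE)
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 0.2 / sqrt(n))          # |dmean| < 3 SE
  expect_equal(stats::sd(resid), 0.2, tolerance = 0.01)
})

test_that("sub-streams isolate effects: toggling one leaves others unchanged", {
  base <- generate_dataset(synth_config(seed = 4, n_plates = 2))
  nobim <- generate_dataset(synth_config(seed = 4, n_plates = 2,
                                         bimodal_effect = 0))
  ## plate factors, well factors and intracellular scores identical
  expect_identical(base$truth$plate_log_factors, nobim$truth$plate_log_factors)
  expect_identical(base$truth$well_log_factors, nobim$truth$well_log_factors)
  expect_identical(base$truth$intracellular_score,
                   nobim$truth$intracellular_score)
  ## unaffected SOMAmers carry identical values
  unaffected <- setdiff(names(base$truth$lambda), base$truth$bimodal_somamers)
  st <- which(base$dataset$samples$role == "study")
  expect_equal(base$dataset$rfu[st, unaffected],
               nobim$dataset$rfu[st, unaffected], tolerance = 1e-12)
})

test_that("paired generator shares latents and inflates the unspun score", {
  p <- generate_paired_spun_unspun(synth_config(seed = 2), 18)
  sa <- p$dataset$samples
  st <- which(sa$role == "study")
  expect_length(st, 36)
  expect_identical(sort(table(sa$participant_id[st]))[[1]], 2L)
  u <- p$truth$intracellular_score
  spun_u <- u[sa$sample_id[st[sa$spun[st]]]]
  unspun_u <- u[sa$sample_id[st[!sa$spun[st]]]]
  ## identical ordering of participants across arms
  expect_identical(sa$participant_id[st[sa$spun[st]]],
                   sa$participant_id[st[!sa$spun[st]]])
  expect_equal(unname(unspun_u - spun_u), rep(1.0, 18))
  ## covariates shared within pairs
  expect_identical(sa$sample_age_years[st[sa$spun[st]]],
                   sa$sample_age_years[st[!sa$spun[st]]])
})

test_that("a zero spun increment leaves pairs differing only by noise", {
  ## well effects off: members of a pair occupy different wells
  p <- generate_paired_spun_unspun(synth_config(seed = 2, spun_increment = 0,
                                                noise_sd = 0.05, well_sd = 0,
                                                well_gradient_amplitude = 0), 6)
  sa <- p$dataset$samples
  st <- which(sa$role == "study")
  ## baseline-noise proteins only (planted low-repeatability SOMAmers carry
  ## deliberately inflated replicate noise)
  prot <- setdiff(names(p$truth$lambda), p$truth$bad_somamers$low_r2)
  a <- log(p$dataset$rfu[st[sa$spun[st]], prot])
  b <- log(p$dataset$rfu[st[!sa$spun[st]], prot])
  d <- a - b
  expect_lt(max(abs(d)), 6 * 0.05 * sqrt(2))
  expect_lt(abs(mean(d)), 0.01)
})

test_that("fewer than 2 pairs is an error", {
  expect_error(generate_paired_spun_unspun(synth_config(seed = 1), 1),
               ">= 2")
})
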