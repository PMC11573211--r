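## Shared fixtures, built once per test run and cached. All fixtures are
## generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

## 4-plate dataset for I/O and standardisation unit tests
fx_small <- function() fx("small", function() {
  generate_dataset(synth_config(seed = 1, n_plates = 4))
})

## full 22-plate study-design fixture plus its paired spun/unspun companion
## (same seed: same SOMAmer universe) and a complete pipeline run
fx_full <- function() fx("full", function() {
  g <- generate_dataset(synth_config(seed = 1))
  paired <- generate_paired_spun_unspun(synth_config(seed = 1), 18)
  res <- run_pipeline(pipeline_config(g$dataset, paired$dataset))
  list(truth = g$truth, paired_truth = paired$truth, result = res,
       raw = g$dataset, paired_raw = paired$dataset)
})

## clean fixture (no planted failures) taken through correction, for the
## intracellular-score recovery checks
fx_ips <- function() fx("ips", function() {
  g <- generate_dataset(synth_config(seed = 5, n_lod_fail = 0,
                                     n_pc_outlier = 0, n_total_outlier = 0,
                                     n_vendor_flag = 0))
  paired <- generate_paired_spun_unspun(synth_config(seed = 5), 18)
  std <- run_standardisation(g$dataset)
  lg <- log_transform(std$dataset)
  lg <- subset_dataset(lg, samples = somaqc:::study_pooled_idx(lg))
  p0 <- fit_pca(lg)
  gmm <- fit_pc2_gmm(stats::setNames(p0$scores[, 2], p0$sample_ids))
  corrected <- correct_bimodal_and_plate(lg, gmm)$dataset
  paired_log <- log_transform(run_standardisation(paired$dataset)$dataset)
  list(truth = g$truth, paired_truth = paired$truth,
       corrected = corrected, paired_log = paired_log,
       model = compute_ips_weights(paired_log))
})

## hand-built minimal dataset: `rfu` is samples x SOMAmers
make_dataset <- function(rfu, roles = NULL, plate = NULL, scale_state = "log",
                         somamer_type = NULL, organism = NULL,
                         dilution_bin = NULL, is_hyb = NULL,
                         calibrator_reference = NULL, spun = NULL,
                         participant = NULL, blood_grade = NULL,
                         vendor_flag = NULL, well = NULL) {
  rfu <- as.matrix(rfu)
  n <- nrow(rfu); p <- ncol(rfu)
  if (is.null(roles)) roles <- rep("study", n)
  if (is.null(plate)) plate <- rep("P1", n)
  if (is.null(somamer_type)) somamer_type <- rep("protein", p)
  if (is.null(organism)) organism <- rep("human", p)
  if (is.null(dilution_bin)) dilution_bin <- rep(0.2, p)
  if (is.null(is_hyb)) is_hyb <- somamer_type == "hyb_control_elution"
  if (is.null(calibrator_reference)) calibrator_reference <- rep(NA_real_, p)
  if (is.null(spun)) spun <- rep(NA, n)
  if (is.null(participant)) participant <- sprintf("PT%03d", seq_len(n))
  if (is.null(blood_grade)) blood_grade <- rep(NA_integer_, n)
  if (is.null(vendor_flag)) vendor_flag <- rep(FALSE, n)
  if (is.null(well)) well <- paste0(rep(LETTERS[1:8], each = 12),
                                    rep(1:12, 8))[seq_len(n)]
  som <- data.frame(seq_id = sprintf("seq-%03d", seq_len(p)),
                    target_name = sprintf("T%03d", seq_len(p)),
                    dilution_bin = dilution_bin, organism = organism,
                    somamer_type = somamer_type,
                    secretion_class = "unknown",
                    calibrator_reference = calibrator_reference,
                    is_hyb_control = is_hyb, stringsAsFactors = FALSE)
  sam <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    participant_id = participant, role = roles,
                    plate_id = plate, well = well,
                    processing_batch = 1L, processing_order = seq_len(n),
                    cohort = "test",
                    disease_group = ifelse(roles %in% c("blank", "calibrator",
                                                        "plasma_qc"),
                                           "none", "oa"),
                    spun = spun, blood_grade = blood_grade,
                    volume_ml = NA_real_, sample_age_years = NA_real_,
                    freeze_thaw_count = NA_integer_,
                    vendor_flag = vendor_flag, stringsAsFactors = FALSE)
  soma_dataset(rfu, som, sam, scale_state = scale_state)
}
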