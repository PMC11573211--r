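blank_ds <- function(blanks, extra = NULL) {
  vals <- c(blanks, extra)
  roles <- c(rep("blank", length(blanks)), rep("study", length(extra)))
  make_dataset(matrix(vals, ncol = 1), roles = roles,
               scale_state = "standardised")
}

test_that("LOD follows median + 4.9 x unscaled MAD with an 80000 ceiling", {
  lod <- compute_lod(blank_ds(c(100, 110, 120)))
  expect_equal(unname(lod$lower["P1", 1]), 159)   # 110 + 4.9 * 10
  expect_equal(lod$upper, 80000)
  lod2 <- compute_lod(blank_ds(c(50, 50, 50)))
  expect_equal(unname(lod2$lower["P1", 1]), 50)
  ## scaled-MAD variant is opt-in
  lod3 <- compute_lod(blank_ds(c(100, 110, 120)), mad_scaled = TRUE)
  expect_equal(unname(lod3$lower["P1", 1]), 110 + 4.9 * 1.4826 * 10)
  expect_error(compute_lod(blank_ds(c(100, 110))), ">= 3")
  ## location equivariance of the blank statistics
  l1 <- compute_lod(blank_ds(c(80, 95, 130)))$lower[1, 1]
  l2 <- compute_lod(blank_ds(c(80, 95, 130) + 25))$lower[1, 1]
  expect_equal(l2, l1 + 25)
})

test_that("the 25% LOD rule uses a strict inequality", {
  ## 20 proteins; lower LOD 159 everywhere
  n_low <- c(6, 5)      # 30% fails, exactly 25% survives
  mats <- lapply(n_low, function(k)
    c(rep(100, k), rep(1000, 20 - k)))
  rfu <- rbind(matrix(rep(c(100, 110, 120), 20), 3, 20),  # blanks
               do.call(rbind, mats))
  ds <- make_dataset(rfu, roles = c(rep("blank", 3), "study", "study"),
                     scale_state = "standardised")
  lod <- compute_lod(ds)
  removed <- filter_samples_lod(ds, lod)
  expect_identical(removed, "S004")     # 6/20 = 30% > 25%; 5/20 = 25% kept
})

test_that("PCA outlier filter flags gross score deviations only", {
  set.seed(6)
  x <- matrix(rnorm(500 * 10), 500, 10)
  ## plant an outlier at ~10 SD on the first factor direction
  x[1, ] <- x[1, ] + 10 * sqrt(10)
  ds <- make_dataset(x, scale_state = "log")
  expect_identical(filter_samples_pca(ds), "S001")
  ## all-Gaussian data: no removals
  set.seed(7)
  clean <- make_dataset(matrix(rnorm(1000 * 8), 1000, 8), scale_state = "log")
  expect_length(filter_samples_pca(clean), 0)
  ## radial variant also catches the planted outlier
  expect_identical(filter_samples_pca(ds, mode = "radial"), "S001")
})

test_that("total-RFU filter uses study-sample moments and strict 5 SD", {
  set.seed(8)
  x <- exp(matrix(rnorm(200 * 10, 7, 0.05), 200, 10))
  x[5, ] <- x[5, ] * 10
  ds <- make_dataset(x, scale_state = "standardised")
  expect_identical(filter_samples_total_rfu(ds), "S005")
  same <- make_dataset(matrix(1000, 50, 4), scale_state = "standardised")
  expect_length(filter_samples_total_rfu(same), 0)
})

test_that("vendor flags remove study wells only", {
  ds <- make_dataset(matrix(1000, 6, 2),
                     roles = c("study", "study", "calibrator", "blank",
                               "study", "pooled_oa"),
                     vendor_flag = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
                     scale_state = "standardised")
  expect_setequal(filter_samples_flagged(ds), c("S001", "S005"))
  none <- make_dataset(matrix(1000, 3, 2), scale_state = "standardised")
  expect_length(filter_samples_flagged(none), 0)
})

test_that("confounder filter is Bonferroni-controlled and powered", {
  set.seed(9)
  n <- 300; p <- 80
  age <- runif(n, 0, 8)
  y <- matrix(rnorm(n * p, 6, 0.3), n, p)
  y[, 1:10] <- y[, 1:10] + outer(age, rep(0.15, 10))
  ds <- make_dataset(y, scale_state = "log")
  removed <- filter_somamers_confounder(ds, data.frame(age = age))
  expect_setequal(removed, sprintf("seq-%03d", 1:10))
  expect_error(filter_somamers_confounder(ds, data.frame(k = rep(1, n))),
               "constant")
  expect_error(filter_somamers_confounder(
    subset_dataset(ds, samples = 1:5), data.frame(age = age[1:5])),
    "fewer than 10")
})

test_that("control-reagent filter removes by organism and type", {
  ds <- make_dataset(matrix(1000, 2, 5),
                     somamer_type = c("protein", "protein", "spuriomer",
                                      "deprecated", "protein"),
                     organism = c("human", "mouse", "human", "human", "human"),
                     scale_state = "log")
  expect_setequal(filter_somamers_control(ds),
                  c("seq-002", "seq-003", "seq-004"))
})

test_that("R-squared filter applies the 'either group' rule strictly", {
  r2o <- c(a = 0.6, b = 0.55, c = 0.5, d = 0.9)
  r2i <- c(a = 0.4, b = 0.55, c = 0.5, d = 0.45)
  expect_setequal(filter_somamers_r2(r2o, r2i), c("a", "d"))
  expect_length(filter_somamers_r2(c(a = 0.5), c(a = 0.5)), 0)  # strict <
  expect_error(filter_somamers_r2(c(a = 0.6), c(b = 0.6)), "different")
})

test_that("the full battery removes exactly the planted truth", {
  g <- fx_full()
  tr <- g$truth
  rep <- g$result$branches$without_ips$report
  got <- stats::setNames(lapply(rep$entries, `[[`, "removed"),
                         vapply(rep$entries, `[[`, "", "filter"))
  ## SOMAmer filters: exact category-level recovery
  expect_setequal(got$control_somamers, tr$bad_somamers$control)
  conf_sens <- mean(tr$bad_somamers$confounder %in% got$confounder_association)
  conf_fp <- length(setdiff(got$confounder_association, tr$bad_somamers$confounder))
  expect_gte(conf_sens, 0.95)
  expect_lte(conf_fp, ceiling(0.05 * (418 - 50)))
  r2_sens <- mean(tr$bad_somamers$low_r2 %in% got$low_r2)
  expect_gte(r2_sens, 0.95)
  expect_lte(length(setdiff(got$low_r2, tr$bad_somamers$low_r2)),
             ceiling(0.05 * (418 - 30)))
  ## sample filters: every planted bad sample is removed by the battery
  sample_removed <- unlist(got[c("vendor_flag", "lod_fraction", "total_rfu",
                                 "pca_outlier")])
  for (mode in names(tr$bad_samples))
    expect_gte(mean(tr$bad_samples[[mode]] %in% sample_removed), 0.95)
  ## per-filter specificity against the union of planted bad samples
  planted <- unlist(tr$bad_samples)
  for (f in c("vendor_flag", "lod_fraction", "total_rfu", "pca_outlier")) {
    fp <- length(setdiff(got[[f]], planted))
    expect_lte(fp, ceiling(0.05 * (1826 - length(planted))))
  }
  ## bookkeeping identity: survivors = initial - cumulative removals
  ## (the corrected dataset holds study + pooled wells: 22 * (83 + 2))
  n_sam <- 1870L; n_som <- 418L
  for (e in rep$entries) {
    if (e$type == "somamer") n_som <- n_som - length(e$removed)
    else n_sam <- n_sam - length(e$removed)
    expect_identical(e$surviving_samples, n_sam)
    expect_identical(e$surviving_somamers, n_som)
  }
  expect_identical(rep$surviving_samples, n_sam)
  expect_identical(rep$surviving_somamers, n_som)
})

test_that("re-applying the battery to a clean dataset removes nothing further", {
  cfg <- synth_config(seed = 15, n_plates = 4, n_lod_fail = 0,
                      n_pc_outlier = 0, n_total_outlier = 0, n_vendor_flag = 0,
                      n_lowr2 = 0, n_age_proteins = 0,
                      n_freezethaw_proteins = 0, intracellular_sdlog = 0.2)
  g <- generate_dataset(cfg)
  std <- run_standardisation(g$dataset)
  lg <- log_transform(std$dataset)
  lg <- subset_dataset(lg, samples = somaqc:::study_pooled_idx(lg))
  f1 <- apply_filters(lg, std$dataset)
  ## only structural control reagents go; no sample removals
  expect_identical(f1$report$surviving_samples, nrow(lg$rfu))
  ## closure: a second pass removes nothing
  f2 <- apply_filters(f1$dataset, f1$linear_dataset)
  expect_identical(f2$report$surviving_samples, f1$report$surviving_samples)
  expect_identical(f2$report$surviving_somamers, f1$report$surviving_somamers)
})
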