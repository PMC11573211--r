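## Tiny exactly-solvable hybridisation fixture: 3 wells x (2 proteins +
## 3 hyb controls); controls at (100,100,100), (50,50,50), (200,200,200)
## against per-plate references (100,100,100).
hyb_toy <- function() {
  rfu <- cbind(matrix(c(1000, 500, 2000, 300, 150, 600), 3, 2),
               matrix(c(100, 50, 200), 3, 3))
  make_dataset(rfu, scale_state = "raw",
               somamer_type = c("protein", "protein",
                                rep("hyb_control_elution", 3)))
}

test_that("hybridisation factors follow the median-of-ratios formula", {
  r <- hybridisation_normalise(hyb_toy())
  expect_equal(unname(r$factors), c(1, 2, 0.5))
  ## all values in a well scaled by its factor
  expect_equal(unname(r$dataset$rfu[2, 1]), 1000)
  ## fixed point: per-well median of (reference / value) is exactly 1
  hyb <- r$dataset$rfu[, 3:5]
  ref <- apply(hyb, 2, median)
  ratios <- sweep(1 / hyb, 2, ref, `*`)
  expect_equal(unname(apply(ratios, 1, median)), rep(1, 3), tolerance = 1e-9)
  ## exact multiplicative structure: second application is the identity
  r2 <- hybridisation_normalise(r$dataset)
  expect_equal(unname(r2$factors), rep(1, 3), tolerance = 1e-12)
})

test_that("wells already at reference are untouched", {
  ds <- hyb_toy()
  ds$rfu[, 3:5] <- 100
  r <- hybridisation_normalise(ds)
  expect_equal(unname(r$factors), rep(1, 3))
})

test_that("hybridisation normalisation errors are informative", {
  ds <- make_dataset(matrix(exp(rnorm(6, 7)), 3, 2), scale_state = "raw")
  expect_error(hybridisation_normalise(ds), "no hybridisation control")
  ds2 <- hyb_toy()
  ds2$rfu[2, 4] <- 0
  expect_error(hybridisation_normalise(ds2), "S002")
})

test_that("plate scaling recovers a uniform brightness difference", {
  ## two plates, identical layout; plate 2 uniformly x1.5 brighter
  base <- c(400, 900)
  rfu <- rbind(matrix(base, 4, 2, byrow = TRUE),
               1.5 * matrix(base, 4, 2, byrow = TRUE))
  ds <- make_dataset(rfu, roles = rep(c("study", "calibrator", "calibrator",
                                        "calibrator"), 2),
                     plate = rep(c("P1", "P2"), each = 4),
                     calibrator_reference = base, scale_state = "raw",
                     well = rep(c("A1", "A2", "A3", "A4"), 2))
  r <- plate_scale(ds)
  expect_equal(unname(r$factors), c(1, 2 / 3), tolerance = 1e-12)
  expect_equal(r$dataset$rfu[5, ], r$dataset$rfu[1, ], tolerance = 1e-12)
})

test_that("planted plate factors are recovered within 2%", {
  cfg <- synth_config(seed = 21, n_plates = 4,
                      plate_factors = c(1.0, 1.2, 0.8, 1.1))
  g <- generate_dataset(cfg)
  r1 <- hybridisation_normalise(g$dataset)
  r2 <- plate_scale(r1$dataset)
  expect_equal(unname(r2$factors), 1 / c(1.0, 1.2, 0.8, 1.1),
               tolerance = 0.02)
})

test_that("calibration forces calibrator medians onto the references", {
  ## toy: one SOMAmer at twice its reference in the calibrators
  rfu <- matrix(c(500, 800, 800, 800,
                  900, 450, 450, 450), 4, 2)
  ds <- make_dataset(rfu, roles = c("study", rep("calibrator", 3)),
                     calibrator_reference = c(400, 450), scale_state = "raw")
  r <- calibrate(ds)
  expect_equal(unname(r$factors["P1", ]), c(0.5, 1), tolerance = 1e-12)
  expect_equal(unname(r$dataset$rfu[1, ]), c(250, 900))

  ## fixture: per-plate calibrator medians equal references to <= 1e-9
  g <- fx_small()
  std <- run_standardisation(g$dataset)
  ref <- g$dataset$somamers$calibrator_reference
  ip <- which(g$dataset$somamers$somamer_type == "protein" & !is.na(ref))
  for (q in unique(std$dataset$samples$plate_id)) {
    cal <- which(std$dataset$samples$plate_id == q &
                   std$dataset$samples$role == "calibrator")
    med <- apply(std$dataset$rfu[cal, ip], 2, median)
    expect_lt(max(abs(med - ref[ip]) / ref[ip]), 1e-9)
  }
})

test_that("median normalisation restores a uniformly scaled sample", {
  set.seed(1)
  base <- matrix(exp(rnorm(60, 7)), 6, 10)
  base[2, ] <- 3 * base[1, ]
  ds <- make_dataset(base, scale_state = "raw",
                     dilution_bin = rep(c(0.2, 0.005), each = 5))
  r <- median_normalise(ds)
  expect_equal(unname(r$factors[2, ]),
               unname(r$factors[1, ]) / 3, tolerance = 1e-9)
  ## identical samples: all factors 1
  same <- make_dataset(matrix(rep(exp(rnorm(10, 7)), each = 4), 4, 10),
                       scale_state = "raw")
  expect_true(all(median_normalise(same)$factors == 1))
})

test_that("run_standardisation applies steps in order and records provenance", {
  g <- fx_small()
  expect_error(run_standardisation(g$dataset, c("hyb", "hyb")), "repeated")
  expect_error(run_standardisation(g$dataset, c("hyb", "unknown")), "unknown")
  r <- run_standardisation(g$dataset, c("hyb", "plate", "median", "cal"))
  ops <- vapply(r$dataset$provenance, `[[`, "", "op")
  expect_identical(ops[-1],
                   c("hybridisation_normalise", "plate_scale",
                     "median_normalise", "calibrate", "run_standardisation"))
  expect_identical(r$dataset$scale_state, "standardised")
  expect_error(run_standardisation(r$dataset), "raw-scale")
})

test_that("stored factors reproduce the standardised data from raw", {
  g <- fx_small()
  r <- run_standardisation(g$dataset)
  replayed <- apply_factors(g$dataset, r$factors)
  expect_equal(replayed$rfu, r$dataset$rfu, tolerance = 1e-12)
  expect_true(all(unlist(lapply(r$factors, function(f) all(f > 0 & is.finite(f))))))
})

test_that("dilution-adjusted abundance divides by the bin fraction", {
  rfu <- matrix(1000, 3, 2)
  ds <- make_dataset(rfu, scale_state = "standardised",
                     dilution_bin = c(0.005, 0.2))
  ab <- dilution_adjusted_abundance(ds)
  expect_equal(unname(ab), c(200000, 5000))
  ## equal medians order inversely to the bin fraction
  expect_gt(ab[1], ab[2])

  g <- fx_small()
  std <- run_standardisation(g$dataset)
  ab <- dilution_adjusted_abundance(std$dataset)
  prot <- names(g$truth$baseline_log)
  ## generating construction: baseline plus the median intracellular lift,
  ## divided by the dilution-bin fraction
  st2 <- g$dataset$samples$role == "study"
  med_u <- median(g$truth$intracellular_score[
    g$dataset$samples$sample_id[st2]])
  truth <- g$truth$baseline_log + g$truth$lambda * med_u -
    log(std$dataset$somamers$dilution_bin[
      match(prot, std$dataset$somamers$seq_id)])
  expect_gt(cor(ab[prot], truth, method = "spearman"), 0.95)
})

test_that("log transform is exact and guards its domain", {
  ds <- make_dataset(matrix(exp(1), 2, 2), scale_state = "standardised")
  lg <- log_transform(ds)
  expect_equal(unname(lg$rfu), matrix(1, 2, 2))
  expect_identical(lg$scale_state, "log")
  lg2 <- log_transform(make_dataset(matrix(8, 2, 2), scale_state = "standardised"),
                       base = 2)
  expect_equal(unname(lg2$rfu), matrix(3, 2, 2))
  bad <- make_dataset(matrix(c(1, -1, 2, 3), 2, 2), scale_state = "standardised")
  expect_error(log_transform(bad), "nonpositive RFU")
  ## round trip
  g <- fx_small()
  std <- run_standardisation(g$dataset)
  back <- exp(log_transform(std$dataset)$rfu)
  expect_lt(max(abs(back - std$dataset$rfu) / std$dataset$rfu), 1e-12)
})

test_that("pooled-replicate %CV decreases across the default steps", {
  g <- fx_full()
  mean_cv <- function(ds) {
    ip <- which(ds$somamers$somamer_type == "protein" &
                  ds$somamers$organism == "human")
    oa <- which(ds$samples$role == "pooled_oa")
    m <- ds$rfu[oa, ip]
    mean(100 * apply(m, 2, sd) / colMeans(m))
  }
  ds <- g$raw
  cvs <- mean_cv(ds)
  for (f in list(hybridisation_normalise, plate_scale, calibrate)) {
    ds <- f(ds)$dataset
    cvs <- c(cvs, mean_cv(ds))
  }
  expect_true(all(diff(cvs) < 0))
})
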