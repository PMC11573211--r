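test_that("the PC2 mixture separates well-separated components", {
  x <- c(rep(-10, 30), rep(10, 30)) + rnorm(60, 0, 1e-3)
  a <- fit_pc2_gmm(x, seed = 0)
  expect_true(a$converged)
  expect_true(all(a$posterior > 0.999))
  expect_identical(as.character(a$status[1]), "low")
  expect_identical(as.character(a$status[60]), "high")
  expect_gt(a$params$mean[1], a$params$mean[2])  # "high" has larger mean
})

test_that("a degenerate constant input is flagged, not fitted", {
  expect_warning(a <- fit_pc2_gmm(rep(1, 20)), "degenerate")
  expect_false(a$converged)
  expect_true(all(a$posterior == 0.5))
  expect_error(fit_pc2_gmm(c(rnorm(10), NA)), "non-finite")
  expect_error(fit_pc2_gmm(rnorm(5)), ">= 10")
})

test_that("classification approaches the Bayes rate on a 4-sigma mixture", {
  set.seed(3)
  lab <- rbinom(1000, 1, 0.5)
  x <- rnorm(1000, ifelse(lab == 1, 2, -2), 1)
  a <- fit_pc2_gmm(x, seed = 3)
  acc <- mean((a$status == "high") == (lab == 1))
  expect_gte(acc, 0.97)   # Bayes-optimal about 97.7%
  ## label convention is stable under input reordering
  perm <- sample(1000)
  b <- fit_pc2_gmm(x[perm], seed = 3)
  expect_identical(as.character(b$status), as.character(a$status[perm]))
})

## small labelled dataset builder for ComBat tests
combat_fixture <- function(seed, n = 50, p = 20, nb = 3) {
  set.seed(seed)
  y <- matrix(rnorm(n * p, 10, 2), n, p)
  b <- sample(rep(seq_len(nb), length.out = n))
  if (nb >= 2) y[b == 2, ] <- y[b == 2, ] + 1
  if (nb >= 3) y[b == 3, ] <- y[b == 3, ] * 1.1
  list(ds = make_dataset(y, scale_state = "log"), batch = b, y = y)
}

test_that("a single batch is the identity", {
  f <- combat_fixture(1, n = 20, p = 10, nb = 1)
  out <- combat(f$ds, rep("a", 20))
  expect_lt(max(abs(out$dataset$rfu - f$y)), 1e-8)
})

test_that("ComBat matches the reference implementation elementwise", {
  maxdiff <- 0
  for (s in 1:20) {
    f <- combat_fixture(s)
    mine <- combat(f$ds, f$batch)$dataset$rfu
    ref <- t(sva::ComBat(t(f$y), batch = f$batch))
    maxdiff <- max(maxdiff, max(abs(mine - ref)))
  }
  expect_lt(maxdiff, 1e-6)
})

test_that("ComBat with a protected covariate matches the reference", {
  set.seed(7)
  f <- combat_fixture(7)
  covar <- rnorm(50)
  mine <- combat(f$ds, f$batch, design = cbind(covar))$dataset$rfu
  ref <- t(sva::ComBat(t(f$y), batch = f$batch,
                       mod = model.matrix(~covar)))
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("ComBat removes a planted per-gene location/scale batch effect", {
  set.seed(8)
  n <- 8000; p <- 100
  y <- matrix(rnorm(n * p), n, p)
  b <- rep(1:2, each = n / 2)
  ## heterogeneous effects: per-SOMAmer shift and scale for batch 2 (the
  ## regime the empirical-Bayes prior is built for)
  shift <- rnorm(p, 1, 0.5)
  scale <- exp(rnorm(p, log(2), 0.2))
  y[b == 2, ] <- sweep(sweep(y[b == 2, ], 2, scale, `*`), 2, shift, `+`)
  out <- combat(make_dataset(y, scale_state = "log"), b)$dataset$rfu
  smd <- abs(colMeans(out[b == 1, ]) - colMeans(out[b == 2, ])) /
    apply(out, 2, sd)
  vr <- apply(out[b == 1, ], 2, var) / apply(out[b == 2, ], 2, var)
  expect_gte(mean(smd < 0.05), 0.95)
  expect_gte(mean(vr > 0.9 & vr < 1.1), 0.95)
  ## grand means essentially preserved, values finite
  expect_lt(max(abs(colMeans(out) - colMeans(y))), 0.05)
  expect_true(all(is.finite(out)))
})

test_that("shrinkage vanishes in the large-batch limit", {
  set.seed(9)
  n <- 20000; p <- 6
  y <- matrix(rnorm(n * p), n, p)
  b <- rep(1:2, each = n / 2)
  y[b == 2, ] <- y[b == 2, ] + rep(rnorm(p, 0, 0.5), each = n / 2)
  m <- combat(make_dataset(y, scale_state = "log"), b)$model
  expect_lt(max(abs(m$gamma_star - m$gamma_hat)), 1e-3)
  ## estimation constraint: size-weighted unshrunk batch means sum to zero
  w <- m$batch_sizes / sum(m$batch_sizes)
  expect_lt(max(abs(drop(w %*% m$gamma_hat))), 1e-10)
})

test_that("ComBat validates its inputs", {
  f <- combat_fixture(2, n = 21, p = 5, nb = 2)
  bad <- f$batch
  bad[bad == 2] <- 1
  bad[1] <- 2   # singleton batch
  expect_error(combat(f$ds, bad), "fewer than 2")
  conf <- model.matrix(~ 0 + factor(f$batch))[, 1, drop = FALSE]
  expect_error(combat(f$ds, f$batch, design = conf), "confounded")
  lin <- f$ds; lin$scale_state <- "standardised"
  expect_error(combat(lin, f$batch), "log-scale")
})

test_that("sequential status/plate correction closes the bimodal gap", {
  g <- fx_full()
  res <- g$result
  ## status groups overlap on PC2 after correction (both branches filtered)
  pca <- res$branches$without_ips$pca
  st <- g$truth$bimodal_high[pca$sample_ids]
  ks <- suppressWarnings(stats::ks.test(pca$scores[st, 2],
                                        pca$scores[!st, 2]))
  expect_gt(ks$p.value, 0.01)
  ## per-SOMAmer status effect is gone: BH-significant count near zero
  corr <- res$corrected
  stc <- g$truth$bimodal_high[corr$samples$sample_id]
  p <- apply(corr$rfu, 2, function(v) stats::t.test(v[stc], v[!stc])$p.value)
  expect_lt(mean(p.adjust(p, "BH") < 0.05), 0.01)
})

test_that("correction without planted batch structure is nearly a no-op", {
  ## a null run: replicate noise and per-sample biology only
  cfg <- synth_config(seed = 12, ips_loading_scale = 0, bimodal_effect = 0,
                      plate_effect_sd = 0, plate_somamer_sd = 0,
                      blood_effect_hba = 0, blood_effect_other = 0,
                      age_effect = 0, freezethaw_effect = 0,
                      pool_offset_sd = 0, n_lowr2 = 0,
                      n_lod_fail = 0, n_pc_outlier = 0, n_total_outlier = 0,
                      n_vendor_flag = 0)
  g <- generate_dataset(cfg)
  lg <- log_transform(run_standardisation(g$dataset)$dataset)
  lg <- subset_dataset(lg, samples = somaqc:::study_pooled_idx(lg))
  p0 <- fit_pca(lg)
  gmm <- fit_pc2_gmm(stats::setNames(p0$scores[, 2], p0$sample_ids))
  ## the single-Gaussian model wins by BIC, so the status pass is skipped;
  ## the plate pass only tracks batch-estimation noise
  expect_false(gmm$bimodal)
  expect_message(out <- correct_bimodal_and_plate(lg, gmm)$dataset,
                 "no bimodal signal")
  expect_lt(max(abs(out$rfu - lg$rfu)), 0.4)
  data_sd <- stats::sd(sweep(lg$rfu, 2, colMeans(lg$rfu)))
  expect_lt(mean(abs(out$rfu - lg$rfu)), 0.25 * data_sd)
})
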