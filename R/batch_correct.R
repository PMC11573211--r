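## Bimodal-status detection (1-D two-component Gaussian mixture on PC2)
## and parametric empirical-Bayes location/scale batch correction (ComBat)
## written from first principles.

dnorm_safe <- function(x, m, s2) stats::dnorm(x, m, sqrt(pmax(s2, 1e-300)))

## One EM run from given initial means; returns parameters and loglik.
em_gmm2 <- function(x, m1, m2, s1, s2, w = 0.5, tol = 1e-8, max_iter = 500L) {
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p1 <- w * dnorm_safe(x, m1, s1)
    p2 <- (1 - w) * dnorm_safe(x, m2, s2)
    tot <- p1 + p2
    if (any(tot <= 0) || !all(is.finite(tot))) break
    r <- p1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(r)
    if (n1 < 1e-10 || n - n1 < 1e-10) break
    m1 <- sum(r * x) / n1
    m2 <- sum((1 - r) * x) / (n - n1)
    s1 <- sum(r * (x - m1)^2) / n1
    s2 <- sum((1 - r) * (x - m2)^2) / (n - n1)
    if (s1 < 1e-12 || s2 < 1e-12) break
    w <- n1 / n
  }
  list(m = c(m1, m2), s2 = c(s1, s2), w = w, loglik = ll_old,
       converged = converged, iter = it)
}

#' Classify samples into bimodal high/low status by a PC2 Gaussian mixture
#'
#' Fits a one-dimensional two-component Gaussian mixture (distinct
#' variances, free mixing weight) to per-sample PC2 scores by EM,
#' initialised at the 25th/75th percentiles with four additional seeded
#' random restarts (best likelihood kept). Samples are assigned by maximum
#' posterior; the component with the larger mean is labelled `"high"`.
#' Exact posterior ties go to the lower-mean component and are flagged.
#'
#' @param pc2_scores numeric vector of per-sample scores (>= 10 samples).
#' @param seed integer seed for the EM restarts (recorded).
#' @return An object of class `bimodal_assignment`: `status` (factor
#'   high/low, named by sample where scores were named), `posterior`
#'   (probability of the assigned status, in \[0.5, 1\]), `params` (means,
#'   variances, mixing weight), `bimodal` (whether the two-component fit
#'   beats a single Gaussian by BIC), `bic`, `converged`, `tied`, `seed`.
#' @export
fit_pc2_gmm <- function(pc2_scores, seed = 0L) {
  x <- as.numeric(pc2_scores)
  if (any(!is.finite(x))) stop("non-finite PC2 scores")
  if (length(x) < 10) stop("need >= 10 samples for the mixture fit")
  if (stats::sd(x) == 0) {
    warning("all scores equal: degenerate mixture; posteriors set to 0.5")
    status <- factor(rep("low", length(x)), levels = c("high", "low"))
    names(status) <- names(pc2_scores)
    return(structure(list(status = status,
                          posterior = rep(0.5, length(x)),
                          params = list(mean = rep(x[1], 2),
                                        var = c(0, 0), weight = 0.5),
                          bimodal = FALSE, bic = c(one = NA_real_, two = NA_real_),
                          converged = FALSE, tied = rep(TRUE, length(x)),
                          seed = seed), class = "bimodal_assignment"))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  v <- stats::var(x)
  n <- length(x)
  ## single-component reference: is there a bimodal signal at all?
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                          log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  fits <- list(em_gmm2(x, q[1], q[2], v, v))
  restarts <- with_seed(seed, replicate(4, sort(sample(x, 2)) +
                                          stats::rnorm(2, 0, stats::sd(x) / 10),
                                        simplify = FALSE))
  for (r in restarts) fits[[length(fits) + 1]] <- em_gmm2(x, r[1], r[2], v, v)
  ll <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(ll)]]
  ## order components so that 1 = high (larger mean)
  ord <- order(best$m, decreasing = TRUE)
  m <- best$m[ord]; s2 <- best$s2[ord]
  w <- if (ord[1] == 1) best$w else 1 - best$w
  p_high <- w * dnorm_safe(x, m[1], s2[1])
  p_low <- (1 - w) * dnorm_safe(x, m[2], s2[2])
  post_high <- p_high / (p_high + p_low)
  tied <- abs(post_high - 0.5) < 1e-12
  status <- factor(ifelse(post_high > 0.5 & !tied, "high", "low"),
                   levels = c("high", "low"))
  names(status) <- names(pc2_scores)
  bic2 <- -2 * best$loglik + 5 * log(n)
  structure(list(status = status,
                 posterior = pmax(post_high, 1 - post_high),
                 params = list(mean = m, var = s2, weight = w),
                 bimodal = bic2 < bic1, bic = c(one = bic1, two = bic2),
                 converged = best$converged, tied = tied, seed = seed),
            class = "bimodal_assignment")
}

#' @export
print.bimodal_assignment <- function(x, ...) {
  cat("bimodal_assignment:", sum(x$status == "high"), "high /",
      sum(x$status == "low"), "low;",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  means:", fmt_num(x$params$mean), " vars:", fmt_num(x$params$var),
      " weight(high):", fmt_num(x$params$weight), "\n")
  invisible(x)
}

#' Parametric empirical-Bayes batch correction (ComBat)
#'
#' Location/scale adjustment of every SOMAmer for a known batch factor.
#' Per SOMAmer the data are standardised around the batch-size-weighted
#' grand mean and pooled variance (optionally retaining covariate effects),
#' batchwise location and scale estimates are shrunk towards normal /
#' inverse-gamma priors fitted across SOMAmers by the method of moments,
#' the shrunken estimates are found by the standard iterative conditional
#' updates (tolerance 1e-4), and the data are back-transformed.
#'
#' @param dataset a log-scale [soma_dataset].
#' @param batch per-sample batch labels (length = samples; every batch
#'   needs >= 2 samples).
#' @param design optional per-sample covariate matrix to protect (no
#'   intercept column); must not be confounded with batch.
#' @param conv convergence tolerance of the conditional updates.
#' @return A list with the corrected `dataset` and `model` (class
#'   `combat_model`): batch levels and sizes, `alpha` (grand mean per
#'   SOMAmer), `beta` (covariate coefficients), `sigma2` (pooled variance),
#'   `gamma_hat`/`delta_hat` (unshrunk), `gamma_star`/`delta_star`
#'   (shrunk), prior hyperparameters, iterations per batch.
#' @export
combat <- function(dataset, batch, design = NULL, conv = 1e-4) {
  if (!dataset$scale_state %in% c("log", "adjusted"))
    stop("combat expects log-scale data")
  batch <- droplevels(as.factor(batch))
  if (length(batch) != nrow(dataset$rfu))
    stop("batch labels must align with samples")
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("batch with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  dat <- t(dataset$rfu)                      # SOMAmers x samples
  n_array <- ncol(dat)
  levels_b <- levels(batch)
  n_batch <- length(levels_b)
  batches <- lapply(levels_b, function(b) which(batch == b))
  n_batches <- vapply(batches, length, 0L)

  if (n_batch == 1) {
    model <- structure(list(batch_levels = levels_b, batch_sizes = n_batches,
                            note = "single batch: identity"),
                       class = "combat_model")
    return(list(dataset = add_provenance(dataset, "combat",
                                         list(batches = n_batch)),
                model = model))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  X <- batch_design
  if (!is.null(design)) {
    design <- as.matrix(design)
    X <- cbind(batch_design, design)
  }
  if (qr(X)$rank < ncol(X))
    stop("design is confounded with batch (rank-deficient combined design)")

  B_hat <- solve(crossprod(X), t(X) %*% t(dat))       # (n_batch+q) x G
  grand_mean <- crossprod(n_batches / n_array, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- drop(((dat - t(X %*% B_hat))^2) %*% rep(1 / n_array, n_array))
  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  if (!is.null(design)) {
    tmp <- X
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / (sqrt(var_pooled) %*% t(rep(1, n_array)))

  gamma_hat <- solve(crossprod(batch_design), t(batch_design) %*% t(s_data))
  delta_hat <- t(vapply(batches, function(ix)
    apply(s_data[, ix, drop = FALSE], 1, stats::var), numeric(nrow(dat))))
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }
  a_prior <- apply(delta_hat, 1, aprior)
  b_prior <- apply(delta_hat, 1, bprior)

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(n_batch)
  for (i in seq_len(n_batch)) {
    sdat <- s_data[, batches[[i]], drop = FALSE]
    n <- rowSums(!is.na(sdat))
    g_hat <- gamma_hat[i, ]; g_old <- g_hat
    d_old <- delta_hat[i, ]
    change <- 1; it <- 0L
    while (change > conv) {
      it <- it + 1L
      g_new <- (t2[i] * n * g_hat + d_old * gamma_bar[i]) / (t2[i] * n + d_old)
      sum2 <- rowSums((sdat - g_new %*% t(rep(1, ncol(sdat))))^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
    iters[i] <- it
  }

  bayesdata <- s_data
  for (i in seq_len(n_batch)) {
    ix <- batches[[i]]
    bayesdata[, ix] <- (bayesdata[, ix, drop = FALSE] - gamma_star[i, ]) /
      (sqrt(delta_star[i, ]) %*% t(rep(1, n_batches[i])))
  }
  bayesdata <- bayesdata * (sqrt(var_pooled) %*% t(rep(1, n_array))) + stand_mean

  dataset$rfu <- t(bayesdata)
  dataset <- add_provenance(dataset, "combat",
                            list(batches = n_batch, conv = conv,
                                 covariates = if (is.null(design)) 0 else ncol(design)))
  model <- structure(list(
    batch_levels = levels_b, batch_sizes = n_batches,
    alpha = drop(grand_mean),
    beta = if (is.null(design)) NULL else
      B_hat[(n_batch + 1):nrow(B_hat), , drop = FALSE],
    sigma2 = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2, a_prior = a_prior, b_prior = b_prior,
    iterations = iters), class = "combat_model")
  list(dataset = dataset, model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat("combat_model:", length(x$batch_levels), "batches (",
      paste(x$batch_sizes, collapse = ", "), "samples )\n")
  invisible(x)
}

#' Correct the bimodal artefact and plate effects with sequential ComBat
#'
#' Runs ComBat with the bimodal high/low status as the batch factor, then
#' with the plate as the batch factor (order configurable); alternatively
#' a single run on the status-by-plate interaction.
#'
#' @param dataset a log-scale [soma_dataset] with plate labels.
#' @param assignment a [fit_pc2_gmm()] assignment aligned with the
#'   dataset's samples.
#' @param order `c("bimodal", "plate")` (default), its reverse, or
#'   `"interaction"` for a single run on the crossed factor.
#' @return A list with the corrected `dataset` and `models` (one
#'   `combat_model` per pass).
#' @export
correct_bimodal_and_plate <- function(dataset, assignment,
                                      order = c("bimodal", "plate")) {
  status <- assignment$status
  if (!is.null(names(status))) status <- status[dataset$samples$sample_id]
  if (length(status) != nrow(dataset$rfu) || anyNA(status))
    stop("assignment does not cover the dataset's samples")
  models <- list()
  ## only correct for status when the mixture actually found two modes
  ## (BIC of the 2-component fit below the single-Gaussian fit); otherwise
  ## the assignment merely splits a continuum and "correction" would strip
  ## genuine variance along that axis
  if (isFALSE(assignment$bimodal) && !identical(order, "interaction")) {
    message("no bimodal signal detected (single-component BIC preferred); ",
            "skipping the status correction pass")
    order <- setdiff(order, "bimodal")
  }
  if (identical(order, "interaction")) {
    b <- interaction(status, dataset$samples$plate_id, drop = TRUE)
    res <- combat(dataset, b)
    dataset <- res$dataset
    models$interaction <- res$model
  } else {
    for (step in order) {
      b <- switch(step, bimodal = status, plate = dataset$samples$plate_id,
                  stop("unknown correction step: ", step))
      res <- combat(dataset, b)
      dataset <- res$dataset
      models[[step]] <- res$model
    }
  }
  list(dataset = dataset, models = models)
}
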