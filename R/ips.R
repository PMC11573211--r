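## Intracellular Protein Score (IPS): a per-sample weighted sum of log
## protein levels, IPS_i = sum_p d_p * C_ip, where the weight d_p is the
## paired Cohen's d of the log difference between unspun and spun aliquots
## of the same synovial fluid. Higher IPS means more intracellular signal
## (unspun minus spun sign convention).

#' Estimate IPS weights from paired spun/unspun samples
#'
#' For each protein SOMAmer, the per-pair difference
#' `delta_j = log C(unspun_j) - log C(spun_j)` is summarised as the paired
#' Cohen's d (d_z): `mean(delta) / sd(delta)` with the n-1 standard
#' deviation. A pooled-SD variant is available. SOMAmers whose differences
#' have zero variance are excluded from the score and listed.
#'
#' @param paired_dataset a log-scale [soma_dataset] whose study samples
#'   pair by `participant_id` with `spun` TRUE/FALSE members.
#' @param variant `"dz"` (paired; default) or `"pooled"` (mean difference
#'   over the pooled SD of the two arms).
#' @return An object of class `ips_model`: `weights` (named per-SOMAmer),
#'   `n_pairs`, `excluded` (seq_ids with zero-variance differences),
#'   `variant`, `scale_note`.
#' @export
compute_ips_weights <- function(paired_dataset, variant = c("dz", "pooled")) {
  variant <- match.arg(variant)
  if (!paired_dataset$scale_state %in% c("log", "adjusted"))
    stop("compute_ips_weights expects log-scale data")
  sa <- paired_dataset$samples
  st <- which(sa$role == "study" & !is.na(sa$spun))
  ids <- sa$participant_id[st]
  spun_rows <- st[sa$spun[st]]
  unspun_rows <- st[!sa$spun[st]]
  if (length(spun_rows) != length(unspun_rows)) {
    orphan <- names(which(table(ids) != 2))
    stop("unmatched pair member(s) for participant(s): ",
         paste(orphan, collapse = ", "))
  }
  m <- match(sa$participant_id[spun_rows], sa$participant_id[unspun_rows])
  if (anyNA(m)) {
    orphan <- sa$sample_id[spun_rows][is.na(m)]
    stop("unmatched pair member(s): ", paste(orphan, collapse = ", "))
  }
  unspun_rows <- unspun_rows[m]
  n_pairs <- length(spun_rows)
  if (n_pairs < 2) stop("need at least 2 complete spun/unspun pairs")
  ip <- which(paired_dataset$somamers$somamer_type == "protein" &
                paired_dataset$somamers$organism == "human")
  delta <- paired_dataset$rfu[unspun_rows, ip, drop = FALSE] -
    paired_dataset$rfu[spun_rows, ip, drop = FALSE]
  mu <- colMeans(delta)
  sdd <- apply(delta, 2, stats::sd)
  if (variant == "pooled") {
    s1 <- apply(paired_dataset$rfu[spun_rows, ip, drop = FALSE], 2, stats::var)
    s2 <- apply(paired_dataset$rfu[unspun_rows, ip, drop = FALSE], 2, stats::var)
    sdd <- sqrt((s1 + s2) / 2)
  }
  zero <- sdd == 0
  if (all(zero)) warning("all SOMAmers have zero-variance differences; empty IPS model")
  weights <- mu[!zero] / sdd[!zero]
  names(weights) <- paired_dataset$somamers$seq_id[ip][!zero]
  structure(list(weights = weights, n_pairs = n_pairs,
                 excluded = paired_dataset$somamers$seq_id[ip][zero],
                 variant = variant,
                 scale_note = "log (natural)"),
            class = "ips_model")
}

#' @export
print.ips_model <- function(x, ...) {
  cat("ips_model:", length(x$weights), "weights from", x$n_pairs,
      "pairs (", x$variant, ")\n")
  if (length(x$excluded)) cat("  excluded (zero variance):",
                              length(x$excluded), "\n")
  invisible(x)
}

#' Score samples with an IPS model
#'
#' `IPS_i = sum_p d_p * C_ip` over the model's SOMAmers; deterministic.
#'
#' @param dataset a log-scale [soma_dataset] containing every non-excluded
#'   SOMAmer of the model.
#' @param model an [compute_ips_weights()] model.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_ips <- function(dataset, model) {
  if (!dataset$scale_state %in% c("log", "adjusted"))
    stop("compute_ips expects log-scale data")
  missing <- setdiff(names(model$weights), dataset$somamers$seq_id)
  if (length(missing))
    stop("dataset lacks model SOMAmers: ", paste(missing, collapse = ", "))
  idx <- match(names(model$weights), dataset$somamers$seq_id)
  drop(dataset$rfu[, idx, drop = FALSE] %*% model$weights)
}

#' Residualise proteins on the IPS
#'
#' Per SOMAmer, ordinary least squares of log concentration on the centred
#' IPS; each value is replaced by its residual plus the SOMAmer's overall
#' mean, so the sample covariance with IPS becomes exactly zero while the
#' mean is preserved. Marks the dataset `adjusted`.
#'
#' @param dataset a log-scale [soma_dataset].
#' @param ips per-sample score aligned with the dataset (named vector from
#'   [compute_ips()]).
#' @return The adjusted [soma_dataset].
#' @export
adjust_for_ips <- function(dataset, ips) {
  if (!is.null(names(ips))) ips <- ips[dataset$samples$sample_id]
  if (anyNA(ips)) stop("ips scores missing for some samples")
  if (stats::sd(ips) == 0) stop("IPS constant across samples: design singular")
  dataset <- residualise(dataset, data.frame(ips = as.numeric(ips)))
  dataset$scale_state <- "adjusted"
  add_provenance(dataset, "adjust_for_ips", list())
}

#' Residualise proteins on continuous covariates
#'
#' Joint per-SOMAmer OLS on all supplied covariates (with intercept);
#' residuals plus the per-SOMAmer mean are returned. Complete covariate
#' values are required for every sample in the dataset.
#'
#' @param dataset a log-scale [soma_dataset].
#' @param covariates data.frame of per-sample continuous covariates (same
#'   row order as the dataset's samples).
#' @return The adjusted [soma_dataset] (unchanged if `covariates` has no
#'   columns).
#' @export
covariate_adjust <- function(dataset, covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0) return(dataset)
  if (nrow(covariates) != nrow(dataset$rfu))
    stop("covariates must have one row per sample")
  if (anyNA(covariates))
    stop("covariates contain missing values; supply complete cases")
  dataset <- residualise(dataset, covariates)
  dataset$scale_state <- "adjusted"
  add_provenance(dataset, "covariate_adjust",
                 list(covariates = names(covariates)))
}

## Shared OLS residualisation: residual + column mean, all SOMAmers at once.
residualise <- function(dataset, covariates) {
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  y <- dataset$rfu
  resid <- y - x %*% qr.coef(qrx, y)
  dataset$rfu <- sweep(resid, 2, colMeans(y), `+`)
  dataset
}
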