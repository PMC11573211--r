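## SOMAmer and sample filter battery with blank-based limits of detection.
## Boundary conventions are strict everywhere: "more than 25%", "beyond
## 5 SD", "less than 50%". Only study and pooled samples are subject to
## sample filters; control wells are exempt.

#' Per-plate, per-SOMAmer limits of detection from blank wells
#'
#' Lower LOD is `median(blanks) + 4.9 * MAD(blanks)` with the *unscaled*
#' median absolute deviation (no 1.4826 consistency factor; the 4.9
#' constant is calibrated to the raw MAD); upper LOD is a constant
#' saturation ceiling, 80000 RFU by default. Requires at least three
#' blanks per plate.
#'
#' @param dataset a standardised linear-scale [soma_dataset].
#' @param upper upper LOD in RFU.
#' @param mad_scaled apply the 1.4826 normal-consistency scaling (default
#'   `FALSE`, the vendor convention).
#' @return An object of class `lod_table`: `lower` (plate x SOMAmer
#'   matrix), `upper` (scalar), `plates`.
#' @export
compute_lod <- function(dataset, upper = 80000, mad_scaled = FALSE) {
  plates <- unique(dataset$samples$plate_id)
  lower <- matrix(NA_real_, length(plates), ncol(dataset$rfu),
                  dimnames = list(plates, dataset$somamers$seq_id))
  for (q in plates) {
    bl <- which(dataset$samples$plate_id == q & dataset$samples$role == "blank")
    if (length(bl) < 3)
      stop("plate ", q, " has ", length(bl), " blanks; >= 3 required for LOD")
    b <- dataset$rfu[bl, , drop = FALSE]
    med <- col_medians(b)
    mad_raw <- apply(abs(sweep(b, 2, med)), 2, stats::median)
    if (mad_scaled) mad_raw <- 1.4826 * mad_raw
    lower[q, ] <- med + 4.9 * mad_raw
  }
  structure(list(lower = lower, upper = upper, plates = plates),
            class = "lod_table")
}

filterable_idx <- function(dataset) study_pooled_idx(dataset)

#' Sample filter: out-of-detection-range fraction
#'
#' Removes a sample when *more than* `max_fraction` of its protein-type
#' SOMAmer values fall below the lower or above the upper limit of
#' detection of its plate.
#'
#' @param dataset standardised linear-scale [soma_dataset].
#' @param lod a [compute_lod()] table.
#' @param max_fraction removal threshold (strict inequality), default 0.25.
#' @return Character vector of removed sample IDs.
#' @export
filter_samples_lod <- function(dataset, lod, max_fraction = 0.25) {
  ip <- protein_idx(dataset)
  rows <- filterable_idx(dataset)
  out <- character()
  for (i in rows) {
    q <- dataset$samples$plate_id[i]
    if (!q %in% rownames(lod$lower)) stop("no LOD available for plate ", q)
    v <- dataset$rfu[i, ip]
    frac <- mean(v < lod$lower[q, ip] | v > lod$upper)
    if (frac > max_fraction) out <- c(out, dataset$samples$sample_id[i])
  }
  out
}

#' Sample filter: PC-space outliers
#'
#' Removes samples lying beyond `n_sd` standard deviations from the centre
#' on any of the top components that together explain at least `threshold`
#' of the variance. A radial (Mahalanobis-type) variant over the same
#' components is available.
#'
#' @param dataset log-scale [soma_dataset] (PCA is fitted on study +
#'   pooled samples).
#' @param n_sd removal threshold in SDs (strict), default 5.
#' @param threshold cumulative variance fraction defining the top
#'   components, default 0.80.
#' @param mode `"per_pc"` (default) or `"radial"`.
#' @param pca optionally, a pre-fitted [fit_pca()] model to reuse.
#' @return Character vector of removed sample IDs.
#' @export
filter_samples_pca <- function(dataset, n_sd = 5, threshold = 0.80,
                               mode = c("per_pc", "radial"), pca = NULL) {
  mode <- match.arg(mode)
  if (is.null(pca)) pca <- fit_pca(dataset)
  k <- top_pcs_at_threshold(pca, threshold)
  sc <- pca$scores[, seq_len(k), drop = FALSE]
  sds <- apply(sc, 2, stats::sd)
  if (mode == "per_pc") {
    flag <- rowSums(sweep(abs(sc), 2, n_sd * sds, `>`)) > 0
  } else {
    z2 <- sweep(sc, 2, sds, `/`)^2
    flag <- sqrt(rowSums(z2)) > n_sd * sqrt(k)
  }
  pca$sample_ids[flag]
}

#' Sample filter: total-RFU outliers
#'
#' Total RFU per sample is the sum of its protein-type SOMAmer values on
#' the linear standardised scale; samples beyond `n_sd` SDs from the mean
#' of the study-sample totals are removed.
#'
#' @param dataset standardised linear-scale [soma_dataset].
#' @param n_sd removal threshold in SDs (strict), default 5.
#' @return Character vector of removed sample IDs.
#' @export
filter_samples_total_rfu <- function(dataset, n_sd = 5) {
  ip <- protein_idx(dataset)
  rows <- filterable_idx(dataset)
  totals <- rowSums(dataset$rfu[rows, ip, drop = FALSE])
  ref <- totals[dataset$samples$role[rows] == "study"]
  dev <- abs(totals - mean(ref))
  dataset$samples$sample_id[rows][dev > n_sd * stats::sd(ref)]
}

#' Sample filter: vendor QC flag
#'
#' Removes study and pooled samples carrying the vendor's in-house QC
#' flag; flags on control wells are ignored.
#'
#' @param dataset a [soma_dataset] with `vendor_flag`.
#' @return Character vector of removed sample IDs.
#' @export
filter_samples_flagged <- function(dataset) {
  rows <- filterable_idx(dataset)
  dataset$samples$sample_id[rows][dataset$samples$vendor_flag[rows] %in% TRUE]
}

#' SOMAmer filter: confounder association
#'
#' Per SOMAmer and per confounder, a simple least-squares slope test of
#' log concentration on the confounder over complete-case study samples;
#' p-values are Bonferroni-adjusted across SOMAmers within each
#' confounder, and a SOMAmer is removed when adjusted p < `alpha` for any
#' listed confounder.
#'
#' @param dataset log-scale [soma_dataset].
#' @param confounders data.frame of per-sample confounder values (study
#'   samples used; rows aligned with the dataset).
#' @param alpha adjusted-p removal threshold, default 0.05.
#' @return Character vector of removed `seq_id`s.
#' @export
filter_somamers_confounder <- function(dataset, confounders, alpha = 0.05) {
  ip <- protein_idx(dataset)
  st <- role_idx(dataset, "study")
  removed <- character()
  for (nm in names(confounders)) {
    x <- as.numeric(confounders[[nm]])[st]
    ok <- !is.na(x)
    if (sum(ok) < 10) stop("confounder ", nm, " has fewer than 10 non-missing values")
    if (stats::sd(x[ok]) == 0) stop("confounder ", nm, " is constant")
    y <- dataset$rfu[st[ok], ip, drop = FALSE]
    xc <- x[ok] - mean(x[ok])
    n <- sum(ok)
    sxx <- sum(xc^2)
    beta <- drop(crossprod(xc, y)) / sxx
    fitted_dev <- outer(xc, beta)
    resid <- sweep(y, 2, colMeans(y)) - fitted_dev
    s2 <- colSums(resid^2) / (n - 2)
    tval <- beta / sqrt(s2 / sxx)
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    p_adj <- pmin(1, p * length(ip))
    removed <- union(removed, dataset$somamers$seq_id[ip][p_adj < alpha])
  }
  removed
}

#' SOMAmer filter: non-human and control reagents
#'
#' Removes SOMAmers whose organism is not human or whose type is one of
#' the control classes (spuriomer, hybridisation control elution,
#' deprecated, non-biotin, non-cleavable).
#'
#' @param dataset a [soma_dataset].
#' @return Character vector of removed `seq_id`s.
#' @export
filter_somamers_control <- function(dataset) {
  sm <- dataset$somamers
  bad <- sm$organism != "human" |
    sm$somamer_type %in% c("spuriomer", "hyb_control_elution", "deprecated",
                           "non_biotin", "non_cleavable")
  sm$seq_id[bad]
}

#' SOMAmer filter: insufficient non-technical variation
#'
#' Removes a SOMAmer when its non-technical R-squared is below `min_r2`
#' in either the pooled-OA or the pooled-injury group (strict inequality).
#'
#' @param r2_oa,r2_injury named per-SOMAmer R-squared vectors over the
#'   same SOMAmer set.
#' @param min_r2 removal threshold, default 0.5.
#' @return Character vector of removed `seq_id`s.
#' @export
filter_somamers_r2 <- function(r2_oa, r2_injury, min_r2 = 0.5) {
  if (!setequal(names(r2_oa), names(r2_injury)))
    stop("R-squared tables cover different SOMAmer sets: ",
         paste(union(setdiff(names(r2_oa), names(r2_injury)),
                     setdiff(names(r2_injury), names(r2_oa))), collapse = ", "))
  r2_injury <- r2_injury[names(r2_oa)]
  names(r2_oa)[pmin(r2_oa, r2_injury) < min_r2]
}

#' Apply the full filter battery in fixed order
#'
#' SOMAmer filters first (control reagents, confounder association,
#' low R-squared), then sample filters (vendor flag, limit-of-detection
#' fraction, total RFU, and PC-space outliers with the PCA refitted after
#' the earlier removals). The log-scale (batch-corrected) dataset drives
#' the confounder, R-squared and PCA filters; the companion linear-scale
#' standardised dataset drives the LOD and total-RFU filters.
#'
#' @param dataset batch-corrected log-scale [soma_dataset].
#' @param linear_dataset companion standardised linear-scale dataset with
#'   the same samples and SOMAmers (plus control wells for the LOD).
#' @param confounders data.frame of per-sample confounder values aligned
#'   with `dataset` (default: `sample_age_years` and `freeze_thaw_count`
#'   from the sample table).
#' @param alpha,min_r2,lod_max_fraction,n_sd,pca_threshold filter
#'   parameters (see the individual filters).
#' @param r2_formula R-squared estimator form used for the filter; the
#'   default is the squared complement `(1 - V_pooled/V_total)^2`.
#' @return A list with the filtered `dataset`, filtered `linear_dataset`
#'   and `report` (class `filter_report`): one ordered entry per filter
#'   with parameters, removed IDs and survivor counts.
#' @export
apply_filters <- function(dataset, linear_dataset,
                          confounders = NULL,
                          alpha = 0.05, min_r2 = 0.5,
                          lod_max_fraction = 0.25, n_sd = 5,
                          pca_threshold = 0.80,
                          r2_formula = "squared_one_minus_ratio") {
  if (is.null(confounders))
    confounders <- dataset$samples[, c("sample_age_years", "freeze_thaw_count")]
  entries <- list()
  note <- function(filter, params, removed, type) {
    entries[[length(entries) + 1L]] <<- list(
      filter = filter, params = params, removed = removed, type = type,
      surviving_samples = NA_integer_, surviving_somamers = NA_integer_)
  }

  ## --- SOMAmer filters -----------------------------------------------------
  rm_ctrl <- filter_somamers_control(dataset)
  note("control_somamers", list(), rm_ctrl, "somamer")
  ds <- subset_dataset(dataset, somamers = !dataset$somamers$seq_id %in% rm_ctrl)
  rm_conf <- filter_somamers_confounder(ds, confounders, alpha = alpha)
  note("confounder_association",
       list(alpha = alpha, confounders = names(confounders)), rm_conf, "somamer")
  ds <- subset_dataset(ds, somamers = !ds$somamers$seq_id %in% rm_conf)
  rt <- repeatability_table(ds, r2_formula = r2_formula)
  rm_r2 <- filter_somamers_r2(stats::setNames(rt$r2_oa, rt$seq_id),
                              stats::setNames(rt$r2_injury, rt$seq_id),
                              min_r2 = min_r2)
  note("low_r2", list(min_r2 = min_r2, formula = r2_formula), rm_r2, "somamer")
  ds <- subset_dataset(ds, somamers = !ds$somamers$seq_id %in% rm_r2)

  rm_som <- c(rm_ctrl, rm_conf, rm_r2)
  lin <- subset_dataset(linear_dataset,
                        somamers = !linear_dataset$somamers$seq_id %in% rm_som)

  ## --- sample filters ------------------------------------------------------
  rm_flag <- filter_samples_flagged(ds)
  note("vendor_flag", list(), rm_flag, "sample")
  ds <- subset_dataset(ds, samples = !ds$samples$sample_id %in% rm_flag)
  lin_f <- subset_dataset(lin, samples = !lin$samples$sample_id %in% rm_flag)

  lod <- compute_lod(lin_f)
  rm_lod <- filter_samples_lod(lin_f, lod, max_fraction = lod_max_fraction)
  note("lod_fraction", list(max_fraction = lod_max_fraction), rm_lod, "sample")
  ds <- subset_dataset(ds, samples = !ds$samples$sample_id %in% rm_lod)
  lin_f <- subset_dataset(lin_f, samples = !lin_f$samples$sample_id %in% rm_lod)

  rm_tot <- filter_samples_total_rfu(lin_f, n_sd = n_sd)
  note("total_rfu", list(n_sd = n_sd), rm_tot, "sample")
  ds <- subset_dataset(ds, samples = !ds$samples$sample_id %in% rm_tot)
  lin_f <- subset_dataset(lin_f, samples = !lin_f$samples$sample_id %in% rm_tot)

  rm_pca <- filter_samples_pca(ds, n_sd = n_sd, threshold = pca_threshold)
  note("pca_outlier", list(n_sd = n_sd, threshold = pca_threshold), rm_pca,
       "sample")
  ds <- subset_dataset(ds, samples = !ds$samples$sample_id %in% rm_pca)
  lin_f <- subset_dataset(lin_f, samples = !lin_f$samples$sample_id %in% rm_pca)

  n_sam <- nrow(dataset$rfu); n_som <- ncol(dataset$rfu)
  for (i in seq_along(entries)) {
    if (entries[[i]]$type == "somamer") n_som <- n_som - length(entries[[i]]$removed)
    else n_sam <- n_sam - length(entries[[i]]$removed)
    entries[[i]]$surviving_samples <- n_sam
    entries[[i]]$surviving_somamers <- n_som
  }
  report <- structure(list(entries = entries,
                           surviving_samples = nrow(ds$rfu),
                           surviving_somamers = ncol(ds$rfu)),
                      class = "filter_report")
  ds <- add_provenance(ds, "apply_filters",
                       list(removed_samples = length(c(rm_flag, rm_lod, rm_tot, rm_pca)),
                            removed_somamers = length(rm_som)))
  list(dataset = ds, linear_dataset = lin_f, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  for (e in x$entries)
    cat(sprintf("  %-24s removed %4d %-8s -> %d samples x %d SOMAmers\n",
                e$filter, length(e$removed), paste0(e$type, "s"),
                e$surviving_samples, e$surviving_somamers))
  cat("  surviving:", x$surviving_samples, "samples x",
      x$surviving_somamers, "SOMAmers\n")
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param report a `filter_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
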