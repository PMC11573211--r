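#' Percent coefficient of variation of replicate measurements
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation, computed on
#' linear standardised RFU by vendor convention.
#'
#' @param values numeric vector of replicate measurements for one SOMAmer.
#' @return Percent CV (scalar).
#' @export
percent_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("percent_cv needs at least 2 replicates")
  m <- mean(values)
  if (m <= 0) stop("percent_cv undefined for nonpositive mean")
  100 * stats::sd(values) / m
}

#' Non-technical (biological) variance fraction R-squared
#'
#' Estimated from the variance of pooled replicate wells (technical) and
#' the variance over individual study samples (total). Two published forms
#' of the estimator circulate; both are provided:
#' `one_minus_ratio_squared` is `1 - (V_pooled/V_total)^2` and
#' `squared_one_minus_ratio` is `(1 - V_pooled/V_total)^2`.
#'
#' @param pooled_values replicate measurements of the pooled sample.
#' @param all_sample_values measurements over individual study samples.
#' @param formula which estimator form to evaluate.
#' @return The R-squared estimate (can be negative under the first form
#'   when pooled variance exceeds total variance); `NA` with a warning when
#'   the total variance is zero.
#' @export
nontechnical_r2 <- function(pooled_values, all_sample_values,
                            formula = c("one_minus_ratio_squared",
                                        "squared_one_minus_ratio")) {
  formula <- match.arg(formula)
  v_pooled <- stats::var(as.numeric(pooled_values))
  v_total <- stats::var(as.numeric(all_sample_values))
  if (!is.finite(v_total) || v_total == 0) {
    warning("total variance is zero; R-squared undefined")
    return(NA_real_)
  }
  ratio <- v_pooled / v_total
  switch(formula,
         one_minus_ratio_squared = 1 - ratio^2,
         squared_one_minus_ratio = (1 - ratio)^2)
}

#' Per-SOMAmer repeatability table from pooled replicates
#'
#' Computes, for each protein-type SOMAmer and each pooled group (OA and
#' knee injury), the percent CV of the pooled replicate wells on the
#' linear scale and the non-technical R-squared against the individual
#' study samples. On a log/adjusted-scale dataset the CV is evaluated
#' after exponentiation; on a linear-scale dataset the R-squared variances
#' are evaluated on the log values.
#'
#' @param dataset a standardised (linear) or log/adjusted [soma_dataset].
#' @param r2_formula estimator form passed to [nontechnical_r2()].
#' @return data.frame with `seq_id`, `cv_oa`, `cv_injury`, `r2_oa`,
#'   `r2_injury`, `v_pooled_oa`, `v_pooled_injury`, `v_total`.
#' @export
repeatability_table <- function(dataset,
                                r2_formula = c("one_minus_ratio_squared",
                                               "squared_one_minus_ratio")) {
  r2_formula <- match.arg(r2_formula)
  ip <- protein_idx(dataset)
  on_log <- dataset$scale_state %in% c("log", "adjusted")
  lin <- if (on_log) exp(dataset$rfu[, ip, drop = FALSE])
         else dataset$rfu[, ip, drop = FALSE]
  lg <- if (on_log) dataset$rfu[, ip, drop = FALSE]
        else log(pmax(dataset$rfu[, ip, drop = FALSE], .Machine$double.xmin))
  st <- role_idx(dataset, "study")
  oa <- role_idx(dataset, "pooled_oa")
  inj <- role_idx(dataset, "pooled_injury")
  if (length(oa) < 2 || length(inj) < 2)
    stop("need >= 2 pooled replicate wells per group")
  cv <- function(m) 100 * apply(m, 2, stats::sd) / colMeans(m)
  v <- function(m) apply(m, 2, stats::var)
  v_total <- v(lg[st, , drop = FALSE])
  v_oa <- v(lg[oa, , drop = FALSE])
  v_inj <- v(lg[inj, , drop = FALSE])
  r2 <- function(vp) {
    ratio <- vp / v_total
    if (r2_formula == "one_minus_ratio_squared") 1 - ratio^2 else (1 - ratio)^2
  }
  data.frame(seq_id = dataset$somamers$seq_id[ip],
             cv_oa = cv(lin[oa, , drop = FALSE]),
             cv_injury = cv(lin[inj, , drop = FALSE]),
             r2_oa = r2(v_oa), r2_injury = r2(v_inj),
             v_pooled_oa = v_oa, v_pooled_injury = v_inj,
             v_total = v_total, stringsAsFactors = FALSE, row.names = NULL)
}

#' Immunoassay concordance by Pearson correlation
#'
#' Correlates log SomaScan RFU with log immunoassay concentration per
#' analyte over the overlapping samples, with a Fisher-z 95% confidence
#' interval; optionally stratified by disease group.
#'
#' @param dataset a standardised (linear) or log-scale [soma_dataset].
#' @param immunoassay data.frame with columns `analyte`, `sample_id`,
#'   `concentration` (absolute, positive).
#' @param mapping named character vector: analyte name -> `seq_id`.
#' @param by_group stratify by `disease_group` (default `FALSE`).
#' @return data.frame with `analyte`, `group`, `n`, `r`, `ci_lo`, `ci_hi`.
#'   Analytes with fewer than 4 overlapping samples are skipped with a
#'   warning.
#' @export
immunoassay_concordance <- function(dataset, immunoassay, mapping,
                                    by_group = FALSE) {
  on_log <- dataset$scale_state %in% c("log", "adjusted")
  out <- list()
  groups <- if (by_group) unique(dataset$samples$disease_group) else "all"
  for (an in unique(immunoassay$analyte)) {
    seqid <- mapping[[an]]
    if (is.null(seqid) || !seqid %in% dataset$somamers$seq_id) {
      warning("no SOMAmer mapping for analyte ", an, "; skipped")
      next
    }
    tab <- immunoassay[immunoassay$analyte == an, , drop = FALSE]
    for (g in groups) {
      rows <- match(tab$sample_id, dataset$samples$sample_id)
      keep <- !is.na(rows) & tab$concentration > 0
      if (g != "all")
        keep <- keep & dataset$samples$disease_group[rows] == g
      if (sum(keep) < 4) {
        warning("analyte ", an, " (", g, "): fewer than 4 overlapping samples; skipped")
        next
      }
      x <- dataset$rfu[rows[keep], seqid]
      if (!on_log) x <- log(x)
      y <- log(tab$concentration[keep])
      r <- stats::cor(x, y)
      n <- sum(keep)
      z <- atanh(r); se <- 1 / sqrt(n - 3)
      out[[length(out) + 1]] <- data.frame(
        analyte = an, group = g, n = n, r = r,
        ci_lo = tanh(z - 1.959963984540054 * se),
        ci_hi = tanh(z + 1.959963984540054 * se),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(analyte = character(), group = character(),
                      n = integer(), r = numeric(), ci_lo = numeric(),
                      ci_hi = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
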