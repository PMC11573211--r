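## Validity diagnostics: confounder-association maps for the top PCs,
## predictors of the protein-PC1 correlation, the spun/unspun paired
## comparison, and the HBA blood score.

#' Associate top principal components with technical confounders
#'
#' Per component (up to `top_k`) and confounder: simple linear regression
#' for continuous/ordinal confounders, one-way ANOVA for categorical
#' ones, over complete cases. Both Bonferroni (within confounder, across
#' PCs and the whole table) and Benjamini-Hochberg adjusted p-values are
#' reported.
#'
#' @param pca a [fit_pca()] model.
#' @param confounders data.frame of per-sample confounder values aligned
#'   with the PCA's samples; factors/characters are treated as
#'   categorical.
#' @param top_k number of leading components to test, default 10.
#' @return data.frame of class `association_table`: `pc`, `confounder`,
#'   `statistic`, `r2`, `n`, `p`, `p_bonferroni`, `p_bh`.
#' @export
associate_pcs_confounders <- function(pca, confounders, top_k = 10) {
  k <- min(top_k, ncol(pca$scores))
  out <- list()
  for (nm in names(confounders)) {
    x <- confounders[[nm]]
    ok <- !is.na(x)
    if (!any(ok)) {
      warning("confounder ", nm, " is all-missing; skipped")
      next
    }
    categorical <- is.character(x) || is.factor(x)
    if (sum(ok) < 10) {
      warning("confounder ", nm, " has fewer than 10 complete cases; skipped")
      next
    }
    for (c_i in seq_len(k)) {
      sc <- pca$scores[ok, c_i]
      if (categorical) {
        f <- droplevels(as.factor(x[ok]))
        if (nlevels(f) < 2) next
        a <- stats::anova(stats::lm(sc ~ f))
        stat <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
        r2 <- a$`Sum Sq`[1] / sum(a$`Sum Sq`)
      } else {
        xv <- as.numeric(x[ok])
        if (stats::sd(xv) == 0) next
        fit <- stats::lm(sc ~ xv)
        s <- summary(fit)
        stat <- s$coefficients["xv", "t value"]
        p <- s$coefficients["xv", "Pr(>|t|)"]
        r2 <- s$r.squared
      }
      out[[length(out) + 1]] <- data.frame(
        pc = c_i, confounder = nm, statistic = stat, r2 = r2,
        n = sum(ok), p = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  tab$p_bh <- stats::p.adjust(tab$p, method = "BH")
  class(tab) <- c("association_table", class(tab))
  tab
}

#' Predictors of the protein-PC1 correlation
#'
#' Computes, per SOMAmer, the Pearson correlation between its log values
#' and the PC1 scores, then regresses that correlation on log
#' dilution-adjusted abundance and secretion-class indicators.
#'
#' @param dataset log-scale [soma_dataset] restricted to the PCA's
#'   samples, plus a standardised linear companion for the abundance axis.
#' @param pca a [fit_pca()] model fitted on `dataset`.
#' @param abundance named per-SOMAmer dilution-adjusted abundance (from
#'   [dilution_adjusted_abundance()] on the linear dataset).
#' @return A list with `correlations` (named per-SOMAmer r with PC1) and
#'   `coefficients` (OLS coefficient table).
#' @export
pc1_predictor_regression <- function(dataset, pca, abundance) {
  idx <- match(pca$seq_ids, dataset$somamers$seq_id)
  rows <- match(pca$sample_ids, dataset$samples$sample_id)
  r <- drop(stats::cor(pca$scores[, 1], dataset$rfu[rows, idx, drop = FALSE]))
  names(r) <- pca$seq_ids
  ab <- log(abundance[pca$seq_ids])
  cls <- dataset$somamers$secretion_class[idx]
  df <- data.frame(r = r, log_abundance = ab, secretion = cls)
  if (length(unique(cls)) < 2) {
    warning("single secretion class present; indicators dropped")
    fit <- stats::lm(r ~ log_abundance, data = df)
  } else {
    df$secretion <- stats::relevel(factor(cls), ref = "secreted")
    fit <- stats::lm(r ~ log_abundance + secretion, data = df)
  }
  list(correlations = r,
       coefficients = as.data.frame(summary(fit)$coefficients))
}

#' Spun/unspun paired comparison per SOMAmer
#'
#' For each protein SOMAmer: the paired Cohen's d (d_z) of the
#' unspun-minus-spun log difference, a two-sided paired t-test, and the
#' Pearson correlation between the paired members, with
#' Benjamini-Hochberg adjustment within each test family and the
#' resulting quadrant classification (significantly different means x
#' significantly correlated).
#'
#' @param paired_dataset log-scale [soma_dataset] with spun/unspun
#'   pairing in the sample table.
#' @param alpha BH significance level for the quadrants, default 0.05.
#' @return data.frame with `seq_id`, `cohens_d`, `t_p`, `t_p_bh`,
#'   `pearson_r`, `r_p`, `r_p_bh`, `different_means`, `correlated`.
#' @export
spun_unspun_comparison <- function(paired_dataset, alpha = 0.05) {
  sa <- paired_dataset$samples
  st <- which(sa$role == "study" & !is.na(sa$spun))
  spun_rows <- st[sa$spun[st]]
  unspun_rows <- st[!sa$spun[st]]
  m <- match(sa$participant_id[spun_rows], sa$participant_id[unspun_rows])
  unspun_rows <- unspun_rows[m]
  n <- length(spun_rows)
  if (n < 3 || anyNA(m)) stop("need >= 3 complete spun/unspun pairs")
  ip <- which(paired_dataset$somamers$somamer_type == "protein" &
                paired_dataset$somamers$organism == "human")
  a <- paired_dataset$rfu[unspun_rows, ip, drop = FALSE]
  b <- paired_dataset$rfu[spun_rows, ip, drop = FALSE]
  delta <- a - b
  mu <- colMeans(delta)
  sdd <- apply(delta, 2, stats::sd)
  d <- mu / sdd
  tstat <- d * sqrt(n)
  t_p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  r <- vapply(seq_along(ip), function(j) stats::cor(a[, j], b[, j]), 0)
  r_t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  r_p <- 2 * stats::pt(abs(r_t), df = n - 2, lower.tail = FALSE)
  t_bh <- stats::p.adjust(t_p, "BH")
  r_bh <- stats::p.adjust(r_p, "BH")
  data.frame(seq_id = paired_dataset$somamers$seq_id[ip],
             cohens_d = d, t_p = t_p, t_p_bh = t_bh,
             pearson_r = r, r_p = r_p, r_p_bh = r_bh,
             different_means = t_bh < alpha,
             correlated = r_bh < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' HBA blood score
#'
#' The log standardised RFU of haemoglobin A, taken from non-IPS-adjusted
#' data, as a per-sample measure of blood content, together with the
#' Spearman correlation against the ordinal visual blood-staining grade.
#'
#' @param dataset log-scale [soma_dataset] (a warning is issued if the
#'   data have been residualised, since the score is defined on
#'   unadjusted values).
#' @param hba_seq_id `seq_id` of the HBA SOMAmer.
#' @return A list with `score` (named per-sample log HBA), `spearman_rho`
#'   and `n_graded`.
#' @export
blood_score <- function(dataset, hba_seq_id) {
  if (!hba_seq_id %in% dataset$somamers$seq_id)
    stop("HBA SOMAmer not present: ", hba_seq_id)
  if (dataset$scale_state == "adjusted")
    warning("blood score is defined on non-IPS-adjusted data")
  score <- dataset$rfu[, hba_seq_id]
  names(score) <- dataset$samples$sample_id
  g <- dataset$samples$blood_grade
  ok <- !is.na(g)
  rho <- if (sum(ok) >= 3)
    suppressWarnings(stats::cor(score[ok], g[ok], method = "spearman"))
  else NA_real_
  list(score = score, spearman_rho = rho, n_graded = sum(ok))
}
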