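#' PCA of the sample x SOMAmer log matrix
#'
#' Centres each SOMAmer (optionally unit-scales) and computes an SVD-based
#' PCA over the selected samples (study and pooled wells by default;
#' calibrators, plasma QC and blanks describe a different matrix and are
#' excluded). A deterministic sign convention is applied: each loading
#' vector's largest-magnitude element is positive.
#'
#' @param dataset a log- or adjusted-scale [soma_dataset].
#' @param scale unit-variance scale each SOMAmer (default `FALSE`; centring
#'   only).
#' @param samples optional index of samples to fit on; defaults to study +
#'   pooled wells.
#' @param somamers optional index of SOMAmers; defaults to protein-type,
#'   human SOMAmers.
#' @return An object of class `pca_model`: `center`, `scale`, `loadings`
#'   (SOMAmer x component), `scores` (sample x component),
#'   `variance_explained` (fractions, nonincreasing), `sample_ids`,
#'   `seq_ids`.
#' @export
fit_pca <- function(dataset, scale = FALSE, samples = NULL, somamers = NULL) {
  if (!dataset$scale_state %in% c("log", "adjusted"))
    stop("fit_pca expects log or adjusted scale data")
  if (is.null(samples)) samples <- study_pooled_idx(dataset)
  if (is.null(somamers))
    somamers <- which(dataset$somamers$somamer_type == "protein" &
                        dataset$somamers$organism == "human")
  x <- dataset$rfu[samples, somamers, drop = FALSE]
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (all(abs(sweep(x, 2, x[1, ])) < 1e-12)) stop("constant matrix: PCA undefined")
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  ## sign convention: largest |loading| positive per component
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  structure(list(center = p$center,
                 scale = if (scale) p$scale else NULL,
                 loadings = p$rotation,
                 scores = p$x,
                 variance_explained = p$sdev^2 / sum(p$sdev^2),
                 sample_ids = dataset$samples$sample_id[samples],
                 seq_ids = dataset$somamers$seq_id[somamers]),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ve <- x$variance_explained
  cat("pca_model:", length(x$sample_ids), "samples,", length(x$seq_ids),
      "SOMAmers,", length(ve), "components\n")
  cat("  variance explained (top 5):",
      paste(sprintf("%.1f%%", 100 * utils::head(ve, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of top components reaching a cumulative-variance threshold
#'
#' @param model a [fit_pca()] model.
#' @param threshold fraction in (0, 1]; default 0.80.
#' @return Smallest k with cumulative variance explained >= `threshold`.
#' @export
top_pcs_at_threshold <- function(model, threshold = 0.80) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  cum <- cumsum(model$variance_explained)
  which(cum >= threshold - 1e-12)[1]
}

#' UMAP embedding of the top principal components
#'
#' Thin visualisation-only wrapper that delegates to the `umap-learn`
#' implementation through the system `python`; no embedding mathematics is
#' reimplemented here, and the coordinates feed no quantitative contract in
#' the pipeline. Requires `python` with the `umap-learn` package on the
#' PATH.
#'
#' @param model a [fit_pca()] model.
#' @param k number of leading components to embed (>= 2).
#' @param seed integer random seed forwarded to UMAP.
#' @param n_neighbors UMAP neighbourhood size (capped at n - 1).
#' @return A matrix (samples x 2) of embedding coordinates, rownames set to
#'   sample IDs.
#' @export
umap_embed <- function(model, k, seed = 0L, n_neighbors = 15L) {
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(model$scores)) stop("k exceeds available components")
  x <- model$scores[, seq_len(k), drop = FALSE]
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(x, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- paste(
    "import sys, numpy as np, warnings",
    "warnings.filterwarnings('ignore')",
    "import umap",
    sprintf("x = np.loadtxt('%s', delimiter=',', ndmin=2)", fin),
    sprintf("nn = min(%d, x.shape[0] - 1)", as.integer(n_neighbors)),
    sprintf("e = umap.UMAP(n_components=2, n_neighbors=nn, random_state=%d).fit_transform(x)",
            as.integer(seed)),
    sprintf("np.savetxt('%s', e, delimiter=',')", fout),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("umap_embed requires a system 'python' with the umap-learn package")
  emb <- as.matrix(utils::read.csv(fout, header = FALSE))
  dimnames(emb) <- list(rownames(model$scores), c("D1", "D2"))
  emb
}
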