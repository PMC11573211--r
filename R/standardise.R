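## Standardisation of linear-scale RFU: hybridisation-control normalisation,
## plate scaling, (optional) median signal normalisation, and per-SOMAmer
## plate calibration, plus the log transform and the dilution-adjusted
## abundance diagnostic. Median normalisation is implemented but excluded
## from the default step list: on synovial fluid it removes genuine
## between-sample signal along with nuisance intensity variation.

## Calibrator reference values: annotated where present, otherwise the
## across-plate median of plate-calibrator medians (single-run self
## reference). Returns a named vector over protein-type SOMAmers.
calibrator_references <- function(dataset) {
  ip <- protein_idx(dataset)
  ref <- dataset$somamers$calibrator_reference[ip]
  names(ref) <- dataset$somamers$seq_id[ip]
  if (anyNA(ref)) {
    cal <- role_idx(dataset, "calibrator")
    if (!length(cal)) stop("no calibrator wells to derive self-reference from")
    plates <- unique(dataset$samples$plate_id[cal])
    med <- sapply(plates, function(q) {
      w <- cal[dataset$samples$plate_id[cal] == q]
      col_medians(dataset$rfu[w, ip, drop = FALSE])
    })
    ref[is.na(ref)] <- apply(as.matrix(med), 1, stats::median)[is.na(ref)]
  }
  ref
}

#' Hybridisation control normalisation
#'
#' Removes well-to-well variation in hybridisation efficiency. For each
#' plate, the reference for hybridisation control `h` is the median of its
#' RFU over the plate's wells; each well is rescaled by the median over
#' controls of (reference / observed), so that afterwards the per-well
#' median of those ratios is exactly 1.
#'
#' @param dataset a raw-scale [soma_dataset] with at least one
#'   hybridisation control SOMAmer.
#' @return A list with the rescaled `dataset` and `factors` (named
#'   per-sample scale factors).
#' @export
hybridisation_normalise <- function(dataset) {
  ih <- hyb_idx(dataset)
  if (!length(ih)) stop("no hybridisation control SOMAmers in dataset")
  hyb <- dataset$rfu[, ih, drop = FALSE]
  if (any(hyb == 0)) {
    w <- rownames(hyb)[which(hyb == 0, arr.ind = TRUE)[, 1]]
    stop("zero hybridisation-control RFU in well(s): ",
         paste(unique(w), collapse = ", "))
  }
  factors <- rep(NA_real_, nrow(dataset$rfu))
  names(factors) <- dataset$samples$sample_id
  for (q in unique(dataset$samples$plate_id)) {
    rows <- which(dataset$samples$plate_id == q)
    ref <- col_medians(hyb[rows, , drop = FALSE])
    ratio <- matrix(ref, length(rows), length(ih), byrow = TRUE) /
      hyb[rows, , drop = FALSE]
    factors[rows] <- row_medians(ratio)
  }
  dataset$rfu <- dataset$rfu * factors
  dataset <- add_provenance(dataset, "hybridisation_normalise", list())
  list(dataset = dataset, factors = factors)
}

#' Plate scaling from plasma calibrators
#'
#' One multiplicative factor per plate: the median over protein SOMAmers of
#' (calibrator reference / median calibrator RFU on that plate).
#'
#' @param dataset a linear-scale [soma_dataset]; every plate needs at least
#'   one calibrator well.
#' @return A list with the rescaled `dataset` and `factors` (named
#'   per-plate scale factors).
#' @export
plate_scale <- function(dataset) {
  ref <- calibrator_references(dataset)
  ip <- protein_idx(dataset)
  plates <- unique(dataset$samples$plate_id)
  factors <- stats::setNames(rep(NA_real_, length(plates)), plates)
  for (q in plates) {
    cal <- which(dataset$samples$plate_id == q & dataset$samples$role == "calibrator")
    if (!length(cal)) stop("plate without calibrator wells: ", q)
    m <- col_medians(dataset$rfu[cal, ip, drop = FALSE])
    factors[q] <- stats::median(ref / m)
    dataset$rfu[dataset$samples$plate_id == q, ] <-
      dataset$rfu[dataset$samples$plate_id == q, , drop = FALSE] * factors[q]
  }
  dataset <- add_provenance(dataset, "plate_scale", list())
  list(dataset = dataset, factors = factors)
}

#' Median signal normalisation (excluded from the default pipeline)
#'
#' Within each dilution bin and sample-role group (study plus pooled wells
#' in one group, control wells in the other), each sample is rescaled by the
#' inverse median of its SOMAmer-wise ratios to the per-SOMAmer group
#' median. Implemented for comparison runs; the default standardisation
#' omits it because total-signal differences in synovial fluid carry
#' biological signal.
#'
#' @param dataset a linear-scale [soma_dataset].
#' @return A list with the rescaled `dataset` and `factors` (sample x bin
#'   matrix of scale factors).
#' @export
median_normalise <- function(dataset) {
  bins <- sort(unique(dataset$somamers$dilution_bin[protein_idx(dataset)]))
  groups <- list(study = study_pooled_idx(dataset),
                 control = setdiff(seq_len(nrow(dataset$rfu)), study_pooled_idx(dataset)))
  factors <- matrix(1, nrow(dataset$rfu), length(bins),
                    dimnames = list(dataset$samples$sample_id, as.character(bins)))
  for (b in seq_along(bins)) {
    pb <- which(dataset$somamers$dilution_bin == bins[b] &
                  dataset$somamers$somamer_type == "protein")
    if (length(pb) < 2) stop("dilution bin ", bins[b], " has fewer than 2 SOMAmers")
    for (g in groups) {
      if (!length(g)) next
      med <- col_medians(dataset$rfu[g, pb, drop = FALSE])
      r <- dataset$rfu[g, pb, drop = FALSE] / matrix(med, length(g), length(pb),
                                                     byrow = TRUE)
      f <- 1 / row_medians(r)
      dataset$rfu[g, pb] <- dataset$rfu[g, pb, drop = FALSE] * f
      factors[g, b] <- f
    }
  }
  dataset <- add_provenance(dataset, "median_normalise", list())
  list(dataset = dataset, factors = factors)
}

#' Per-SOMAmer plate calibration
#'
#' For each plate and SOMAmer, samples are rescaled so the plate's
#' calibrator median equals the calibrator reference exactly.
#'
#' @param dataset a linear-scale [soma_dataset] with calibrator wells.
#' @return A list with the rescaled `dataset` and `factors` (plate x
#'   SOMAmer matrix; 1 for SOMAmers without a reference).
#' @export
calibrate <- function(dataset) {
  ref <- calibrator_references(dataset)
  ip <- protein_idx(dataset)
  plates <- unique(dataset$samples$plate_id)
  factors <- matrix(1, length(plates), ncol(dataset$rfu),
                    dimnames = list(plates, dataset$somamers$seq_id))
  for (q in plates) {
    cal <- which(dataset$samples$plate_id == q & dataset$samples$role == "calibrator")
    if (!length(cal)) stop("plate without calibrator wells: ", q)
    m <- col_medians(dataset$rfu[cal, ip, drop = FALSE])
    if (any(m == 0))
      stop("zero calibrator median at (", q, ", ",
           paste(dataset$somamers$seq_id[ip][m == 0], collapse = ","), ")")
    factors[q, ip] <- ref / m
    rows <- dataset$samples$plate_id == q
    dataset$rfu[rows, ] <- sweep(dataset$rfu[rows, , drop = FALSE], 2,
                                 factors[q, ], `*`)
  }
  dataset <- add_provenance(dataset, "calibrate", list())
  list(dataset = dataset, factors = factors)
}

#' Run the standardisation sequence
#'
#' Applies the requested steps in order on raw linear RFU and marks the
#' result `standardised`. The default sequence is hybridisation control
#' normalisation, plate scaling, then calibration; median normalisation
#' can be inserted explicitly for comparison runs.
#'
#' @param dataset a raw-scale [soma_dataset].
#' @param steps character vector drawn from `"hyb"`, `"plate"`,
#'   `"median"`, `"cal"`; no repeats.
#' @return A list with the standardised `dataset` and `factors`, a list
#'   with one element per applied step.
#' @export
run_standardisation <- function(dataset, steps = c("hyb", "plate", "cal")) {
  if (dataset$scale_state != "raw")
    stop("run_standardisation expects a raw-scale dataset")
  if (anyDuplicated(steps)) stop("repeated standardisation step: ",
                                 steps[duplicated(steps)][1])
  fns <- list(hyb = hybridisation_normalise, plate = plate_scale,
              median = median_normalise, cal = calibrate)
  bad <- setdiff(steps, names(fns))
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  factors <- list()
  for (stp in steps) {
    res <- fns[[stp]](dataset)
    dataset <- res$dataset
    factors[[stp]] <- res$factors
  }
  dataset$scale_state <- "standardised"
  dataset <- add_provenance(dataset, "run_standardisation", list(steps = steps))
  list(dataset = dataset, factors = factors)
}

#' Re-apply stored normalisation factors to a raw dataset
#'
#' Reproduces the standardised data from the raw data and the factor
#' record returned by [run_standardisation()] (steps `hyb`, `plate`,
#' `cal`; median factors are sample-by-bin and are also honoured).
#'
#' @param dataset a raw-scale [soma_dataset].
#' @param factors the `factors` element returned by [run_standardisation()].
#' @return The standardised [soma_dataset].
#' @export
apply_factors <- function(dataset, factors) {
  if (!is.null(factors$hyb))
    dataset$rfu <- dataset$rfu * factors$hyb[dataset$samples$sample_id]
  if (!is.null(factors$plate))
    dataset$rfu <- dataset$rfu * factors$plate[dataset$samples$plate_id]
  if (!is.null(factors$median)) {
    f <- factors$median
    for (b in colnames(f)) {
      pb <- which(dataset$somamers$dilution_bin == as.numeric(b) &
                    dataset$somamers$somamer_type == "protein")
      dataset$rfu[, pb] <- dataset$rfu[, pb, drop = FALSE] *
        f[dataset$samples$sample_id, b]
    }
  }
  if (!is.null(factors$cal))
    dataset$rfu <- dataset$rfu *
      factors$cal[dataset$samples$plate_id, , drop = FALSE]
  dataset$scale_state <- "standardised"
  add_provenance(dataset, "apply_factors", list())
}

#' Dilution-adjusted abundance diagnostic
#'
#' Median standardised RFU over study samples divided by the SOMAmer's
#' dilution-bin fraction; used as the protein-abundance axis in
#' diagnostics.
#'
#' @param dataset a standardised [soma_dataset].
#' @return Named numeric vector over SOMAmers.
#' @export
dilution_adjusted_abundance <- function(dataset) {
  st <- role_idx(dataset, "study")
  med <- col_medians(dataset$rfu[st, , drop = FALSE])
  stats::setNames(med / dataset$somamers$dilution_bin, dataset$somamers$seq_id)
}

#' Elementwise log transform
#'
#' @param dataset a linear-scale [soma_dataset] with strictly positive RFU.
#' @param base logarithm base (natural by default).
#' @return The dataset on the log scale (`scale_state = "log"`).
#' @export
log_transform <- function(dataset, base = exp(1)) {
  if (dataset$scale_state %in% c("log", "adjusted"))
    stop("dataset is already on the log scale")
  if (any(dataset$rfu <= 0)) {
    ij <- which(dataset$rfu <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive RFU at (", rownames(dataset$rfu)[ij[1]], ", ",
         colnames(dataset$rfu)[ij[2]], "); cannot log-transform")
  }
  dataset$rfu <- log(dataset$rfu, base = base)
  dataset$scale_state <- "log"
  add_provenance(dataset, "log_transform", list(base = base))
}
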