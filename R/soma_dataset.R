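#' SomaScan-style dataset container
#'
#' Bundles an RFU matrix (samples x SOMAmers) with its two annotation tables
#' and an append-only provenance log. The matrix rows are keyed by
#' `sample_id`, the columns by `seq_id`; both must match the annotation
#' tables exactly.
#'
#' @param rfu numeric matrix of nonnegative relative fluorescence units,
#'   samples in rows, SOMAmers in columns, dimnames set to sample and seq IDs.
#' @param somamers data.frame of SOMAmer annotation; must contain `seq_id`,
#'   `target_name`, `dilution_bin`, `organism`, `somamer_type`,
#'   `secretion_class`, `calibrator_reference`, `is_hyb_control`.
#' @param samples data.frame of sample annotation; must contain `sample_id`,
#'   `participant_id`, `role`, `plate_id`, `well`, `processing_batch`,
#'   `processing_order`, `cohort`, `disease_group`, `spun`, `blood_grade`,
#'   `volume_ml`, `sample_age_years`, `freeze_thaw_count`, `vendor_flag`.
#' @param scale_state one of `"raw"`, `"standardised"`, `"log"`, `"adjusted"`.
#' @param provenance list of previously applied transforms (each a list with
#'   elements `op` and `params`).
#'
#' @return An object of class `soma_dataset`.
#' @export
soma_dataset <- function(rfu, somamers, samples,
                         scale_state = c("raw", "standardised", "log", "adjusted"),
                         provenance = list()) {
  scale_state <- match.arg(scale_state)
  rfu <- as.matrix(rfu)
  storage.mode(rfu) <- "double"
  somamers <- as.data.frame(somamers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(rfu) != nrow(samples))
    stop("rfu has ", nrow(rfu), " rows but samples table has ", nrow(samples))
  if (ncol(rfu) != nrow(somamers))
    stop("rfu has ", ncol(rfu), " columns but somamers table has ", nrow(somamers))
  rownames(rfu) <- samples$sample_id
  colnames(rfu) <- somamers$seq_id
  x <- structure(list(rfu = rfu, somamers = somamers, samples = samples,
                      scale_state = scale_state, provenance = provenance),
                 class = "soma_dataset")
  x
}

SOMAMER_TYPES <- c("protein", "spuriomer", "hyb_control_elution", "deprecated",
                   "non_biotin", "non_cleavable")
SECRETION_CLASSES <- c("secreted", "nuclear_not_secreted", "not_secreted_other",
                       "unknown")
SAMPLE_ROLES <- c("study", "pooled_oa", "pooled_injury", "calibrator",
                  "plasma_qc", "blank")
DISEASE_GROUPS <- c("oa", "injury", "healthy", "inflammatory", "none")
DILUTION_BINS <- c(0.20, 0.005, 0.00005)

#' @export
print.soma_dataset <- function(x, ...) {
  cat("soma_dataset:", nrow(x$rfu), "samples x", ncol(x$rfu), "SOMAmers\n")
  cat("  scale_state:", x$scale_state, "\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$samples$role)),
                                table(x$samples$role)), collapse = ", "), "\n")
  cat("  plates:", length(unique(x$samples$plate_id)), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                               collapse = " -> "), "\n")
  invisible(x)
}

## Append one provenance entry; provenance is append-only by construction.
add_provenance <- function(dataset, op, params = list()) {
  dataset$provenance <- c(dataset$provenance, list(list(op = op, params = params)))
  dataset
}

#' Subset a soma_dataset by samples and/or SOMAmers
#'
#' @param dataset a [soma_dataset].
#' @param samples logical/integer/character index into the sample dimension.
#' @param somamers logical/integer/character index into the SOMAmer dimension.
#' @param record if `TRUE`, record the subsetting in the provenance log.
#' @return the subsetted `soma_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, somamers = NULL, record = FALSE) {
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, dataset$samples$sample_id)
    dataset$rfu <- dataset$rfu[samples, , drop = FALSE]
    dataset$samples <- dataset$samples[samples, , drop = FALSE]
    rownames(dataset$samples) <- NULL
  }
  if (!is.null(somamers)) {
    if (is.character(somamers)) somamers <- match(somamers, dataset$somamers$seq_id)
    dataset$rfu <- dataset$rfu[, somamers, drop = FALSE]
    dataset$somamers <- dataset$somamers[somamers, , drop = FALSE]
    rownames(dataset$somamers) <- NULL
  }
  if (record)
    dataset <- add_provenance(dataset, "subset",
                              list(n_samples = nrow(dataset$rfu),
                                   n_somamers = ncol(dataset$rfu)))
  dataset
}

## Index helpers -------------------------------------------------------------

protein_idx <- function(dataset) which(dataset$somamers$somamer_type == "protein")
hyb_idx <- function(dataset) which(dataset$somamers$is_hyb_control)
role_idx <- function(dataset, roles) which(dataset$samples$role %in% roles)
study_pooled_idx <- function(dataset)
  role_idx(dataset, c("study", "pooled_oa", "pooled_injury"))

#' Validate a soma_dataset against its structural rules
#'
#' Report-only: the dataset itself is never modified. Rules checked include
#' uniqueness of `seq_id` and `(plate_id, well)`, permitted enum levels, the
#' three permitted dilution-bin fractions, nonnegative finite RFU on the raw
#' and standardised scales, role-consistent disease groups for blanks and
#' calibrators, and plates with fewer than three blanks (which would make the
#' limit-of-detection computation fail).
#'
#' @param dataset a [soma_dataset].
#' @return A data.frame with columns `rule`, `severity` (`"error"` or
#'   `"warning"`) and `ids` (offending identifiers, comma-separated); zero
#'   rows when the dataset is clean.
#' @export
validate_dataset <- function(dataset) {
  out <- list()
  bad <- function(rule, severity, ids) {
    out[[length(out) + 1L]] <<- data.frame(
      rule = rule, severity = severity,
      ids = paste(ids, collapse = ","), stringsAsFactors = FALSE)
  }
  sm <- dataset$somamers; sa <- dataset$samples
  dup <- sm$seq_id[duplicated(sm$seq_id)]
  if (length(dup)) bad("duplicate_seq_id", "error", unique(dup))
  dup <- sa$sample_id[duplicated(sa$sample_id)]
  if (length(dup)) bad("duplicate_sample_id", "error", unique(dup))
  pw <- paste(sa$plate_id, sa$well, sep = ":")
  if (anyDuplicated(pw)) {
    key <- pw[duplicated(pw)]
    bad("duplicate_plate_well", "error", sa$sample_id[pw %in% key])
  }
  off <- !sm$dilution_bin %in% DILUTION_BINS & !is.na(sm$dilution_bin)
  if (any(off)) bad("invalid_dilution_bin", "error", sm$seq_id[off])
  off <- !sm$somamer_type %in% SOMAMER_TYPES
  if (any(off)) bad("invalid_somamer_type", "error", sm$seq_id[off])
  off <- sm$is_hyb_control & sm$somamer_type != "hyb_control_elution"
  if (any(off)) bad("hyb_control_type_mismatch", "error", sm$seq_id[off])
  off <- !sa$role %in% SAMPLE_ROLES
  if (any(off)) bad("invalid_role", "error", sa$sample_id[off])
  off <- sa$role %in% c("blank", "calibrator") & sa$disease_group != "none"
  if (any(off)) bad("control_disease_group", "error", sa$sample_id[off])
  if (any(!is.finite(dataset$rfu))) {
    ij <- which(!is.finite(dataset$rfu), arr.ind = TRUE)
    bad("nonfinite_rfu", "error",
        paste(rownames(dataset$rfu)[ij[, 1]], colnames(dataset$rfu)[ij[, 2]],
              sep = "@"))
  } else if (dataset$scale_state %in% c("raw", "standardised") &&
             any(dataset$rfu < 0)) {
    ij <- which(dataset$rfu < 0, arr.ind = TRUE)
    bad("negative_rfu", "error",
        paste(rownames(dataset$rfu)[ij[, 1]], colnames(dataset$rfu)[ij[, 2]],
              sep = "@"))
  }
  nb <- table(sa$plate_id[sa$role == "blank"])
  plates <- unique(sa$plate_id)
  short <- plates[!plates %in% names(nb)[nb >= 3]]
  if (length(short))
    bad("plate_fewer_than_3_blanks_lod_unavailable", "warning", short)
  if (!length(out))
    return(data.frame(rule = character(), severity = character(),
                      ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## stop() if the validation report contains errors
assert_valid <- function(dataset) {
  rep <- validate_dataset(dataset)
  err <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(err))
    stop("invalid soma_dataset: ",
         paste(sprintf("%s [%s]", err$rule, err$ids), collapse = "; "))
  invisible(dataset)
}
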