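#' Pipeline configuration
#'
#' Collects every stage's parameters for [run_pipeline()]. Inputs may be
#' [soma_dataset] objects or paths to ADAT-style files.
#'
#' @param raw raw-scale main dataset (object or path).
#' @param paired optional paired spun/unspun raw dataset (object or path);
#'   required for the IPS branch.
#' @param steps standardisation step list (default omits median
#'   normalisation).
#' @param ips_branch `"both"` (co-primary outputs, default),
#'   `"with_ips"`, or `"without_ips"`.
#' @param gmm_pc which principal component carries the bimodal signal
#'   (default 2).
#' @param gmm_seed seed for the mixture-model restarts.
#' @param combat_order order of the sequential ComBat passes.
#' @param alpha,min_r2,lod_max_fraction,n_sd,pca_threshold,r2_formula
#'   filter parameters, see [apply_filters()].
#' @param out_dir optional directory for intermediate and final ADAT
#'   files, the filter report and the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(raw, paired = NULL,
                            steps = c("hyb", "plate", "cal"),
                            ips_branch = c("both", "with_ips", "without_ips"),
                            gmm_pc = 2L, gmm_seed = 0L,
                            combat_order = c("bimodal", "plate"),
                            alpha = 0.05, min_r2 = 0.5,
                            lod_max_fraction = 0.25, n_sd = 5,
                            pca_threshold = 0.80,
                            r2_formula = "squared_one_minus_ratio",
                            out_dir = NULL) {
  ips_branch <- match.arg(ips_branch)
  if (ips_branch != "without_ips" && is.null(paired))
    stop("the IPS branch needs a paired spun/unspun dataset")
  structure(as.list(environment()), class = "pipeline_config")
}

load_input <- function(x) {
  if (inherits(x, "soma_dataset")) return(x)
  if (is.character(x)) return(read_adat(x))
  stop("input must be a soma_dataset or a file path")
}

#' Run the end-to-end QC pipeline
#'
#' Standardisation (hybridisation normalisation, plate scaling,
#' calibration) -> log transform -> PCA on study + pooled wells -> Gaussian
#' mixture classification of the bimodal status on PC2 -> sequential ComBat
#' for status and plate -> optional IPS adjustment (weights from the paired
#' spun/unspun dataset) -> SOMAmer and sample filter battery -> final PCA.
#' Identical configuration and inputs give identical outputs and manifest.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result`: `branches` (per branch:
#'   filtered log-scale `dataset`, `linear_dataset`, `report`, final
#'   `pca`), `assignment` (bimodal), `ips_model` (when fitted), `factors`
#'   (standardisation factors), and `manifest` (stage parameters and
#'   checksums).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- list()
  mark <- function(name, obj, params = list())
    stage[[length(stage) + 1L]] <<- list(stage = name, params = params,
                                         checksum = object_checksum(obj))

  raw <- load_input(config$raw)
  mark("input", raw$rfu, list(samples = nrow(raw$rfu), somamers = ncol(raw$rfu)))

  std <- run_standardisation(raw, steps = config$steps)
  mark("standardise", std$dataset$rfu, list(steps = config$steps))
  lg <- log_transform(std$dataset)

  sp <- study_pooled_idx(lg)
  lg_sp <- subset_dataset(lg, samples = sp)
  pca0 <- fit_pca(lg_sp)
  if (config$gmm_pc > ncol(pca0$scores)) stop("gmm_pc exceeds components")
  assignment <- fit_pc2_gmm(stats::setNames(pca0$scores[, config$gmm_pc],
                                            pca0$sample_ids),
                            seed = config$gmm_seed)
  mark("gmm", assignment$params,
       list(pc = config$gmm_pc, seed = config$gmm_seed,
            n_high = sum(assignment$status == "high")))

  corr <- correct_bimodal_and_plate(lg_sp, assignment,
                                    order = config$combat_order)
  mark("combat", corr$dataset$rfu, list(order = config$combat_order))

  ips_model <- NULL
  branches_cfg <- switch(config$ips_branch,
                         both = c("without_ips", "with_ips"),
                         with_ips = "with_ips",
                         without_ips = "without_ips")
  if ("with_ips" %in% branches_cfg) {
    paired_raw <- load_input(config$paired)
    paired_std <- run_standardisation(paired_raw, steps = config$steps)
    paired_log <- log_transform(paired_std$dataset)
    ips_model <- compute_ips_weights(paired_log)
    mark("ips_weights", ips_model$weights,
         list(n_pairs = ips_model$n_pairs,
              excluded = length(ips_model$excluded)))
  }

  branches <- list()
  for (br in branches_cfg) {
    ds <- corr$dataset
    if (br == "with_ips") {
      ips <- compute_ips(ds, ips_model)
      ds <- adjust_for_ips(ds, ips)
    }
    flt <- apply_filters(ds, std$dataset,
                         alpha = config$alpha, min_r2 = config$min_r2,
                         lod_max_fraction = config$lod_max_fraction,
                         n_sd = config$n_sd,
                         pca_threshold = config$pca_threshold,
                         r2_formula = config$r2_formula)
    final_pca <- fit_pca(flt$dataset)
    mark(paste0("filter_", br), flt$dataset$rfu,
         list(surviving_samples = flt$report$surviving_samples,
              surviving_somamers = flt$report$surviving_somamers))
    branches[[br]] <- list(dataset = flt$dataset,
                           linear_dataset = flt$linear_dataset,
                           report = flt$report, pca = final_pca)
  }

  manifest <- list(
    package = "somaqc",
    version = as.character(utils::packageVersion("somaqc")),
    parameters = config[setdiff(names(config), c("raw", "paired", "out_dir"))],
    stages = stage)

  result <- structure(list(branches = branches, assignment = assignment,
                           ips_model = ips_model, factors = std$factors,
                           corrected = corr$dataset, standardised = std$dataset,
                           initial_pca = pca0, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with branches:", paste(names(x$branches), collapse = ", "), "\n")
  for (br in names(x$branches)) {
    b <- x$branches[[br]]
    cat(sprintf("  %-12s %d samples x %d SOMAmers after filtering\n", br,
                nrow(b$dataset$rfu), ncol(b$dataset$rfu)))
  }
  invisible(x)
}

## Write final datasets, reports and the manifest under out_dir.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (br in names(result$branches)) {
    b <- result$branches[[br]]
    write_adat(b$dataset, file.path(out_dir, paste0("final_", br, ".adat")))
    write_filter_report(b$report, file.path(out_dir, paste0("filters_", br, ".json")))
  }
  if (!is.null(result$ips_model))
    write_ips_model(result$ips_model, file.path(out_dir, "ips_model.json"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Serialise / read an IPS model as JSON
#'
#' @param model an `ips_model`.
#' @param path file path.
#' @return `write_ips_model`: invisibly `path`; `read_ips_model`: the model.
#' @export
write_ips_model <- function(model, path) {
  jsonlite::write_json(list(weights = as.list(model$weights),
                            n_pairs = model$n_pairs,
                            excluded = model$excluded,
                            variant = model$variant,
                            scale_note = model$scale_note),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ips_model
#' @export
read_ips_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(x$weights), n_pairs = x$n_pairs,
                 excluded = as.character(x$excluded %||% character()),
                 variant = x$variant, scale_note = x$scale_note),
            class = "ips_model")
}
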