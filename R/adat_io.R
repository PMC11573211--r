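## ADAT-style tab-delimited I/O.
##
## The dialect written here mirrors the vendor container's structure
## (header key-value block, a column-annotation block for SOMAmers, then a
## combined row-annotation + matrix block) without claiming byte
## compatibility with any particular vendor version; a configurable alias
## table maps vendor field names onto the canonical ones.

SOMAMER_FIELDS <- c(seq_id = "character", target_name = "character",
                    dilution_bin = "numeric", organism = "character",
                    somamer_type = "character", secretion_class = "character",
                    calibrator_reference = "numeric", is_hyb_control = "logical")
SAMPLE_FIELDS <- c(sample_id = "character", participant_id = "character",
                   role = "character", plate_id = "character", well = "character",
                   processing_batch = "integer", processing_order = "integer",
                   cohort = "character", disease_group = "character",
                   spun = "logical", blood_grade = "integer",
                   volume_ml = "numeric", sample_age_years = "numeric",
                   freeze_thaw_count = "integer", vendor_flag = "logical")

coerce_field <- function(x, type) {
  x[x == ""] <- NA
  switch(type,
         character = ifelse(is.na(x), NA_character_, x),
         numeric = as.numeric(x),
         integer = as.integer(x),
         logical = as.logical(x))
}

## Load an alias map from a YAML/JSON file or pass through a named list.
## Entries map canonical field name -> name used in the file.
read_alias_map <- function(alias_map) {
  if (is.null(alias_map)) return(list())
  if (is.character(alias_map) && length(alias_map) == 1L && file.exists(alias_map)) {
    if (grepl("\\.ya?ml$", alias_map)) return(yaml::read_yaml(alias_map))
    return(jsonlite::read_json(alias_map, simplifyVector = TRUE))
  }
  as.list(alias_map)
}

apply_aliases <- function(nms, alias_map) {
  for (canonical in names(alias_map)) nms[nms == alias_map[[canonical]]] <- canonical
  nms
}

#' Write a dataset as an ADAT-style tab-delimited file
#'
#' The emitted file has a `^HEADER` key-value block (scale state, provenance
#' as JSON, format version), a `^SOMAMER_DATA` block with one line per
#' annotation field, and a `^SAMPLE_DATA` block whose first row names the
#' sample fields followed by the SOMAmer `seq_id`s, with one row per sample.
#' RFU values are written with 17 significant digits so that
#' [read_adat()] recovers them to better than 1e-12 relative error.
#'
#' @param dataset a [soma_dataset].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_adat <- function(dataset, path) {
  stopifnot(inherits(dataset, "soma_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  esc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  w("^HEADER")
  w("!AdatFormat\tsomaqc-1.0")
  w("!ScaleState\t", dataset$scale_state)
  w("!Provenance\t", as.character(jsonlite::toJSON(dataset$provenance,
                                                   auto_unbox = TRUE, digits = NA,
                                                   null = "null")))
  extra_som <- setdiff(names(dataset$somamers), names(SOMAMER_FIELDS))
  extra_sam <- setdiff(names(dataset$samples), names(SAMPLE_FIELDS))
  w("^SOMAMER_DATA")
  for (f in c(names(SOMAMER_FIELDS), extra_som)) {
    v <- dataset$somamers[[f]]
    if (is.numeric(v)) v <- formatC(v, digits = 17, format = "g")
    v[is.na(dataset$somamers[[f]])] <- ""
    w(paste(c(f, v), collapse = "\t"))
  }
  w("^SAMPLE_DATA")
  sam_fields <- c(names(SAMPLE_FIELDS), extra_sam)
  w(paste(c(sam_fields, "", dataset$somamers$seq_id), collapse = "\t"))
  rfu_chr <- formatC(dataset$rfu, digits = 17, format = "g")
  for (i in seq_len(nrow(dataset$rfu))) {
    ann <- vapply(sam_fields, function(f) {
      v <- dataset$samples[[f]][i]
      if (is.na(v)) "" else as.character(v)
    }, "")
    w(paste(c(ann, "", rfu_chr[i, ]), collapse = "\t"))
  }
  w("^END")
  invisible(path)
}

#' Read an ADAT-style tab-delimited file
#'
#' @param path file to read.
#' @param alias_map optional field-name alias table: a named list (canonical
#'   name -> name used in the file), or a path to a YAML/JSON file holding
#'   one. Applied to both annotation blocks before parsing.
#' @return A [soma_dataset]. Unknown annotation fields are preserved
#'   verbatim as character columns.
#' @export
read_adat <- function(path, alias_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  alias_map <- read_alias_map(alias_map)
  lines <- readLines(path)
  sec <- function(tag) which(lines == tag)
  h0 <- sec("^HEADER"); s0 <- sec("^SOMAMER_DATA"); m0 <- sec("^SAMPLE_DATA")
  if (!length(m0))
    stop("format error: missing matrix block '^SAMPLE_DATA'; first line was: ",
         lines[1])
  if (!length(h0) || !length(s0))
    stop("format error: missing '^HEADER' or '^SOMAMER_DATA' block")
  endl <- sec("^END")
  endl <- if (length(endl)) endl[1] else length(lines) + 1L

  header <- list()
  for (ln in lines[(h0 + 1):(s0 - 1)]) {
    if (!startsWith(ln, "!")) next
    kv <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    header[[substring(kv[1], 2)]] <- if (length(kv) > 1) kv[2] else ""
  }
  scale_state <- header$ScaleState %||% "raw"
  provenance <- if (!is.null(header$Provenance) && nzchar(header$Provenance))
    jsonlite::fromJSON(header$Provenance, simplifyVector = FALSE) else list()

  ## SOMAmer block: one line per field
  som <- list()
  for (ln in lines[(s0 + 1):(m0 - 1)]) {
    cells <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    som[[cells[1]]] <- cells[-1]
  }
  names(som) <- apply_aliases(names(som), alias_map)
  n_som <- length(som[["seq_id"]])
  if (is.null(som$seq_id)) stop("format error: SOMAMER_DATA lacks seq_id")
  som_df <- as.data.frame(lapply(names(som), function(f) {
    type <- if (f %in% names(SOMAMER_FIELDS)) SOMAMER_FIELDS[[f]] else "character"
    v <- som[[f]]
    length(v) <- n_som  # right-pad truncated trailing empties
    coerce_field(v, type)
  }), stringsAsFactors = FALSE)
  names(som_df) <- names(som)

  ## SAMPLE block: header row then one row per sample
  hdr <- strsplit(lines[m0 + 1], "\t", fixed = TRUE)[[1]]
  split_at <- which(hdr == "")[1]
  if (is.na(split_at))
    stop("format error: malformed SAMPLE_DATA header (no annotation/matrix ",
         "separator): ", lines[m0 + 1])
  sam_fields <- apply_aliases(hdr[seq_len(split_at - 1)], alias_map)
  seq_ids <- hdr[(split_at + 1):length(hdr)]
  body <- lines[(m0 + 2):(endl - 1)]
  body <- body[nzchar(body)]
  mat <- matrix(NA_real_, length(body), length(seq_ids))
  sam <- matrix("", length(body), length(sam_fields))
  for (i in seq_along(body)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(cells) < split_at + length(seq_ids))
      stop("format error: malformed matrix row at line ", m0 + 1 + i, ": ",
           substr(body[i], 1, 60))
    sam[i, ] <- cells[seq_len(split_at - 1)]
    mat[i, ] <- as.numeric(cells[(split_at + 1):(split_at + length(seq_ids))])
  }
  sam_df <- as.data.frame(lapply(seq_along(sam_fields), function(j) {
    f <- sam_fields[j]
    type <- if (f %in% names(SAMPLE_FIELDS)) SAMPLE_FIELDS[[f]] else "character"
    coerce_field(sam[, j], type)
  }), stringsAsFactors = FALSE)
  names(sam_df) <- sam_fields

  ds <- soma_dataset(mat, som_df, sam_df, scale_state = scale_state,
                     provenance = provenance)
  rep <- validate_dataset(ds)
  dup <- rep[rep$rule %in% c("duplicate_seq_id", "duplicate_plate_well",
                             "duplicate_sample_id"), , drop = FALSE]
  if (nrow(dup))
    stop("validation error: ",
         paste(sprintf("%s [%s]", dup$rule, dup$ids), collapse = "; "))
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an annotation table as CSV
#'
#' @param dataset a [soma_dataset].
#' @param which `"somamers"` or `"samples"`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
export_annotation <- function(dataset, which = c("somamers", "samples"), path) {
  which <- match.arg(which)
  utils::write.csv(dataset[[which]], path, row.names = FALSE, na = "")
  invisible(path)
}
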