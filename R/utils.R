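## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. Keeps library code from perturbing
## user RNG streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive k reproducible sub-seeds from one master seed. Each generator
## effect consumes its own sub-stream, so toggling one effect leaves the
## draws of every other effect unchanged.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

## Column medians without apply() overhead for wide matrices.
col_medians <- function(m) {
  if (is.null(dim(m))) return(stats::median(m))
  apply(m, 2, stats::median)
}

row_medians <- function(m) apply(m, 1, stats::median)

## MD5 of an R object via serialisation to a temp file (used for the
## pipeline manifest's per-stage checksums).
object_checksum <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  ## version 3, fixed ASCII serialisation for cross-run stability
  saveRDS(x, f, version = 3, ascii = TRUE)
  unname(tools::md5sum(f))
}

## signif() that tolerates NA without warnings
fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
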