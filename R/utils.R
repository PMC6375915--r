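#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

clip01 <- function(x) pmin(1, pmax(0, x))

clip_range <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Derive a stream of per-stage seeds from one master seed.
#'
#' Deterministic and independent of R's RNG state; keeps every derived seed
#' below 2^31 so it is a valid R integer.
#' @noRd
derive_seeds <- function(master_seed, stages) {
  master_seed <- as.integer(master_seed)
  offs <- seq_along(stages) * 7919L  # fixed prime stride
  s <- (abs(master_seed) %% 1000000L) * 1000L + offs %% 1000000000L
  stats::setNames(as.integer(s %% 2147483647L), stages)
}

## Run `expr` with a local RNG state seeded by `seed`; the caller's RNG
## stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Format a numeric for CSV output with 6 significant digits (pipeline
## convention); leaves characters/integers alone.
format_sig6 <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 6, format = "g")
    out[is.na(x)] <- ""
    out
  } else x
}

## atomic CSV write (tmp + rename), floats at 6 significant digits
write_pipeline_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_sig6), stringsAsFactors = FALSE,
                       check.names = FALSE)
  tmp <- paste0(path, ".tmp")
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, ...)
  file.rename(tmp, path)
  invisible(path)
}

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
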