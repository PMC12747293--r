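#' @keywords internal
"_PACKAGE"

## Invisible-NULL placeholder so roxygen has a block to attach the package doc.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so seeded generators never perturb the global
#' random stream. Used by every generator in the package to make outputs
#' bit-reproducible for a fixed seed.
#'
#' @param seed Integer seed, or `NULL` to run against the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a label
#'
#' Deterministic splitting of one master seed into per-stage / per-replicate
#' streams. The derivation is a simple 32-bit polynomial hash; results stay in
#' `[0, 2^31 - 2]` so they are valid R integer seeds.
#'
#' @param seed Master integer seed.
#' @param ... Labels (strings or integers) identifying the child stream.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "decompose")
#' derive_seed(1, "bootstrap", 17)
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab)
    for (v in codes) h <- (h * 69069 + as.double(v) + 1) %% m
  }
  as.integer(h %% (m - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

## Fixed-format numeric serialization used by all TSV writers so that reruns
## with the same seed are byte-identical.
fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 12)
  out[is.na(x)] <- ""
  trimws(out)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
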