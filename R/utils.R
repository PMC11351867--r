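`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, kept below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483587)
}

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_same_shape <- function(a, b, what = "masks") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db))
    stop(sprintf("shape mismatch: %s have dimensions [%s] vs [%s]",
                 what, paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}
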