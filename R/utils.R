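#' @keywords internal
"_PACKAGE"

#' Derive a deterministic sub-seed from a master seed
#'
#' Hashes a master seed together with one or more stream indices into a
#' new 32-bit seed. Used throughout the package to give every
#' participant, replicate and bootstrap draw its own deterministic RNG
#' substream, so simulations are reproducible and individual components
#' are stable when unrelated parts of a design change.
#'
#' @param seed Master seed (integer).
#' @param ... Integer stream indices.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (k in idx) {
    h <- (h * 48271 + (as.numeric(k) + 1) * 16807) %% m
  }
  as.integer(if (h == 0) 1 else h)
}

## Evaluate expr under a temporary RNG seed, restoring the caller's state.
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

stop_config <- function(...) {
  stop(structure(class = c("longimorph_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("longimorph_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_data(sprintf("%s is missing required column(s): %s",
                      what, paste(missing, collapse = ", ")))
  invisible(df)
}
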