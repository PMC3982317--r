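# Internal helpers: structured conditions, logging, seeded RNG scopes.

#' Signal a structured parasurf error
#'
#' All user-facing failures in the package are conditions of class
#' `parasurf_error` with a specific subclass (e.g. `parasurf_empty_surface`)
#' and a `data` field carrying machine-readable context.
#'
#' @param message character, human-readable message.
#' @param class character, error subclass (without the `parasurf_` prefix).
#' @param data named list with structured context.
#' @keywords internal
#' @noRd
psf_stop <- function(message, class, data = list()) {
  cond <- structure(
    class = c(paste0("parasurf_", class), "parasurf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

# verbosity-gated log line; pipeline redirects via option
psf_log <- function(..., level = "info") {
  opt <- getOption("parasurf.verbose", FALSE)
  if (isTRUE(opt) || identical(level, "warn")) {
    message(sprintf("[parasurf:%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# squared Euclidean norm of rows
row_norms2 <- function(m) rowSums(m * m)

`%||%` <- function(a, b) if (is.null(a)) b else a
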