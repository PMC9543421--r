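# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators never clobber the session
#' stream. A `NULL` seed evaluates `code` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-300) stop("cannot normalise a zero-length vector")
  v / nv
}

is_unit <- function(v, tol = 1e-9) abs(sqrt(sum(v^2)) - 1) < tol

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# double -> shortest decimal string that round-trips bit-identically
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.nan(x)] <- "NaN"
  ok <- is.finite(x)
  if (any(ok)) {
    short <- sprintf("%.15g", x[ok])
    keep <- as.numeric(short) == x[ok]
    out[ok][keep] <- short[keep]
  }
  out
}
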