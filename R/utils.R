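# internal helpers

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "stackstab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_validation <- function(msg) abort(msg, "stackstab_validation_error")
abort_io <- function(msg) abort(msg, "stackstab_io_error")
abort_degenerate <- function(msg) abort(msg, "stackstab_degenerate_error")
abort_capability <- function(msg) abort(msg, "stackstab_capability_error")

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    abort_validation(sprintf("`%s` must be a single finite number", name))
}

#' Cyclically shift a frame
#'
#' Rolls a matrix so that content moves `dx` columns rightward and `dy`
#' rows downward, wrapping around the borders. Cyclic shifts are exact
#' translations in the Fourier sense, which makes them the reference
#' construction for registration oracles.
#'
#' @param frame numeric matrix.
#' @param dx integer column shift (positive moves content right).
#' @param dy integer row shift (positive moves content down).
#' @return the rolled matrix.
#' @export
cyclic_shift <- function(frame, dx, dy) {
  if (!is.matrix(frame)) abort_validation("`frame` must be a matrix")
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  h <- nrow(frame); w <- ncol(frame)
  frame[((seq_len(h) - 1L - dy) %% h) + 1L, ((seq_len(w) - 1L - dx) %% w) + 1L]
}

# half-precision emulation: quantize the mantissa to 10 bits
quantize_half <- function(x) {
  nz <- is.finite(x) & x != 0
  if (!any(nz)) return(x)
  e <- floor(log2(abs(x[nz])))
  q <- 2^(e - 10)
  x[nz] <- round(x[nz] / q) * q
  x
}
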