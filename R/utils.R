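# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation functions do not clobber the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Draw n reproducible sub-seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_param <- function(...) stop(..., call. = FALSE)

# Horner evaluation of sum coefs[i] * zz^(i-1) for complex zz.
polyval_zz <- function(coefs, zz) {
  acc <- rep(coefs[length(coefs)] + 0i, length(zz))
  for (i in rev(seq_len(length(coefs) - 1L))) acc <- acc * zz + coefs[i]
  acc
}

# Frequency response H(e^{i 2 pi f / fs}) of a rational filter with
# coefficients in powers of z^-1.
filter_freq_response <- function(b, a, f, fs) {
  zz <- exp(-2i * pi * f / fs)
  polyval_zz(b, zz) / polyval_zz(a, zz)
}

#' Sleep stage labels
#'
#' The five AASM stage labels used throughout the package, in the fixed
#' order W, N1, N2, N3, REM.
#' @return Character vector of length 5.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "REM")
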