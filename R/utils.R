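#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif quantile sd var lm coef qnorm predict
#'   pt rpois rexp approx nextn mvfft setNames
#' @importFrom utils head tail
NULL

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic signal of a real vector by zeroing the
#' negative-frequency half of its discrete Fourier transform. The modulus is
#' the instantaneous amplitude envelope and the argument the instantaneous
#' phase in `(-pi, pi]` (cosine convention: phase 0 at a signal peak).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
hilbert_analytic <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("signal too short for an analytic signal")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and phase of a band-limited signal
#'
#' @param x numeric vector, already band-pass filtered.
#' @param fs sampling rate in Hz.
#' @param band optional [band_spec()] describing the filter band.
#' @return an object of class `analytic_signal` with elements `amplitude`,
#'   `phase`, `fs` and `band`.
#' @export
analytic_signal <- function(x, fs, band = NULL) {
  z <- hilbert_analytic(x)
  structure(
    list(amplitude = Mod(z), phase = Arg(z), fs = fs, band = band),
    class = "analytic_signal"
  )
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat("<analytic_signal> ", length(x$amplitude), " samples @ ", x$fs, " Hz",
      sep = "")
  if (!is.null(x$band)) {
    cat(sprintf(", band %.2f-%.2f Hz", x$band$low_hz, x$band$high_hz))
  }
  cat("\n")
  invisible(x)
}

# wrap angles into (-pi, pi]
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# shift a vector by k samples (positive k delays: y[n] = x[n - k]);
# vacated entries are filled by edge replication to keep lengths equal.
shift_samples <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k == 0L) return(x)
  if (abs(k) >= n) stop("shift exceeds signal length")
  if (k > 0) c(rep(x[1L], k), x[seq_len(n - k)])
  else c(x[(1L - k):n], rep(x[n], -k))
}

# Pearson correlation that tolerates zero variance (returns 0).
safe_cor <- function(x, y) {
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(0)
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Interpolating polynomial spline of arbitrary order
#'
#' Fits an interpolating spline of the given order (order = degree + 1,
#' so `order = 5` is the quintic-flavoured smoothing used for coupling
#' spectra) through `(x, y)` and evaluates it at `xout`. Interior knots are
#' placed at running averages of the data sites (Greville-style), which
#' guarantees a well-posed interpolation problem.
#'
#' @param x,y data sites and values (x strictly increasing).
#' @param xout evaluation points inside `range(x)`.
#' @param order spline order (default 5).
#' @return numeric vector of interpolated values at `xout`.
#' @export
spline_interp <- function(x, y, xout, order = 5L) {
  stopifnot(length(x) == length(y), all(diff(x) > 0))
  n <- length(x)
  if (n < order) stop("need at least `order` points to interpolate")
  # interpolation knots: averages of order-1 consecutive interior sites
  if (n > order) {
    interior <- vapply(seq_len(n - order), function(i) {
      mean(x[(i + 1):(i + order - 1)])
    }, numeric(1))
  } else {
    interior <- numeric(0)
  }
  knots <- c(rep(x[1], order), interior, rep(x[n], order))
  B <- splines::splineDesign(knots, x, ord = order)
  coefs <- solve(B, y)
  xo <- pmin(pmax(xout, x[1]), x[n])
  Bo <- splines::splineDesign(knots, xo, ord = order)
  as.numeric(Bo %*% coefs)
}
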