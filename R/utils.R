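#' @useDynLib reefshield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rweibull rlnorm median sd var
#'   optim optimise fft qnorm pnorm cor rgamma approx spline uniroot setNames
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream seed from a global seed
#'
#' Counter-based fan-out so that the seed consumed by one stage or ensemble
#' member does not depend on how many random draws earlier stages made.
#' Two rounds of multiplicative (Lehmer-style) mixing, all arithmetic exact
#' in doubles; the result is a valid 32-bit integer seed.
#'
#' @param seed Global integer seed.
#' @param counter Non-negative integer stream index.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, counter) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.numeric(counter) %% m) * 16807) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 2) + 1)
}

#' Linear-theory (Airy) wavenumber
#'
#' Solves the linear dispersion relation `omega^2 = g k tanh(k d)` by
#' Newton iteration; vectorised over `omega` and `d`.
#'
#' @param omega Angular frequency (rad/s).
#' @param d Water depth (m, positive).
#' @param g Gravitational acceleration (m/s^2).
#' @return Wavenumber k (rad/m).
#' @export
airy_wavenumber <- function(omega, d, g = 9.81) {
  n <- max(length(omega), length(d))
  omega <- rep_len(omega, n)
  d <- rep_len(d, n)
  k <- omega / sqrt(g * pmax(d, 1e-6)) # shallow-water start
  for (it in 1:50) {
    kd <- k * d
    f <- g * k * tanh(kd) - omega^2
    fp <- g * tanh(kd) + g * kd / cosh(kd)^2
    k_new <- k - f / fp
    if (max(abs(k_new - k), na.rm = TRUE) < 1e-12) {
      k <- k_new
      break
    }
    k <- k_new
  }
  k
}

#' Analytic phase speed of the B = 1/15 Boussinesq model
#'
#' The linearised improved-dispersion Boussinesq system used here has
#' `c^2 = g d (1 + B (kd)^2) / (1 + (B + 1/3) (kd)^2)` with `B = 1/15`
#' (a Pade approximation to Airy dispersion).
#'
#' @param k Wavenumber (rad/m).
#' @param d Water depth (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return Phase speed (m/s).
#' @export
bq_phase_speed <- function(k, d, g = 9.81) {
  B <- 1 / 15
  kd <- k * d
  sqrt(g * d * (1 + B * kd^2) / (1 + (B + 1 / 3) * kd^2))
}

# invert the model dispersion relation: k for a given omega (vectorised)
bq_wavenumber <- function(omega, d, g = 9.81) {
  k <- airy_wavenumber(omega, d, g)
  for (it in 1:60) {
    f <- k * bq_phase_speed(k, d, g) - omega
    eps <- pmax(1e-8, k * 1e-6)
    fp <- ((k + eps) * bq_phase_speed(k + eps, d, g) -
             (k - eps) * bq_phase_speed(k - eps, d, g)) / (2 * eps)
    k_new <- k - f / fp
    if (max(abs(k_new - k)) < 1e-12) {
      k <- k_new
      break
    }
    k <- k_new
  }
  k
}

#' JONSWAP variance density spectrum
#'
#' @param f Frequencies (Hz).
#' @param hs Significant wave height (m); the returned spectrum is scaled so
#'   that `4 sqrt(integral S df)` equals `hs` exactly on the given grid.
#' @param tp Peak period (s).
#' @param gamma Peak-enhancement factor (3.3 default).
#' @return Variance density (m^2/Hz) at `f`.
#' @export
jonswap_spectrum <- function(f, hs, tp, gamma = 3.3) {
  fp <- 1 / tp
  sig <- ifelse(f <= fp, 0.07, 0.09)
  r <- exp(-(f - fp)^2 / (2 * sig^2 * fp^2))
  s <- f^-5 * exp(-1.25 * (f / fp)^-4) * gamma^r
  s[!is.finite(s)] <- 0
  df <- diff(f)
  df <- c(df[1], (df[-1] + df[-length(df)]) / 2, df[length(df)])[seq_along(f)]
  m0 <- sum(s * df)
  if (m0 <= 0) stop("degenerate spectrum")
  s * (hs / 4)^2 / m0
}

# discrete spectral components (amplitudes, angular frequencies, random
# phases) for an irregular sea state
wave_components <- function(hs, tp, n_freq = 100, f_range = c(0.5, 3),
                            gamma = 3.3, seed = NULL,
                            spectrum = c("jonswap", "monochromatic")) {
  spectrum <- match.arg(spectrum)
  if (spectrum == "monochromatic") {
    # regular wave train of height hs (amplitude hs/2) at the peak period
    return(list(f = 1 / tp, a = hs / 2, omega = 2 * pi / tp, phase = 0))
  }
  f <- seq(f_range[1] / tp, f_range[2] / tp, length.out = n_freq)
  df <- f[2] - f[1]
  S <- jonswap_spectrum(f, hs, tp, gamma)
  a <- sqrt(2 * S * df)
  if (!is.null(seed)) set.seed(seed)
  ph <- runif(n_freq, 0, 2 * pi)
  list(f = f, a = a, omega = 2 * pi * f, phase = ph)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
}
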