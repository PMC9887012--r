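# Hydraulic (Nikuradse) roughness: spectral attenuation estimation from
# paired pressure records, the structural-complexity-to-roughness power
# law, and assembly of continuous roughness profiles along the transect.

#' Depth-correct bottom pressure to surface elevation
#'
#' Per-burst FFT with the linear-theory pressure transfer function: each
#' frequency component of the (demeaned) pressure-head record is amplified
#' by `cosh(kh)/cosh(k z_a)`, where `z_a` is the sensor elevation above the
#' bed, up to a cutoff frequency (no amplification beyond it); `k` solves
#' the linear dispersion relation.
#'
#' @param pressure Pressure-head record (m): vector (one burst), matrix
#'   (samples x bursts), or a `pressure_records` object (all sensors).
#' @param depth Water depth (m) at the sensor.
#' @param rate_hz Sampling rate (Hz).
#' @param sensor_height Sensor elevation above the bed (m).
#' @param cutoff_hz No amplification above this frequency; must not exceed
#'   the Nyquist frequency.
#' @return Surface-elevation fluctuation series, same shape as the input.
#' @export
depth_correct_pressure <- function(pressure, depth, rate_hz,
                                   sensor_height = 0, cutoff_hz = 0.4) {
  if (cutoff_hz > rate_hz / 2) {
    stop("cutoff frequency above Nyquist")
  }
  stopifnot_positive(depth, "depth")
  if (inherits(pressure, "pressure_records")) {
    stop("pass one sensor's record (pressure[, , s]) with its depth")
  }
  p <- as.matrix(pressure)
  n <- nrow(p)
  f <- c(0, seq_len(n - 1)) / n * rate_hz
  f <- pmin(f, rate_hz - f) # folded (two-sided) frequencies
  amp <- rep(1, n)
  sel <- f > 0 & f <= cutoff_hz
  k <- airy_wavenumber(2 * pi * f[sel], depth)
  amp[sel] <- cosh(pmin(k * depth, 20)) /
    cosh(pmin(k * pmax(sensor_height, 0), 20))
  out <- apply(p, 2, function(col) {
    mu <- mean(col)
    Re(fft(fft(col - mu) * amp, inverse = TRUE)) / n
  })
  if (is.vector(pressure)) out <- drop(out)
  out
}

# two-sided periodogram integrated quantities on a frequency band
band_spectrum <- function(x, rate_hz, band) {
  n <- base::length(x)
  z <- fft(x - mean(x))
  f <- (seq_len(n) - 1) / n * rate_hz
  half <- f > 0 & f <= rate_hz / 2
  S <- 2 * Mod(z)^2 / n^2 # variance per bin (one-sided)
  sel <- half & f >= band[1] & f <= band[2]
  list(f = f[sel], var_bin = S[sel])
}

#' Estimate Nikuradse roughness from paired surface-elevation records
#'
#' Energy-balance (spectral attenuation) method: the sea-swell band energy
#' flux is computed at a seaward sensor A and a shoreward sensor B using
#' linear-theory group velocities (which absorbs the shoaling correction);
#' the flux loss per unit distance is attributed to bottom friction,
#' inverted for the wave energy-dissipation factor through
#' `eps = (2/3pi) rho f_w u_b^3`, and converted to `k_n` by inverting the
#' wave friction factor relation. One estimate per burst; bursts with
#' non-positive inferred dissipation are flagged and excluded.
#'
#' @param elev_a,elev_b Surface-elevation bursts (vector or samples x
#'   bursts matrix) at the seaward (A) and shoreward (B) sensor.
#' @param separation Distance between sensors (m).
#' @param depths Depths `c(h_A, h_B)` (m).
#' @param rate_hz Sampling rate (Hz).
#' @param band Sea-swell integration band (Hz).
#' @param rho Water density (kg/m^3).
#' @param kn_min Lower bound on the inverted roughness (m).
#' @return Data frame of class `kn_estimates`: `burst`, `kn` (m), `fw`,
#'   `eps` (W/m^2), `flagged`.
#' @export
estimate_kn_spectral <- function(elev_a, elev_b, separation, depths,
                                 rate_hz, band = c(0.04, 0.4), rho = 1025,
                                 kn_min = 1e-4) {
  A <- as.matrix(elev_a)
  B <- as.matrix(elev_b)
  if (ncol(A) != ncol(B)) stop("sensor records must have matching bursts")
  g <- 9.81
  h_a <- depths[1]
  h_b <- depths[2]
  out <- lapply(seq_len(ncol(A)), function(b) {
    sa <- band_spectrum(A[, b], rate_hz, band)
    sb <- band_spectrum(B[, b], rate_hz, band)
    # drop noise-dominated bins (no appreciable sea-swell energy at the
    # seaward sensor); the same bins are excluded at both sensors
    keep <- sa$var_bin > 1e-4 * max(sa$var_bin)
    sa$f <- sa$f[keep]
    sa$var_bin <- sa$var_bin[keep]
    sb$f <- sb$f[keep]
    sb$var_bin <- sb$var_bin[keep]
    om <- 2 * pi * sa$f
    cg_a <- airy_group_velocity(om, h_a, g)
    cg_b <- airy_group_velocity(2 * pi * sb$f, h_b, g)
    Fa <- sum(rho * g * sa$var_bin * cg_a)
    Fb <- sum(rho * g * sb$var_bin * cg_b)
    eps <- (Fa - Fb) / separation
    if (!is.finite(eps) || eps <= 0) {
      return(data.frame(burst = b, kn = NA_real_, fw = NA_real_,
                        eps = eps, flagged = TRUE))
    }
    k_a <- airy_wavenumber(om, h_a, g)
    w_j <- sa$var_bin * (om / sinh(pmin(k_a * h_a, 20)))^2
    u_br <- sqrt(2 * sum(w_j))
    om_r <- sum(w_j * om) / sum(w_j)
    a0 <- u_br / om_r
    fw <- 3 * pi * eps / (2 * rho * u_br^3)
    if (fw <= exp(-5.977)) {
      kn <- kn_min
      fl <- TRUE
    } else {
      kn <- a0 * ((log(fw) + 5.977) / 5.213)^(1 / 0.194)
      fl <- FALSE
    }
    data.frame(burst = b, kn = max(kn, kn_min), fw = fw, eps = eps,
               flagged = fl)
  })
  res <- do.call(rbind, out)
  if (any(res$flagged)) {
    attr(res, "log") <- sprintf(
      "%d of %d bursts flagged (no resolvable dissipation) and excluded",
      sum(res$flagged), nrow(res))
  }
  class(res) <- c("kn_estimates", "data.frame")
  res
}

#' Convert structural complexity to Nikuradse roughness
#'
#' Empirical power law `k_n = 0.01 x SC^2.98` (m) relating the rumple-index
#' structural complexity of the reef surface to its hydraulic roughness.
#'
#' @param sc Structural complexity (>= 1).
#' @return Roughness height (m).
#' @export
sc_to_kn <- function(sc) {
  if (any(!is.finite(sc)) || any(sc < 1)) {
    stop("structural complexity must be >= 1")
  }
  0.01 * sc^2.98
}

#' Build a continuous roughness profile along the transect
#'
#' The fore reef takes `sc_to_kn(SC)`; the reef crest and back reef scale
#' that value by section coefficients (ratios to the fore-reef roughness);
#' the sandy section (and subaerial beach) takes the grain-size roughness
#' `k_n = 2.5 d50`.
#'
#' @param sc Structural complexity draw for the reef state.
#' @param bathymetry A [generate_bathymetry()] profile with section labels.
#' @param coefficients List with `reef_crest` and `back_reef` ratios
#'   (`alpha = kn_section / kn_forereef`).
#' @param d50 Median sand grain size (m); default 63 micrometres.
#' @param state,replicate Optional labels carried into the output.
#' @return Data frame of class `kn_profile` with `x`, `kn`, `state`,
#'   `replicate`.
#' @export
build_kn_profile <- function(sc, bathymetry, coefficients = list(
                               reef_crest = 1, back_reef = 1),
                             d50 = 63e-6, state = NA, replicate = NA_integer_) {
  stopifnot_positive(d50, "d50")
  kn_reef <- sc_to_kn(sc)
  kn_sand <- 2.5 * d50
  sec <- bathymetry$section
  kn <- rep(NA_real_, base::length(sec))
  kn[sec == "fore_reef"] <- kn_reef
  kn[sec == "sand" | sec == "beach"] <- kn_sand
  if (any(sec == "reef_crest")) {
    a <- coefficients$reef_crest
    if (is.null(a)) stop("missing coefficient for section 'reef_crest'")
    kn[sec == "reef_crest"] <- a * kn_reef
  }
  if (any(sec %in% c("reef_flat", "back_reef"))) {
    a <- coefficients$back_reef
    if (is.null(a)) stop("missing coefficient for section 'back_reef'")
    kn[sec %in% c("reef_flat", "back_reef")] <- a * kn_reef
  }
  if (any(is.na(kn))) {
    stop("missing coefficient for a labelled reef section: ",
         paste(unique(sec[is.na(kn)]), collapse = ", "))
  }
  out <- data.frame(x = bathymetry$x, kn = kn, state = state,
                    replicate = replicate)
  class(out) <- c("kn_profile", "data.frame")
  out
}

#' Monte-Carlo roughness profiles for all reef states
#'
#' One continuous roughness profile per structural-complexity replicate
#' (100 per year at study scale, 1000 profiles in total).
#'
#' @param sc_ensemble An [complexity_ensemble()] result (`year`,
#'   `replicate`, `sc`).
#' @param bathymetry Bathymetry profile.
#' @param coefficients Section coefficients (see [build_kn_profile()]).
#' @param d50 Sand grain size (m).
#' @return Data frame of class `kn_profile` (long) with `x`, `kn`, `state`,
#'   `replicate`.
#' @export
roughness_ensemble <- function(sc_ensemble, bathymetry,
                               coefficients = list(reef_crest = 1,
                                                   back_reef = 1),
                               d50 = 63e-6) {
  out <- lapply(seq_len(nrow(sc_ensemble)), function(i) {
    build_kn_profile(sc_ensemble$sc[i], bathymetry, coefficients, d50,
                     state = sc_ensemble$year[i],
                     replicate = sc_ensemble$replicate[i])
  })
  res <- do.call(rbind, out)
  class(res) <- c("kn_profile", "data.frame")
  res
}

#' Representative (pointwise-median) roughness profile per state
#'
#' Collapses the Monte-Carlo roughness replicates of each state to its
#' pointwise median profile, the profile used in the simulation ensemble.
#'
#' @param kn_profiles Long `kn_profile` data frame (from
#'   [roughness_ensemble()]).
#' @return Named list of per-state `kn_profile` data frames.
#' @export
representative_kn_profile <- function(kn_profiles) {
  states <- unique(kn_profiles$state)
  setNames(lapply(states, function(s) {
    sub <- kn_profiles[kn_profiles$state == s, ]
    xs <- sort(unique(sub$x))
    kn <- vapply(xs, function(xx) median(sub$kn[sub$x == xx]), numeric(1))
    out <- data.frame(x = xs, kn = kn, state = s, replicate = NA_integer_)
    class(out) <- c("kn_profile", "data.frame")
    out
  }), states)
}
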