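# Synthetic input generators: coral survey tables, cross-shore bathymetry,
# offshore wave climate and paired bottom-pressure records. These emulate
# the statistical structure of the field inputs the analysis assumes
# (multi-year coral cover trajectories through a disturbance-recovery
# cycle, a fringing-reef transect from 20 m depth to the beach, a
# multi-decadal weekly offshore wave climate, and 4 Hz pressure-transducer
# bursts) so that every downstream stage is testable without field data.

default_cover_trajectory <- function() {
  # disturbance-recovery cycle: high cover, collapse to 3%, recovery with
  # Pocillopora dominance
  tab <- data.frame(
    year = c(2005, 2008, 2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016),
    total = c(0.50, 0.35, 0.20, 0.08, 0.03, 0.08, 0.15, 0.25, 0.35, 0.45),
    f_acr = c(0.40, 0.35, 0.28, 0.22, 0.20, 0.20, 0.20, 0.21, 0.22, 0.22),
    f_poc = c(0.30, 0.33, 0.38, 0.42, 0.43, 0.52, 0.56, 0.58, 0.60, 0.62),
    f_por = c(0.30, 0.32, 0.34, 0.36, 0.37, 0.28, 0.24, 0.21, 0.18, 0.16)
  )
  data.frame(
    year = tab$year,
    Acropora = tab$total * tab$f_acr,
    Pocillopora = tab$total * tab$f_poc,
    Porites = tab$total * tab$f_por
  )
}

default_size_params <- function() {
  # lognormal colony width (m); length ~ width * U(0.8, 1.2);
  # height = width * aspect * lognormal jitter
  list(
    Acropora = list(meanlog = log(0.55), sdlog = 0.35, aspect = 0.45),
    Pocillopora = list(meanlog = log(0.40), sdlog = 0.35, aspect = 0.95),
    Porites = list(meanlog = log(0.40), sdlog = 0.40, aspect = 0.65)
  )
}

#' Generate a synthetic coral survey table
#'
#' Per-year, per-taxon planar cover fractions and colony size samples
#' (width, length, height) for the three dominant taxa, following a
#' disturbance-recovery trajectory: high pre-disturbance cover (50%),
#' collapse to 3%, and recovery dominated by *Pocillopora*.
#'
#' @param years Survey years; must be covered by the trajectory.
#' @param disturbance_trajectory Data frame with columns `year` and one
#'   cover column per taxon (fractions in `[0, 1]`); defaults to the
#'   built-in disturbance-recovery cycle.
#' @param n_size_samples Colony size triples drawn per (year, taxon).
#' @param size_params Per-taxon lognormal width parameters and height
#'   aspect ratios (see `default_size_params`).
#' @param seed Integer seed.
#' @return A data frame of class `survey_table` with columns `year`,
#'   `taxon`, `cover` and a list column `size_samples` of `n x 3` matrices
#'   (width, length, height in m).
#' @export
generate_survey_table <- function(years = NULL, disturbance_trajectory = NULL,
                                  n_size_samples = 50, size_params = NULL,
                                  seed = 1) {
  traj <- disturbance_trajectory %||% default_cover_trajectory()
  years <- years %||% traj$year
  taxa <- setdiff(names(traj), "year")
  if (!all(years %in% traj$year)) {
    stop("`years` must be present in the disturbance trajectory")
  }
  covers <- as.matrix(traj[match(years, traj$year), taxa, drop = FALSE])
  if (any(covers < 0) || any(covers > 1) || any(rowSums(covers) > 1 + 1e-9)) {
    stop("trajectory covers must be in [0, 1] and sum to at most 1 per year")
  }
  sp <- size_params %||% default_size_params()
  set.seed(seed)
  rows <- list()
  for (i in seq_along(years)) {
    for (tx in taxa) {
      cov <- covers[i, tx]
      if (cov > 0) {
        p <- sp[[tx]]
        if (is.null(p)) stop(sprintf("no size parameters for taxon '%s'", tx))
        w <- rlnorm(n_size_samples, p$meanlog, p$sdlog)
        l <- w * runif(n_size_samples, 0.8, 1.2)
        h <- w * p$aspect * rlnorm(n_size_samples, 0, 0.15)
        sizes <- cbind(width = w, length = l, height = h)
      } else {
        sizes <- matrix(numeric(0), ncol = 3,
                        dimnames = list(NULL, c("width", "length", "height")))
      }
      rows[[length(rows) + 1]] <- data.frame(year = years[i], taxon = tx,
                                             cover = cov)
      rows[[length(rows)]]$size_samples <- list(sizes)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("survey_table", "data.frame")
  out
}

#' Generate a cross-shore reef bathymetry profile
#'
#' Piecewise-linear fringing-reef transect at 1 m (configurable)
#' resolution: fore reef rising from deep water to a shallow crest, a reef
#' flat, a sandy lagoon section, and a subaerial beach. Each node carries a
#' geomorphologic section label.
#'
#' @param config List overriding any of: `offshore_depth` (m, default 20),
#'   `fore_reef_length` (160), `crest_depth` (0.5), `crest_width` (20),
#'   `flat_depth` (1.5), `back_reef_width` (150), `lagoon_depth` (2.5),
#'   `sand_width` (160), `beach_slope` (0.1), `beach_height` (8), `dx` (1).
#'   Coral roughness occupies the fore reef, crest and a short back-reef
#'   strip; the remainder of the reef-flat/lagoon section is sandy (the
#'   sandy section is delineated within the reef flat), deepening toward
#'   the beach so reformed waves re-shoal onto the beach face. Alternatively a
#'   `segments` data frame (`length`, `end_z`, `label`) builds an arbitrary
#'   piecewise profile starting at `-offshore_depth`.
#' @return Data frame of class `bathymetry_profile` with `x` (m), `z` (m,
#'   negative below still water) and `section`.
#' @export
generate_bathymetry <- function(config = list()) {
  cfg <- modifyList(list(
    offshore_depth = 20, fore_reef_length = 160, crest_depth = 0.5,
    crest_width = 20, flat_depth = 1.5, back_reef_width = 150,
    lagoon_depth = 2.5, sand_width = 160,
    beach_slope = 0.1, beach_height = 8, dx = 1
  ), config)
  if (is.null(cfg$segments)) {
    if (cfg$crest_depth > cfg$flat_depth) {
      stop("non-monotone segment specification: reef crest must be ",
           "shallower than the reef flat")
    }
    beach_len <- (cfg$beach_height + cfg$lagoon_depth) / cfg$beach_slope
    segs <- data.frame(
      length = c(cfg$fore_reef_length, cfg$crest_width,
                 cfg$back_reef_width, cfg$sand_width, beach_len),
      end_z = c(-cfg$crest_depth, -cfg$crest_depth, -cfg$flat_depth,
                -cfg$lagoon_depth, cfg$beach_height),
      label = c("fore_reef", "reef_crest", "back_reef", "sand", "beach"),
      stringsAsFactors = FALSE
    )
  } else {
    segs <- cfg$segments
  }
  if (any(segs$length <= 0)) {
    stop("non-monotone segment specification: lengths must be positive")
  }
  x <- 0
  z <- -cfg$offshore_depth
  xs <- list(0)
  zs <- list(-cfg$offshore_depth)
  labs <- list(segs$label[1])
  for (i in seq_len(nrow(segs))) {
    n_i <- max(1, round(segs$length[i] / cfg$dx))
    xi <- x + seq_len(n_i) * cfg$dx
    zi <- z + (segs$end_z[i] - z) * seq_len(n_i) / n_i
    xs[[i + 1]] <- xi
    zs[[i + 1]] <- zi
    labs[[i + 1]] <- rep(segs$label[i], n_i)
    x <- xi[n_i]
    z <- segs$end_z[i]
  }
  out <- data.frame(x = unlist(xs), z = unlist(zs),
                    section = unlist(labs), stringsAsFactors = FALSE)
  class(out) <- c("bathymetry_profile", "data.frame")
  out
}

#' Generate a synthetic multi-decadal offshore wave climate
#'
#' Weekly significant wave height and peak period pairs. `Hs` follows a
#' Weibull marginal (default mode near 1.5 m); `Tp` is linked through a
#' Gaussian copula of strength `rho`, so that round-trip copula fitting by
#' [fit_hs_tp_copula()] is testable.
#'
#' @param n_years Number of years (52 weekly records per year).
#' @param hs_shape,hs_scale Weibull parameters of the `Hs` marginal.
#' @param tp_meanlog,tp_sdlog Lognormal parameters of the `Tp` marginal.
#' @param rho Gaussian-copula correlation, `|rho| < 1`.
#' @param seed Integer seed.
#' @return Data frame of class `wave_climate` with `week_index`, `hs` (m),
#'   `tp` (s).
#' @export
generate_wave_climate <- function(n_years = 30, hs_shape = 2,
                                  hs_scale = 1.5 * sqrt(2),
                                  tp_meanlog = log(12), tp_sdlog = 0.12,
                                  rho = 0.5, seed = 1) {
  if (abs(rho) >= 1) stop("invalid dependence parameter: |rho| must be < 1")
  stopifnot_positive(c(hs_shape, hs_scale, tp_sdlog), "marginal parameters")
  n <- 52 * n_years
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  hs <- stats::qweibull(pnorm(z1), hs_shape, hs_scale)
  tp <- stats::qlnorm(pnorm(z2), tp_meanlog, tp_sdlog)
  hs <- pmax(hs, 0.01)
  out <- data.frame(week_index = seq_len(n), hs = hs, tp = tp)
  class(out) <- c("wave_climate", "data.frame")
  out
}

#' Generate synthetic paired bottom-pressure records
#'
#' Forward model for the spectral roughness inversion: synthesises
#' bed-mounted pressure-transducer bursts at two or more cross-shore
#' sensors such that the spectral energy flux decays between consecutive
#' sensors exactly according to the friction-dissipation law inverted by
#' [estimate_kn_spectral()] (Jonsson friction factor, energy dissipation
#' `(2/3pi) rho f_w u_b^3`). Used as the closed-loop oracle for roughness
#' recovery.
#'
#' @param hs,tp Sea state at the seaward sensor (m, s).
#' @param sensor_depths Water depths of the sensors (m), seaward first.
#' @param separation Distance between consecutive sensors (m).
#' @param kn_true Nikuradse roughness between the sensors (m); `0` switches
#'   friction off (equal flux at all sensors).
#' @param n_bursts Number of bursts.
#' @param burst_seconds Burst length (s).
#' @param rate_hz Sampling rate (Hz).
#' @param snr Signal-to-noise ratio of additive Gaussian noise (amplitude
#'   ratio); the default reflects the mm-scale resolution of modern
#'   pressure transducers relative to metre-scale wave signals. `Inf`
#'   disables noise.
#' @param n_freq Spectral components per burst.
#' @param seed Integer seed.
#' @return Object of class `pressure_records`: list with `pressure` (array
#'   samples x bursts x sensors, pressure head in m), `depths`,
#'   `separation`, `rate_hz`, `burst_seconds`, `kn_true`.
#' @export
generate_pressure_records <- function(hs = 2, tp = 12,
                                      sensor_depths = c(3, 2.5),
                                      separation = 40, kn_true = 0.42,
                                      n_bursts = 8, burst_seconds = 900,
                                      rate_hz = 4, snr = 100, n_freq = 64,
                                      seed = 1) {
  if (length(sensor_depths) < 2) stop("at least 2 sensors are required")
  stopifnot_positive(sensor_depths, "sensor_depths")
  if (kn_true < 0) stop("kn_true must be >= 0")
  ns <- length(sensor_depths)
  nsamp <- round(burst_seconds * rate_hz)
  tt <- (seq_len(nsamp) - 1) / rate_hz
  g <- 9.81
  rho <- 1025
  set.seed(seed)
  P <- array(0, dim = c(nsamp, n_bursts, ns))
  for (b in seq_len(n_bursts)) {
    comp <- wave_components(hs, tp, n_freq, f_range = c(0.55, 2.8))
    # snap component frequencies to the burst's Fourier grid so that the
    # discrete spectra of the records are leakage-free
    f_snap <- unique(round(comp$f * burst_seconds)) / burst_seconds
    f_snap <- f_snap[f_snap > 0]
    S <- jonswap_spectrum(f_snap, hs, tp)
    df <- mean(diff(f_snap))
    a <- sqrt(2 * S * df)
    om <- 2 * pi * f_snap
    ph <- runif(base::length(f_snap), 0, 2 * pi)
    for (s in seq_len(ns)) {
      h_s <- sensor_depths[s]
      k_s <- airy_wavenumber(om, h_s, g)
      if (s > 1) {
        h_a <- sensor_depths[s - 1]
        k_a <- airy_wavenumber(om, h_a, g)
        cg_a <- airy_group_velocity(om, h_a, g)
        cg_b <- airy_group_velocity(om, h_s, g)
        Fa <- sum(rho * g * a^2 / 2 * cg_a)
        if (kn_true > 0) {
          ub2 <- sum(a^2 / 2 * (om / sinh(pmin(k_a * h_a, 20)))^2)
          u_br <- sqrt(2 * ub2)
          w_j <- a^2 / 2 * (om / sinh(pmin(k_a * h_a, 20)))^2
          om_r <- sum(w_j * om) / sum(w_j)
          a0 <- u_br / om_r
          fw <- friction_factor(kn_true, a0)
          eps <- 2 / (3 * pi) * rho * fw * u_br^3
          Fb <- Fa - separation * eps
          if (Fb <= 0) {
            stop("dissipation exceeds incoming flux; reduce kn_true or ",
                 "separation")
          }
        } else {
          Fb <- Fa
        }
        a <- a * sqrt((Fb / Fa) * cg_a / cg_b)
        ph <- ph - k_a * separation
      }
      att <- 1 / cosh(pmin(k_s * h_s, 20))
      sig <- (a * att) %*% t(rep(1, nsamp)) # amplitudes at bed
      surf <- cos(outer(om, tt) + ph)
      p <- colSums(sig * surf)
      if (is.finite(snr) && snr > 0) p <- p + rnorm(nsamp, 0, sd(p) / snr)
      P[, b, s] <- p
    }
  }
  structure(list(pressure = P, depths = sensor_depths,
                 separation = separation, rate_hz = rate_hz,
                 burst_seconds = burst_seconds, kn_true = kn_true,
                 hs = hs, tp = tp),
            class = "pressure_records")
}

# linear group velocity
airy_group_velocity <- function(omega, d, g = 9.81) {
  k <- airy_wavenumber(omega, d, g)
  c <- omega / k
  kh <- pmin(k * d, 20)
  c / 2 * (1 + 2 * kh / sinh(2 * kh))
}
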