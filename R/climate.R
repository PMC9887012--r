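# Wave-climate ensemble: Hs-Tp dependence via a Gaussian copula on
# rank-transformed margins, the 1000 percentile wave conditions, and the
# reef-state x wave-condition simulation ensemble.

#' Fit an Hs-Tp copula to a wave climate
#'
#' Fits empirical marginals and a one-parameter Gaussian copula to the
#' weekly (Hs, Tp) pairs by maximum likelihood on the rank-transformed
#' (pseudo-) observations; reports the dependence parameter and the
#' corresponding Kendall's tau (`tau = (2/pi) asin(rho)`).
#'
#' @param climate A [generate_wave_climate()] data frame (`hs`, `tp`).
#' @return Object of class `hs_tp_copula`: `rho`, `tau`, `tau_empirical`,
#'   `loglik`, `hs_sorted`, `tp_sorted`, `n`.
#' @export
fit_hs_tp_copula <- function(climate) {
  hs <- climate$hs
  tp <- climate$tp
  n <- base::length(hs)
  if (n < 100) stop("at least 100 (hs, tp) pairs are required")
  if (sd(hs) == 0 || sd(tp) == 0) stop("degenerate (constant) series")
  u <- rank(hs) / (n + 1)
  v <- rank(tp) / (n + 1)
  z1 <- qnorm(u)
  z2 <- qnorm(v)
  nll <- function(rho) {
    r2 <- rho^2
    0.5 * n * log(1 - r2) +
      sum((r2 * (z1^2 + z2^2) - 2 * rho * z1 * z2) / (2 * (1 - r2)))
  }
  opt <- optimise(nll, c(-0.999, 0.999))
  rho <- opt$minimum
  structure(list(rho = rho, tau = 2 / pi * asin(rho),
                 tau_empirical = cor(hs, tp, method = "kendall"),
                 loglik = -opt$objective,
                 hs_sorted = sort(hs), tp_sorted = sort(tp), n = n),
            class = "hs_tp_copula")
}

#' @export
print.hs_tp_copula <- function(x, ...) {
  cat(sprintf(
    "Gaussian Hs-Tp copula: rho = %.3f (Kendall tau %.3f, empirical %.3f), n = %d\n",
    x$rho, x$tau, x$tau_empirical, x$n))
  invisible(x)
}

#' Build the percentile wave conditions
#'
#' Offshore significant wave heights at all percentiles from 0.1 to 100
#' in steps of 0.1 (1000 conditions), each linked to a peak period through
#' the fitted copula: `Tp` is the conditional median (default) of its
#' marginal given the `Hs` percentile.
#'
#' @param climate The wave climate used for empirical quantiles.
#' @param copula A fitted [fit_hs_tp_copula()].
#' @param percentiles Percentile grid (default `seq(0.1, 100, by = 0.1)`).
#' @param linkage `"median"` (conditional median) or `"mean"` (conditional
#'   expectation, by quadrature).
#' @return Data frame of class `wave_conditions` with `percentile`, `hs`,
#'   `tp`.
#' @export
build_conditions <- function(climate, copula,
                             percentiles = seq(0.1, 100, by = 0.1),
                             linkage = c("median", "mean")) {
  linkage <- match.arg(linkage)
  hs <- unname(quantile(climate$hs, percentiles / 100, type = 7))
  n <- copula$n
  u <- pmin(pmax(percentiles / 100, 0.5 / n), 1 - 0.5 / n)
  zu <- qnorm(u)
  rho <- copula$rho
  tp_q <- function(v) {
    unname(quantile(climate$tp, pmin(pmax(v, 0), 1), type = 7))
  }
  if (linkage == "median") {
    v <- pnorm(rho * zu)
    tp <- tp_q(v)
  } else {
    tp <- vapply(zu, function(z) {
      qq <- seq(0.005, 0.995, by = 0.01)
      vv <- pnorm(rho * z + sqrt(1 - rho^2) * qnorm(qq))
      mean(tp_q(vv))
    }, numeric(1))
  }
  out <- data.frame(percentile = percentiles, hs = hs, tp = tp)
  class(out) <- c("wave_conditions", "data.frame")
  out
}

#' Dissipated energy fraction of a simulation
#'
#' `1 - F_innerflat / F_toe` from the time-mean energy-flux diagnostics,
#' clipped to `[0, 1]`.
#'
#' @param result A `reef_simulation`.
#' @return Absorbed fraction of the incoming wave energy.
#' @export
energy_absorption <- function(result) {
  if (is.null(result$flux_toe) || !is.finite(result$flux_toe)) {
    stop("missing flux diagnostics")
  }
  clip01(1 - result$flux_flat / result$flux_toe)
}

#' Run the reef-state x wave-condition simulation ensemble
#'
#' One Boussinesq run per (reef state, wave condition) pair; per-run seeds
#' are derived deterministically from the global seed, so the ensemble is
#' reproducible and rows are independent of execution order. Individual
#' run failures are caught, logged and marked, and the ensemble continues.
#'
#' @param states Named list of per-state roughness profiles (data frames
#'   with `x`, `kn`; see [representative_kn_profile()]).
#' @param conditions A [build_conditions()] data frame (or any data frame
#'   with `hs`, `tp`).
#' @param bathymetry The bathymetry profile shared by all runs.
#' @param duration Simulated duration per run (s).
#' @param seed Global integer seed.
#' @param config A [model_config()].
#' @param sc_by_state Optional named vector of state structural
#'   complexities carried into the output (for the Bayesian stage).
#' @param checkpoint Optional CSV path; completed rows found there are
#'   skipped and new rows appended (resumable ensemble).
#' @return Data frame of class `ensemble_table`: `state`, `condition`,
#'   `percentile`, `hs_offshore`, `tp`, `sc`, `r2`, `hs_nearshore`,
#'   `dissipated_fraction`, `failed`.
#' @export
run_ensemble <- function(states, conditions, bathymetry, duration = 1200,
                         seed = 1, config = model_config(),
                         sc_by_state = NULL, checkpoint = NULL) {
  state_names <- names(states) %||% as.character(seq_along(states))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.csv(checkpoint, stringsAsFactors = FALSE)
  }
  rows <- vector("list", base::length(states) * nrow(conditions))
  k <- 0
  for (is in seq_along(states)) {
    st <- state_names[is]
    kn_prof <- states[[is]]
    for (ic in seq_len(nrow(conditions))) {
      k <- k + 1
      if (!is.null(done) &&
          any(done$state == st & done$condition == ic & !done$failed)) {
        rows[[k]] <- done[done$state == st & done$condition == ic, ][1, ]
        next
      }
      # seed depends on the condition only: every state sees the same
      # incident wave realisation, so state contrasts are paired
      run_seed <- fan_seed(seed, ic)
      hs <- conditions$hs[ic]
      tp <- conditions$tp[ic]
      res <- tryCatch(
        run_simulation(bathymetry, kn_prof, hs, tp, duration = duration,
                       seed = run_seed, config = config),
        error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("run failed (state %s, condition %d): %s",
                        st, ic, conditionMessage(res)))
        row <- data.frame(state = st, condition = ic,
                          percentile = conditions$percentile[ic] %||% NA,
                          hs_offshore = hs, tp = tp,
                          sc = unname((sc_by_state %||% NA)[st]) %||% NA,
                          r2 = NA_real_, hs_nearshore = NA_real_,
                          dissipated_fraction = NA_real_, failed = TRUE)
      } else {
        i_near <- which(res$section %in% c("reef_flat", "back_reef"))
        hs_near <- if (base::length(i_near)) {
          res$hs_x[i_near[base::length(i_near)]]
        } else {
          res$hs_x[base::length(res$hs_x)]
        }
        row <- data.frame(state = st, condition = ic,
                          percentile = conditions$percentile[ic] %||% NA,
                          hs_offshore = hs, tp = tp,
                          sc = unname((sc_by_state %||% NA)[st]) %||% NA,
                          r2 = res$r2, hs_nearshore = hs_near,
                          dissipated_fraction = res$dissipated_fraction,
                          failed = FALSE)
      }
      rows[[k]] <- row
      if (!is.null(checkpoint)) {
        write.csv(do.call(rbind, rows[seq_len(k)]), checkpoint,
                  row.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_table", "data.frame")
  out
}
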