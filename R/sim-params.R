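#' Simulator parameters for the cross-feeding serial-transfer model
#'
#' Parameters of the stochastic consumer--resource model of two amino-acid
#' auxotrophs (a tryptophan auxotroph that over-produces tyrosine and a
#' tyrosine auxotroph that over-produces tryptophan). Within a 72-h batch,
#' each genotype class grows at
#' `r * g_aa * g_ab * (1 - N_tot / C)` where `g_aa = [AA] / (K_aa + [AA])`
#' is Monod limitation by the required free amino acid (1 for prototrophs),
#' and `g_ab = 1 / (1 + (conc / MIC)^kappa)` is pharmacodynamic suppression.
#' Bactericidal antibiotics additionally kill at rate
#' `delta_max * (conc/MIC)^kappa / (1 + (conc/MIC)^kappa)`. Divisions release
#' the partner's amino acid (rate `rho` per 1e9 new cells), a small basal
#' leakage `rho_leak` is released per unit biomass and time, and auxotroph
#' divisions consume their required amino acid (`q_aa` per 1e9 new cells).
#' Resistance evolves in discrete steps: a per-division probability `mu_res`
#' moves a cell one MIC-multiplier level up (`MIC = m0 * lambda^level`, at
#' most `L` levels); a per-division, per-strain probability `mu_rev` restores
#' prototrophy.
#'
#' None of the rate constants are measured quantities of the study system;
#' they are calibrated once (see the package vignette) and frozen in
#' `inst/extdata/sim-params-default.yaml`, which [default_sim_params()]
#' loads.
#'
#' @param r named numeric, maximum growth rate per strain (1/h).
#' @param K_aa Monod constant for the required amino acid (uM).
#' @param rho amino acid released per 1e9 new partner-feeding cells per ml
#'   (uM).
#' @param rho_leak basal amino-acid leakage (uM per h per 1e9 cells/ml).
#' @param q_aa amino acid consumed per 1e9 new auxotroph cells per ml (uM).
#' @param C carrying capacity (cells/ml).
#' @param mode `"bacteriostatic"` or `"bactericidal"`.
#' @param kappa pharmacodynamic Hill exponent.
#' @param m0 baseline (ancestral) strain MIC (ug/ml).
#' @param delta_max maximal kill rate (1/h; bactericidal mode only).
#' @param mu_res per-division resistance step probability.
#' @param lambda MIC multiplier per resistance level (> 1).
#' @param L maximum resistance level.
#' @param mu_rev named numeric, per-division reversion (prototrophy
#'   restoration) probability per strain.
#' @param cost_rev relative growth-rate cost of prototrophy (amino-acid
#'   synthesis burden): prototroph classes grow at `r * (1 - cost_rev)`.
#'   Without a cost, reversion would sweep cocultures even in the absence
#'   of antibiotics and the cross-feeding mutualism could never persist;
#'   the cost makes reversion favourable only when the partner-provided
#'   amino-acid supply deteriorates under stress.
#' @param alpha OD600 per 1e9 cells/ml.
#' @param sigma multiplicative lognormal OD measurement noise (sdlog).
#' @param dt integration step (h).
#' @param batch_h batch duration (h).
#' @param dilution serial-transfer dilution factor.
#' @param supplement_uM amino-acid supplement in monoculture medium (uM).
#' @param pool0_coculture free amino acid carried over with the coculture
#'   inoculum (uM).
#' @param od_inoculum OD600 of each freshly inoculated culture.
#' @return Object of class `"sim_params"` (named list, plus the genotype
#'   class table in `$classes`).
#' @seealso [default_sim_params()], [run_batch()], [run_experiment()]
#' @export
sim_params <- function(r = c(TRP = 0.45, TYR = 0.45),
                       K_aa = 10,
                       rho = 20,
                       rho_leak = 0.3,
                       q_aa = 5,
                       C = 1e9,
                       mode = c("bacteriostatic", "bactericidal"),
                       kappa = 2,
                       m0 = 2.5,
                       delta_max = 0.5,
                       mu_res = 2e-6,
                       lambda = 2,
                       L = 8L,
                       mu_rev = c(TRP = 0, TYR = 2e-7),
                       cost_rev = 0.25,
                       alpha = 1,
                       sigma = 0.05,
                       dt = 0.1,
                       batch_h = 72,
                       dilution = 1 / 25,
                       supplement_uM = 100,
                       pool0_coculture = 2,
                       od_inoculum = 0.004) {
  mode <- match.arg(mode)
  r <- r[STRAINS]
  mu_rev <- mu_rev[STRAINS]
  stopifnot(
    all(r > 0), K_aa > 0, rho >= 0, rho_leak >= 0, q_aa >= 0, C > 0,
    kappa > 0, m0 > 0, delta_max >= 0,
    mu_res >= 0, mu_res <= 1e-4, lambda > 1, L >= 1,
    all(mu_rev >= 0), all(mu_rev <= 1e-4),
    cost_rev >= 0, cost_rev < 1,
    alpha > 0, sigma >= 0, dt > 0, batch_h > 0,
    dilution > 0, dilution < 1, supplement_uM >= 0,
    pool0_coculture >= 0, od_inoculum > 0
  )
  L <- as.integer(L)
  classes <- expand.grid(proto = c(FALSE, TRUE), level = 0:L,
                         strain = STRAINS, stringsAsFactors = FALSE)
  classes <- classes[c("strain", "level", "proto")]
  structure(list(r = r, K_aa = K_aa, rho = rho, rho_leak = rho_leak,
                 q_aa = q_aa, C = C, mode = mode, kappa = kappa, m0 = m0,
                 delta_max = delta_max, mu_res = mu_res, lambda = lambda,
                 L = L, mu_rev = mu_rev, cost_rev = cost_rev,
                 alpha = alpha, sigma = sigma,
                 dt = dt, batch_h = batch_h, dilution = dilution,
                 supplement_uM = supplement_uM,
                 pool0_coculture = pool0_coculture,
                 od_inoculum = od_inoculum, classes = classes),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Cross-feeding simulator parameters (%s mode)\n", x$mode))
  cat(sprintf("  r = %s /h, K_aa = %g uM, C = %.3g cells/ml\n",
              paste(sprintf("%s %.2f", names(x$r), x$r), collapse = ", "),
              x$K_aa, x$C))
  cat(sprintf("  rho = %g, leak = %g, q = %g uM per 1e9 cells/ml\n",
              x$rho, x$rho_leak, x$q_aa))
  cat(sprintf("  m0 = %g ug/ml, kappa = %g, delta_max = %g /h, lambda = %g, L = %d\n",
              x$m0, x$kappa, x$delta_max, x$lambda, x$L))
  cat(sprintf("  mu_res = %.2g, mu_rev = %s, cost_rev = %g\n", x$mu_res,
              paste(sprintf("%s %.2g", names(x$mu_rev), x$mu_rev),
                    collapse = ", "), x$cost_rev))
  cat(sprintf("  dt = %g h, batch = %g h, dilution = 1/%d, sigma = %g\n",
              x$dt, x$batch_h, round(1 / x$dilution), x$sigma))
  invisible(x)
}

#' Load the frozen default simulator parameters
#'
#' Reads `inst/extdata/sim-params-default.yaml`, the single calibrated
#' parameter file used for all direction-of-effect checks, optionally
#' overriding fields.
#'
#' @param ... overrides passed to [sim_params()] (e.g. `mode`, `m0`).
#' @return A `"sim_params"` object.
#' @export
default_sim_params <- function(...) {
  path <- system.file("extdata", "sim-params-default.yaml",
                      package = "muevolab", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  num <- setdiff(names(y), c("mode", "r", "mu_rev"))
  y[num] <- lapply(y[num], as.numeric)
  args <- list(
    r = unlist(y$r), K_aa = y$K_aa, rho = y$rho, rho_leak = y$rho_leak,
    q_aa = y$q_aa, C = y$C, mode = y$mode, kappa = y$kappa, m0 = y$m0,
    delta_max = y$delta_max, mu_res = y$mu_res, lambda = y$lambda, L = y$L,
    mu_rev = unlist(y$mu_rev), cost_rev = y$cost_rev,
    alpha = y$alpha, sigma = y$sigma, dt = y$dt,
    batch_h = y$batch_h, dilution = y$dilution,
    supplement_uM = y$supplement_uM, pool0_coculture = y$pool0_coculture,
    od_inoculum = y$od_inoculum
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(sim_params, args)
}
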