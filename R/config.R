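#' Run configuration
#'
#' Bundles the experiment-wide constants: number of serial transfers, the OD
#' death threshold, the sub-MIC threshold zone, the transfer dilution factor,
#' the amino-acid supplement concentration and the permutation count for the
#' cluster-composition test.
#'
#' Defaults follow the bench protocol: 15 transfers of 72 h each, a culture is
#' scored dead when its OD600 falls below 0.01, the sub-MIC zone is
#' OD600 0.05 +/- 0.005, transfers dilute 40 ul into 960 ul fresh medium
#' (1/25), monocultures are supplemented with 100 uM of each amino acid, and
#' the composition test uses 1e6 permutations.
#'
#' @param random_seed integer; master seed from which all operation-level
#'   seeds are derived (see [child_seed()]).
#' @param n_transfers integer; number of serial transfers after the initial
#'   inoculation (transfers are indexed `0:n_transfers`).
#' @param death_threshold OD600 below which a lineage is scored dead.
#' @param zone_center,zone_halfwidth centre and half-width (OD600) of the
#'   sub-MIC threshold zone.
#' @param dilution_factor fraction of culture carried over at each transfer.
#' @param supplement_conc amino-acid supplement concentration (uM).
#' @param n_permutations Monte-Carlo permutations for [composition_test()].
#' @return An object of class `"run_config"` (a named list).
#' @examples
#' cfg <- run_config(random_seed = 1)
#' cfg$n_transfers
#' @export
run_config <- function(random_seed = 1L,
                       n_transfers = 15L,
                       death_threshold = 0.01,
                       zone_center = 0.05,
                       zone_halfwidth = 0.005,
                       dilution_factor = 1 / 25,
                       supplement_conc = 100,
                       n_permutations = 1e6) {
  cfg <- list(
    random_seed = as.integer(random_seed),
    n_transfers = as.integer(n_transfers),
    death_threshold = death_threshold,
    zone_center = zone_center,
    zone_halfwidth = zone_halfwidth,
    dilution_factor = dilution_factor,
    supplement_conc = supplement_conc,
    n_permutations = n_permutations
  )
  stopifnot(
    cfg$n_transfers >= 1L,
    cfg$death_threshold > 0,
    cfg$zone_center > 0,
    cfg$zone_halfwidth > 0,
    cfg$zone_halfwidth < cfg$zone_center,
    cfg$dilution_factor > 0, cfg$dilution_factor < 1,
    cfg$supplement_conc > 0,
    cfg$n_permutations >= 1
  )
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  transfers           : 0..%d\n", x$n_transfers))
  cat(sprintf("  death threshold     : OD %.3g\n", x$death_threshold))
  cat(sprintf("  sub-MIC zone        : OD %.3g +/- %.3g\n",
              x$zone_center, x$zone_halfwidth))
  cat(sprintf("  transfer dilution   : 1/%d\n", round(1 / x$dilution_factor)))
  cat(sprintf("  supplement          : %g uM each amino acid\n",
              x$supplement_conc))
  cat(sprintf("  permutations        : %g\n", x$n_permutations))
  cat(sprintf("  master seed         : %d\n", x$random_seed))
  invisible(x)
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus a sequence of labels (operation
#' name, lineage id, ...) to a 31-bit integer seed, so every stochastic
#' operation has its own reproducible stream and results do not depend on the
#' order in which operations run.
#'
#' @param seed integer master seed.
#' @param ... character or numeric labels identifying the operation.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1, "simulate", "CO", "KAN")
#' @export
child_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}
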