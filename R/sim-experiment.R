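#' Simulate the full serial-transfer evolution experiment
#'
#' Runs every replicate of an [build_design()] design through the antibiotic
#' ramp: inoculation, 72-h batches at the scheduled concentration, 1/25
#' dilution into fresh medium between transfers. A lineage is scored dead at
#' the first transfer whose measured OD600 falls below `death_threshold`
#' (strictly below) and is not propagated further; no OD records are emitted
#' after death.
#'
#' @param design `"experiment_design"` data.frame (or a subset of one).
#' @param ramps named list of `"ramp_schedule"` objects, one per antibiotic
#'   present in `design` (antibiotic `"NONE"` gets an all-zero schedule
#'   automatically).
#' @param params `"sim_params"`; per-antibiotic `mode` and baseline MIC `m0`
#'   are taken from `modes`/`m0_by_ab` when supplied.
#' @param seed master seed; each treatment cell derives a child seed.
#' @param deterministic logical; expected mutation counts, noiseless OD.
#' @param death_threshold OD600 death threshold.
#' @param modes optional named character vector antibiotic -> mode,
#'   defaulting to the [antibiotic_panel()] assignment.
#' @param m0_by_ab optional named numeric antibiotic -> ancestral MIC
#'   (ug/ml); default `2 * sub_mic` of each supplied ramp.
#' @return List with `transfers` (a validated `"transfer"` table covering
#'   all replicates) and `final` (per-replicate terminal [
#'   genotype_frequencies()] with `lineage_id`, taken at the last transfer a
#'   lineage was propagated).
#' @export
run_experiment <- function(design, ramps, params, seed = 1L,
                           deterministic = FALSE, death_threshold = 0.01,
                           modes = NULL, m0_by_ab = NULL) {
  if (inherits(ramps, "ramp_schedule")) {
    ramps <- setNames(list(ramps), unique(design$antibiotic))
  }
  if (is.null(modes)) {
    panel <- antibiotic_panel()
    modes <- setNames(panel$mode, panel$antibiotic)
  }
  cells <- unique(design[c("culture_type", "antibiotic")])
  transfer_rows <- list()
  final_rows <- list()

  for (k in seq_len(nrow(cells))) {
    ct <- cells$culture_type[k]
    ab <- cells$antibiotic[k]
    ids <- design$lineage_id[design$culture_type == ct &
                               design$antibiotic == ab]
    n_rep <- length(ids)

    if (ab == "NONE") {
      n_tr <- if (length(ramps) > 0) {
        length(ramps[[1]]$conc_by_transfer) - 1L
      } else 15L
      sched <- rep(0, n_tr + 1L)
    } else {
      if (is.null(ramps[[ab]])) {
        stop("no ramp schedule supplied for antibiotic ", ab, call. = FALSE)
      }
      sched <- ramps[[ab]]$conc_by_transfer
    }
    n_transfers <- length(sched) - 1L

    p <- params
    if (ab != "NONE") {
      if (!is.null(modes) && ab %in% names(modes)) p$mode <- modes[[ab]]
      p$m0 <- if (!is.null(m0_by_ab) && ab %in% names(m0_by_ab)) {
        m0_by_ab[[ab]]
      } else 2 * ramps[[ab]]$sub_mic
    }

    state <- init_culture(p, ct, n_rep = n_rep)
    active <- seq_len(n_rep)
    od_rec <- matrix(NA_real_, n_transfers + 1L, n_rep)
    alive_rec <- matrix(NA, n_transfers + 1L, n_rep)
    last_state <- vector("list", n_rep)  # terminal state per replicate
    supplement <- if (state$supplemented) rep(p$supplement_uM, 2) else c(0, 0)

    for (t in 0:n_transfers) {
      if (length(active) == 0) break
      sub <- state
      sub$counts <- state$counts[, active, drop = FALSE]
      sub$pools <- state$pools[, active, drop = FALSE]
      res <- run_batch(sub, p, conc = sched[t + 1L],
                       seed = child_seed(seed, "experiment", ct, ab, t),
                       deterministic = deterministic)
      state$counts[, active] <- res$state$counts
      state$pools[, active] <- res$state$pools
      od_rec[t + 1L, active] <- res$od
      dead <- res$od < death_threshold
      alive_rec[t + 1L, active] <- !dead
      for (j in active) {
        st_j <- state
        st_j$counts <- state$counts[, j, drop = FALSE]
        st_j$pools <- state$pools[, j, drop = FALSE]
        last_state[[j]] <- st_j
      }
      active <- active[!dead]
      if (t < n_transfers && length(active) > 0) {
        state$counts[, active] <- state$counts[, active, drop = FALSE] *
          p$dilution
        state$pools[, active] <- supplement +
          state$pools[, active, drop = FALSE] * p$dilution
      }
    }

    for (j in seq_len(n_rep)) {
      rec <- which(!is.na(od_rec[, j]))
      transfer_rows[[length(transfer_rows) + 1L]] <- data.frame(
        lineage_id = ids[j], culture_type = ct, antibiotic = ab,
        transfer = rec - 1L, od600 = od_rec[rec, j],
        concentration = sched[rec], alive = alive_rec[rec, j],
        stringsAsFactors = FALSE
      )
      fr <- genotype_frequencies(last_state[[j]])
      fr$rep <- NULL
      fr <- cbind(lineage_id = ids[j], culture_type = ct, antibiotic = ab,
                  fr, stringsAsFactors = FALSE)
      fr$alive <- alive_rec[max(rec), j]
      final_rows[[length(final_rows) + 1L]] <- fr
    }
  }

  transfers <- do.call(rbind, transfer_rows)
  rownames(transfers) <- NULL
  final <- do.call(rbind, final_rows)
  rownames(final) <- NULL
  list(transfers = validate_table(transfers, "transfer"), final = final)
}
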