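#' Construct a population state
#'
#' A population state holds, for `n_rep` parallel replicate cultures, the
#' cell count of every genotype class (strain x resistance level x
#' prototrophy flag) and the free amino-acid pools (Trp, Tyr; uM). Counts are
#' cells in the 1-ml culture volume.
#'
#' @param params `"sim_params"` object.
#' @param n_trp,n_tyr initial cells of the tryptophan- and
#'   tyrosine-auxotrophic strain (level 0).
#' @param supplemented logical; if `TRUE` the medium carries
#'   `params$supplement_uM` of each amino acid (renewed at every transfer).
#' @param pools optional length-2 numeric `(Trp, Tyr)` initial free pools
#'   (uM); defaults to the supplement for supplemented media, else 0.
#' @param proto logical; start cells as prototrophs instead of auxotrophs.
#' @param n_rep number of replicate cultures held in the state.
#' @return Object of class `"population_state"`.
#' @export
population_state <- function(params, n_trp = 0, n_tyr = 0,
                             supplemented = FALSE, pools = NULL,
                             proto = FALSE, n_rep = 1L) {
  cl <- params$classes
  n_class <- nrow(cl)
  counts <- matrix(0, n_class, n_rep)
  i_trp <- which(cl$strain == "TRP" & cl$level == 0 & cl$proto == proto)
  i_tyr <- which(cl$strain == "TYR" & cl$level == 0 & cl$proto == proto)
  counts[i_trp, ] <- n_trp
  counts[i_tyr, ] <- n_tyr
  if (is.null(pools)) {
    pools <- if (supplemented) rep(params$supplement_uM, 2) else c(0, 0)
  }
  pool_mat <- matrix(pools, 2, n_rep)
  rownames(pool_mat) <- c("Trp", "Tyr")
  structure(list(counts = counts, pools = pool_mat,
                 supplemented = supplemented, classes = cl),
            class = "population_state")
}

#' Initial state for a treatment-cell inoculation
#'
#' Monocultures inoculate 40 ul of an OD-adjusted preculture into 1 ml
#' (supplemented medium); cocultures inoculate 20 ul of each auxotroph
#' preculture (unsupplemented medium, small carried-over pools).
#'
#' @param params `"sim_params"` object.
#' @param culture_type one of [CULTURE_TYPES].
#' @param n_rep replicate cultures.
#' @return A `"population_state"`.
#' @export
init_culture <- function(params, culture_type, n_rep = 1L) {
  n0 <- params$od_inoculum / params$alpha * 1e9
  switch(culture_type,
    TRP_mono = population_state(params, n_trp = n0, supplemented = TRUE,
                                n_rep = n_rep),
    TYR_mono = population_state(params, n_tyr = n0, supplemented = TRUE,
                                n_rep = n_rep),
    CO = population_state(params, n_trp = n0 / 2, n_tyr = n0 / 2,
                          supplemented = FALSE,
                          pools = rep(params$pool0_coculture, 2),
                          n_rep = n_rep),
    stop("unknown culture type: ", culture_type, call. = FALSE)
  )
}

#' @export
print.population_state <- function(x, ...) {
  n_rep <- ncol(x$counts)
  tot <- colSums(x$counts)
  cat(sprintf("Population state: %d replicate(s), %s medium\n", n_rep,
              if (x$supplemented) "supplemented" else "unsupplemented"))
  cat(sprintf("  total cells/ml: %s\n",
              paste(signif(utils::head(tot, 5), 3), collapse = ", ")))
  cat(sprintf("  pools (Trp, Tyr) uM: %s\n",
              paste(signif(utils::head(c(x$pools[, 1]), 2), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate one 72-h growth batch
#'
#' Integrates the within-batch consumer--resource dynamics on a fixed time
#' grid (`params$dt`), for all replicates held in `state`, at a constant
#' antibiotic concentration. Mutation counts per step are Poisson draws from
#' the expected number of mutant divisions (tau-leap style); in deterministic
#' mode expected counts are used and OD noise is off.
#'
#' @param state `"population_state"`.
#' @param params `"sim_params"`.
#' @param conc antibiotic concentration (ug/ml), constant over the batch.
#' @param seed optional integer seed (set before any draws).
#' @param deterministic logical; use expected mutation counts and noiseless
#'   OD.
#' @param record_times optional numeric times (h) at which per-strain cell
#'   counts are recorded (must be multiples of `params$dt`).
#' @return List: `state` (end-of-batch `"population_state"`), `od` (length
#'   `n_rep`, with measurement noise unless deterministic), `od_expected`,
#'   and if `record_times` is given, `traj` — a data.frame with `time_h`,
#'   `strain`, `rep` and `cells` columns.
#' @export
run_batch <- function(state, params, conc, seed = NULL,
                      deterministic = FALSE, record_times = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(conc) || conc < 0) stop("conc must be finite and >= 0", call. = FALSE)
  cl <- state$classes
  counts <- state$counts
  pools <- state$pools
  n_class <- nrow(cl)
  n_rep <- ncol(counts)
  dt <- params$dt
  n_steps <- round(params$batch_h / dt)

  mic <- params$m0 * params$lambda^cl$level
  frac <- (conc / mic)^params$kappa
  g_ab <- 1 / (1 + frac)
  kill <- if (params$mode == "bactericidal") {
    params$delta_max * frac / (1 + frac)
  } else rep(0, n_class)
  rg <- params$r[cl$strain] * g_ab               # per-class rate ceiling
  rg[cl$proto] <- rg[cl$proto] * (1 - params$cost_rev)  # synthesis burden
  is_trp <- cl$strain == "TRP"
  trp_aux <- which(is_trp & !cl$proto)
  tyr_aux <- which(!is_trp & !cl$proto)
  trp_rows <- which(is_trp)
  tyr_rows <- which(!is_trp)
  res_from <- which(cl$level < params$L)
  res_to <- match(paste(cl$strain[res_from], cl$level[res_from] + 1L,
                        cl$proto[res_from]),
                  paste(cl$strain, cl$level, cl$proto))
  rev_from <- which(!cl$proto)
  rev_to <- match(paste(cl$strain[rev_from], cl$level[rev_from], TRUE),
                  paste(cl$strain, cl$level, cl$proto))
  mu_rev_class <- params$mu_rev[cl$strain[rev_from]]

  record <- !is.null(record_times)
  if (record) {
    rec_steps <- round(record_times / dt)
    if (any(abs(rec_steps * dt - record_times) > 1e-9)) {
      stop("record_times must be multiples of params$dt", call. = FALSE)
    }
    traj <- array(NA_real_, c(length(record_times), 2, n_rep))
    .snap <- function(slot) {
      traj[slot, 1, ] <<- colSums(counts[trp_rows, , drop = FALSE])
      traj[slot, 2, ] <<- colSums(counts[tyr_rows, , drop = FALSE])
    }
    if (any(rec_steps == 0)) .snap(which(rec_steps == 0))
  }

  gaa_mat <- matrix(1, n_class, n_rep)
  for (step in seq_len(n_steps)) {
    ntot <- .colSums(counts, n_class, n_rep)
    logi <- pmax(0, 1 - ntot / params$C)
    g_trp <- pools[1, ] / (params$K_aa + pools[1, ])
    g_tyr <- pools[2, ] / (params$K_aa + pools[2, ])
    gaa_mat[trp_aux, ] <- rep(g_trp, each = length(trp_aux))
    gaa_mat[tyr_aux, ] <- rep(g_tyr, each = length(tyr_aux))
    births <- counts * (rg * gaa_mat) *
      rep(logi * dt, each = n_class)
    counts <- counts + births - counts * (kill * dt)

    b_trp <- .colSums(births[trp_rows, , drop = FALSE],
                      length(trp_rows), n_rep) / 1e9
    b_tyr <- .colSums(births[tyr_rows, , drop = FALSE],
                      length(tyr_rows), n_rep) / 1e9
    b_trp_aux <- .colSums(births[trp_aux, , drop = FALSE],
                          length(trp_aux), n_rep) / 1e9
    b_tyr_aux <- .colSums(births[tyr_aux, , drop = FALSE],
                          length(tyr_aux), n_rep) / 1e9
    # basal leakage scales with the pharmacodynamic factor: antibiotic-
    # suppressed cells synthesise (and so release) fewer amino acids
    leak_trp <- .colSums(counts[tyr_rows, , drop = FALSE] * g_ab[tyr_rows],
                         length(tyr_rows), n_rep) / 1e9 * params$rho_leak * dt
    leak_tyr <- .colSums(counts[trp_rows, , drop = FALSE] * g_ab[trp_rows],
                         length(trp_rows), n_rep) / 1e9 * params$rho_leak * dt
    # TYR-strain cells feed the Trp pool, TRP-strain cells the Tyr pool
    pools[1, ] <- pmax(0, pools[1, ] + params$rho * b_tyr + leak_trp -
                         params$q_aa * b_trp_aux)
    pools[2, ] <- pmax(0, pools[2, ] + params$rho * b_trp + leak_tyr -
                         params$q_aa * b_tyr_aux)

    if (params$mu_res > 0) {
      m_exp <- births[res_from, , drop = FALSE] * params$mu_res
      m <- if (deterministic) m_exp else {
        matrix(rpois(length(m_exp), m_exp), nrow(m_exp))
      }
      m <- pmin(m, counts[res_from, , drop = FALSE])
      counts[res_from, ] <- counts[res_from, , drop = FALSE] - m
      counts[res_to, ] <- counts[res_to, , drop = FALSE] + m
    }
    if (any(params$mu_rev > 0)) {
      v_exp <- births[rev_from, , drop = FALSE] * mu_rev_class
      v <- if (deterministic) v_exp else {
        matrix(rpois(length(v_exp), v_exp), nrow(v_exp))
      }
      v <- pmin(v, counts[rev_from, , drop = FALSE])
      counts[rev_from, ] <- counts[rev_from, , drop = FALSE] - v
      counts[rev_to, ] <- counts[rev_to, , drop = FALSE] + v
    }
    counts[counts < 0] <- 0
    if (!all(is.finite(counts))) {
      stop(sprintf("non-finite state at step %d (t = %.1f h)", step,
                   step * dt), call. = FALSE)
    }
    if (record && any(rec_steps == step)) .snap(which(rec_steps == step))
  }

  od_expected <- params$alpha * .colSums(counts, n_class, n_rep) / 1e9
  od <- if (deterministic || params$sigma == 0) od_expected else {
    od_expected * rlnorm(n_rep, 0, params$sigma)
  }
  state$counts <- counts
  state$pools <- pools
  out <- list(state = state, od = od, od_expected = od_expected)
  if (record) {
    out$traj <- data.frame(
      time_h = rep(record_times, times = 2 * n_rep),
      strain = rep(rep(STRAINS, each = length(record_times)), times = n_rep),
      rep = rep(seq_len(n_rep), each = 2 * length(record_times)),
      cells = c(aperm(traj, c(1, 2, 3)))
    )
  }
  out
}

#' Genotype frequencies of a population state
#'
#' Per replicate and strain: total cells, fraction of prototrophic
#' (reverted) cells and mean resistance level.
#'
#' @param state `"population_state"`.
#' @return data.frame with columns `rep`, `strain`, `cells`,
#'   `frac_prototroph`, `mean_level`.
#' @export
genotype_frequencies <- function(state) {
  cl <- state$classes
  out <- do.call(rbind, lapply(seq_len(ncol(state$counts)), function(j) {
    do.call(rbind, lapply(STRAINS, function(s) {
      rows <- cl$strain == s
      n <- state$counts[rows, j]
      tot <- sum(n)
      data.frame(
        rep = j, strain = s, cells = tot,
        frac_prototroph = if (tot > 0) sum(n[cl$proto[rows]]) / tot else NA_real_,
        mean_level = if (tot > 0) sum(n * cl$level[rows]) / tot else NA_real_
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
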