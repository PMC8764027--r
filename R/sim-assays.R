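#' Simulate a MIC dose--response plate
#'
#' Grows replicate cultures of a strain with baseline MIC `mic0` for one
#' 72-h batch at each concentration of an increasing grid and reports the
#' end-of-batch OD600 (with measurement noise unless deterministic).
#' Mutation is off: the assay probes the planted phenotype.
#'
#' @param mic0 strain MIC (ug/ml) planted in the assay.
#' @param params `"sim_params"`.
#' @param grid strictly increasing concentration grid (ug/ml); must include
#'   at least 2 concentrations.
#' @param n_replicates replicate wells per concentration.
#' @param culture_type label stored in the table (the assay itself grows a
#'   supplemented monoculture of the matching strain; `CO` uses both
#'   strains unsupplemented).
#' @param seed optional integer seed.
#' @param deterministic logical.
#' @return A validated `"mic"` table.
#' @export
gen_mic_assay <- function(mic0, params, grid, n_replicates = 3L,
                          culture_type = "TRP_mono", seed = NULL,
                          deterministic = FALSE) {
  if (length(grid) == 0) stop("empty concentration grid", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  p$m0 <- mic0
  p$mu_res <- 0
  p$mu_rev <- c(TRP = 0, TYR = 0)
  rows <- lapply(seq_along(grid), function(i) {
    st <- init_culture(p, culture_type, n_rep = n_replicates)
    res <- run_batch(st, p, conc = grid[i], deterministic = deterministic)
    data.frame(replicate_id = sprintf("w%d", seq_len(n_replicates)),
               concentration = grid[i], od600 = res$od,
               supplemented = culture_type != "CO",
               culture_type = culture_type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replicate_id, out$concentration), ]
  rownames(out) <- NULL
  validate_table(out, "mic")
}

#' Simulate a colony phenotype screen
#'
#' Draws `n_colonies` colonies multinomially from population genotype
#' frequencies and emits their growth flags on the four selective media
#' (MMAB, MMAB+Trp, MMAB+Tyr, LB). Genotypes whose population frequency is
#' below the screen's detection floor (`lower_limit / plated_density`) are
#' never detected: their frequency is zeroed before drawing.
#'
#' @param freqs named numeric over `c("PROTOTROPH", "TRP_AUX", "TYR_AUX")`,
#'   summing to 1.
#' @param n_colonies colonies picked (>= 1).
#' @param population_id label for the screened population.
#' @param lower_limit,plated_density detection limits (CFU/ml); defaults
#'   2.5e4 and 2.5e6.
#' @param seed optional integer seed.
#' @return A validated `"colony"` table.
#' @export
gen_colony_screen <- function(freqs, n_colonies, population_id = "P1",
                              lower_limit = 2.5e4, plated_density = 2.5e6,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- c("PROTOTROPH", "TRP_AUX", "TYR_AUX")
  if (is.null(names(freqs)) || !all(names(freqs) %in% genotypes)) {
    stop("freqs must be named over PROTOTROPH/TRP_AUX/TYR_AUX", call. = FALSE)
  }
  f <- setNames(numeric(3), genotypes)
  f[names(freqs)] <- freqs
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop("freqs must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_colonies < 1) stop("n_colonies must be >= 1", call. = FALSE)
  floor_freq <- lower_limit / plated_density
  f[f < floor_freq] <- 0
  if (sum(f) == 0) stop("all genotypes below the detection limit", call. = FALSE)
  f <- f / sum(f)
  draw <- rmultinom(1, n_colonies, f)[, 1]
  flags <- rbind(
    PROTOTROPH = c(TRUE, TRUE, TRUE, TRUE),
    TRP_AUX = c(FALSE, TRUE, FALSE, TRUE),
    TYR_AUX = c(FALSE, FALSE, TRUE, TRUE)
  )
  colnames(flags) <- SCREEN_MEDIA
  geno <- rep(genotypes, draw)
  geno <- sample(geno)  # randomize pick order
  out <- data.frame(
    population_id = population_id,
    colony_id = sprintf("%s_c%02d", population_id, seq_len(n_colonies)),
    mmab = flags[geno, "mmab"], mmab_trp = flags[geno, "mmab_trp"],
    mmab_tyr = flags[geno, "mmab_tyr"], lb = flags[geno, "lb"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_table(out, "colony")
}

#' Simulate CFU growth curves
#'
#' Runs one antibiotic-free 72-h batch and records per-strain CFU/ml at the
#' fixed sampling grid [TIME_GRID_H]. Counting noise emulates drop-plating
#' 15 ul of a dilution chosen to give a countable plate (expected count
#' <= 200 colonies): the observed count is Poisson and back-converted to
#' CFU/ml. Deterministic mode returns exact densities.
#'
#' @param params `"sim_params"`.
#' @param culture_type one of [CULTURE_TYPES].
#' @param supplemented logical; override the culture type's default medium
#'   (e.g. a supplemented coculture).
#' @param n_rep replicate cultures.
#' @param seed optional integer seed.
#' @param deterministic logical.
#' @return A validated `"growth"` table (monocultures contribute only their
#'   own strain's rows).
#' @export
gen_growth_curves <- function(params, culture_type, supplemented = NULL,
                              n_rep = 3L, seed = NULL,
                              deterministic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  params$mu_res <- 0                      # the assay probes the ancestral
  params$mu_rev <- c(TRP = 0, TYR = 0)    # phenotypes, not their mutants
  st <- init_culture(params, culture_type, n_rep = n_rep)
  if (!is.null(supplemented) && supplemented != st$supplemented) {
    st$supplemented <- supplemented
    base <- if (supplemented) rep(params$supplement_uM, 2) else c(0, 0)
    st$pools <- matrix(base, 2, n_rep, dimnames = list(c("Trp", "Tyr"), NULL))
  }
  res <- run_batch(st, params, conc = 0, deterministic = deterministic,
                   record_times = TIME_GRID_H)
  traj <- res$traj
  keep <- switch(culture_type,
                 TRP_mono = traj$strain == "TRP",
                 TYR_mono = traj$strain == "TYR",
                 CO = rep(TRUE, nrow(traj)))
  traj <- traj[keep, ]
  cfu <- traj$cells  # 1-ml culture: cells == CFU/ml
  if (!deterministic) {
    vol <- 0.015  # 15 ul plated
    expected <- cfu * vol
    dil <- pmax(0, ceiling(log10(pmax(expected, 1) / 200)))
    lam <- expected / 10^dil
    obs <- rpois(length(lam), lam)
    cfu <- obs * 10^dil / vol
  }
  out <- data.frame(
    replicate_id = sprintf("%s_r%d", culture_type, traj$rep),
    strain = traj$strain, time_h = traj$time_h, cfu_per_ml = cfu,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$replicate_id, out$strain, out$time_h), ]
  rownames(out) <- NULL
  validate_table(out, "growth")
}
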