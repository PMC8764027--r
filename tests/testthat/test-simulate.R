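p_base <- default_sim_params()

test_that("an unsupplemented auxotroph monoculture cannot grow", {
  p <- default_sim_params(mu_rev = c(TRP = 0, TYR = 0))
  st <- population_state(p, n_trp = 4e6, supplemented = FALSE,
                         pools = c(0, 0))
  res <- run_batch(st, p, conc = 0, deterministic = TRUE)
  expect_lte(sum(res$state$counts), 4e6 * (1 + 1e-9))
})

test_that("a prototroph batch matches an independent fine-grid ODE solution", {
  skip_if_not_installed("deSolve")
  p <- default_sim_params(mu_res = 0, mu_rev = c(TRP = 0, TYR = 0),
                          cost_rev = 0, sigma = 0)
  n0 <- 4e6
  st <- population_state(p, n_trp = n0, supplemented = TRUE, proto = TRUE)
  res <- run_batch(st, p, conc = 0, deterministic = TRUE)
  # oracle: logistic ODE dN/dt = r N (1 - N/C) integrated by deSolve
  sol <- deSolve::ode(y = c(N = n0), times = c(0, 72),
                      func = function(t, y, pp) {
                        list(pp$r * y[1] * (1 - y[1] / pp$C))
                      },
                      parms = list(r = unname(p$r["TRP"]), C = p$C),
                      method = "ode45")
  n72 <- sol[nrow(sol), "N"]
  expect_equal(sum(res$state$counts), unname(n72), tolerance = 0.01)
})

test_that("saturating bacteriostatic concentrations freeze the population", {
  p <- default_sim_params(mu_res = 0, mu_rev = c(TRP = 0, TYR = 0))
  st <- population_state(p, n_trp = 4e6, supplemented = TRUE)
  res <- run_batch(st, p, conc = 1e9, deterministic = TRUE)
  expect_equal(sum(res$state$counts), 4e6, tolerance = 1e-6)
})

test_that("deterministic bacteriostatic density is non-increasing in concentration", {
  p <- default_sim_params(mu_res = 0, mu_rev = c(TRP = 0, TYR = 0))
  ods <- vapply(c(0, 1, 2.5, 5, 10, 50), function(conc) {
    st <- population_state(p, n_trp = 4e6, supplemented = TRUE)
    run_batch(st, p, conc = conc, deterministic = TRUE)$od
  }, 0)
  expect_true(all(diff(ods) <= 1e-12))
})

test_that("amino-acid pools never go negative and respond to supply terms", {
  p <- default_sim_params()
  for (s in 1:5) {
    st <- init_culture(p, "CO")
    res <- run_batch(st, p, conc = 0, seed = s)
    expect_true(all(res$state$pools >= 0))
    expect_true(all(res$state$counts >= 0))
  }
  # production: a growing coculture feeds both pools above carry-over
  st <- init_culture(p, "CO")
  res <- run_batch(st, p, conc = 0, deterministic = TRUE)
  expect_true(all(res$state$pools > p$pool0_coculture))
})

test_that("halving the integration step barely changes deterministic densities", {
  p1 <- default_sim_params(mu_rev = c(TRP = 0, TYR = 0), mu_res = 0)
  p2 <- default_sim_params(mu_rev = c(TRP = 0, TYR = 0), mu_res = 0, dt = 0.05)
  for (ct in c("TRP_mono", "CO")) {
    od1 <- run_batch(init_culture(p1, ct), p1, 0, deterministic = TRUE)$od
    od2 <- run_batch(init_culture(p2, ct), p2, 0, deterministic = TRUE)$od
    expect_equal(od1, od2, tolerance = 0.005)
  }
})

test_that("a zero-antibiotic experiment keeps every replicate alive", {
  d <- build_design(n_lineages = 2, n_technical = 1,
                    culture_types = c("TRP_mono", "CO"),
                    antibiotics = "NONE")
  res <- run_experiment(d, panel_ramps(), p_base, seed = 1,
                        deterministic = TRUE)
  ev <- call_events(res$transfers)
  expect_false(any(ev$event))
  expect_true(all(ev$time == 15))
  expect_equal(nrow(res$transfers), 4 * 16)
})

test_that("dead lineages stop being recorded after their death transfer", {
  d <- build_design(n_lineages = 3, n_technical = 1, culture_types = "CO",
                    antibiotics = "KAN")
  res <- run_experiment(d, panel_ramps(), p_base, seed = 3)
  ev <- call_events(res$transfers)
  expect_true(any(ev$event))  # bactericidal ramp kills cocultures
  for (i in which(ev$event)) {
    rows <- res$transfers[res$transfers$lineage_id == ev$lineage_id[i], ]
    expect_equal(max(rows$transfer), ev$time[i])
    expect_false(rows$alive[which.max(rows$transfer)])
  }
  # concentration column follows the kanamycin schedule
  kan <- panel_ramps()$KAN$conc_by_transfer
  expect_equal(res$transfers$concentration,
               unname(kan[res$transfers$transfer + 1]))
})

test_that("MIC assay plates recover a planted MIC in the deterministic limit", {
  p <- default_sim_params(sigma = 0)
  # closed form: OD72 < 0.01 once r*g_ab(c)*72 < log(0.01e9 / n0), ignoring
  # the logistic term (valid at N << C)
  m_true <- 4
  n0 <- p$od_inoculum / p$alpha * 1e9
  g_aa <- p$supplement_uM / (p$K_aa + p$supplement_uM)
  g_crit <- log(0.01 / p$alpha * 1e9 / n0) / (unname(p$r["TRP"]) * g_aa * 72)
  c_crit <- m_true * (1 / g_crit - 1)^(1 / p$kappa)
  grid <- seq(5, 40, by = 2.5)
  plate <- gen_mic_assay(m_true, p, grid, n_replicates = 1,
                         deterministic = TRUE)
  mic <- call_mic_all(plate)
  expect_false(mic$censored)
  expect_equal(mic$mic, grid[which(grid > c_crit)[1]])

  # extremes: no antibiotic ~ carrying capacity, gross excess ~ no growth
  plate0 <- gen_mic_assay(m_true, p, c(0, 100 * m_true), n_replicates = 1,
                          deterministic = TRUE)
  expect_equal(plate0$od600[plate0$concentration == 0],
               p$alpha * p$C / 1e9, tolerance = 0.02)
  expect_lt(plate0$od600[plate0$concentration == 100 * m_true], 0.01)
})

test_that("colony screens draw genotypes faithfully and honour detection limits", {
  pure_aux <- gen_colony_screen(c(TRP_AUX = 1), 20, seed = 1)
  calls <- classify_colonies(pure_aux)
  expect_true(all(calls$call == "TRP_AUXOTROPH"))
  expect_true(all(pure_aux$mmab_trp & pure_aux$lb))
  expect_false(any(pure_aux$mmab | pure_aux$mmab_tyr))

  pure_pro <- gen_colony_screen(c(PROTOTROPH = 1), 10, seed = 1)
  expect_true(all(as.matrix(pure_pro[SCREEN_MEDIA])))

  # planted 30% revertants: recovered fraction inside the binomial 99% CI
  scr <- gen_colony_screen(c(PROTOTROPH = 0.3, TYR_AUX = 0.7), 1000, seed = 42)
  n_rev <- sum(classify_colonies(scr)$call == "PROTOTROPH_REVERTANT")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(n_rev, ci[1])
  expect_lte(n_rev, ci[2])

  # frequencies below lower/plated density are never drawn
  scr2 <- gen_colony_screen(c(PROTOTROPH = 0.005, TYR_AUX = 0.995), 500,
                            seed = 7)
  expect_equal(sum(classify_colonies(scr2)$call == "PROTOTROPH_REVERTANT"), 0)

  expect_error(gen_colony_screen(c(PROTOTROPH = 0.5, TYR_AUX = 0.4), 10),
               "sum to 1")
})

test_that("growth curves start at the inoculum with small large-count noise", {
  g <- gen_growth_curves(p_base, "TRP_mono", n_rep = 1, deterministic = TRUE)
  n0 <- p_base$od_inoculum / p_base$alpha * 1e9
  expect_equal(g$cfu_per_ml[g$time_h == 0], n0)
  expect_setequal(unique(g$time_h), TIME_GRID_H)

  set.seed(11)
  gs <- gen_growth_curves(p_base, "TRP_mono", n_rep = 20, seed = 11)
  late <- merge(gs[gs$time_h == 72, ],
                g[g$time_h == 72, c("strain", "cfu_per_ml")],
                by = "strain")
  rel <- abs(late$cfu_per_ml.x - late$cfu_per_ml.y) / late$cfu_per_ml.y
  expect_lt(median(rel), 0.10)  # Poisson counting noise at ~200 colonies
})
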