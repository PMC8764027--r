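# Sub-MIC threshold-zone rules ------------------------------------------------

test_that("sub-MIC rules resolve the four canonical plate layouts", {
  # single fully contained concentration
  p1 <- make_mic_plate(c(1, 2, 4),
                       rbind(c(0.40, 0.048, 0.004),
                             c(0.35, 0.050, 0.003),
                             c(0.30, 0.052, 0.002)))
  r1 <- determine_sub_mic(p1)
  expect_equal(r1$sub_mic, 2)
  expect_equal(r1$rule, "full")

  # two fully contained concentrations: their mean
  p2 <- make_mic_plate(c(1, 2, 4, 8),
                       rbind(c(0.40, 0.048, 0.052, 0.004),
                             c(0.35, 0.050, 0.049, 0.003)))
  expect_equal(determine_sub_mic(p2)$sub_mic, 3)

  # partial overlap followed by a concentration with none inside: mean of two
  p3 <- make_mic_plate(c(2, 4, 8),
                       rbind(c(0.40, 0.046, 0.004),
                             c(0.35, 0.120, 0.003)))
  r3 <- determine_sub_mic(p3)
  expect_equal(r3$sub_mic, 6)
  expect_equal(r3$rule, "partial_mean")

  # partial overlap at the last measured concentration: that concentration
  p4 <- make_mic_plate(c(2, 4),
                       rbind(c(0.40, 0.052),
                             c(0.35, 0.200)))
  r4 <- determine_sub_mic(p4)
  expect_equal(r4$sub_mic, 4)
  expect_equal(r4$rule, "partial_last")
})

test_that("no zone intersection raises an informative error", {
  p <- make_mic_plate(c(1, 2, 4),
                      rbind(c(0.40, 0.30, 0.004)))
  expect_error(determine_sub_mic(p), "no sub-MIC resolvable")
  expect_error(determine_sub_mic(p), "nearest OD")
})

test_that("sub-MIC is invariant to replicate order and higher dead concentrations", {
  p <- make_mic_plate(c(1, 2, 4),
                      rbind(c(0.40, 0.048, 0.004),
                            c(0.35, 0.050, 0.003)))
  base <- determine_sub_mic(p)$sub_mic
  # swap the order of the replicate blocks
  swapped <- p[c(which(p$replicate_id == "r2"), which(p$replicate_id == "r1")), ]
  expect_equal(determine_sub_mic(swapped)$sub_mic, base)
  # append concentrations wholly above the zone after the resolved one
  p_ext <- make_mic_plate(c(1, 2, 4, 8, 16),
                          rbind(c(0.40, 0.048, 0.004, 0.002, 0.001),
                                c(0.35, 0.050, 0.003, 0.002, 0.001)))
  expect_equal(determine_sub_mic(p_ext)$sub_mic, base)
})

test_that("zone membership is inclusive at both endpoints", {
  p <- make_mic_plate(c(1, 2),
                      rbind(c(0.40, 0.045), c(0.35, 0.055)))
  expect_equal(determine_sub_mic(p)$sub_mic, 2)
})

# Ramp schedules ---------------------------------------------------------------

test_that("kanamycin and tetracycline ramps follow doubling-then-linear rules", {
  kan <- build_ramp(1.25, 50, antibiotic = "KAN")
  expect_equal(unname(kan$conc_by_transfer[1:2]), c(0, 0))
  expect_equal(unname(kan$conc_by_transfer[3:6]),
               c(0.15625, 0.3125, 0.625, 1.25))
  expect_equal(unname(kan$conc_by_transfer[16]), 55)
  expect_gte(kan$conc_by_transfer[16], 50)

  tet <- build_ramp(1.35, 15, antibiotic = "TET")
  expect_equal(unname(tet$conc_by_transfer[16]), 16.5)
  expect_gte(tet$conc_by_transfer[16], 15)
})

test_that("ramp schedules are monotone with an equal-increment linear phase", {
  for (s in c(0.75, 1.25, 3.25, 1.35)) {
    r <- build_ramp(s, 20 * s)
    conc <- r$conc_by_transfer
    expect_length(conc, 16)
    expect_true(all(diff(conc) >= 0))
    expect_equal(sum(conc == s), 1)             # sub-MIC hit exactly once
    expect_equal(unname(conc[3]), s / 8)        # doubling starts at s/8
    incs <- diff(conc[6:16])                    # linear phase
    expect_equal(max(incs) - min(incs), 0, tolerance = 1e-12)
  }
})

test_that("ramp scales linearly with (sub-MIC, working) and rejects bad input", {
  a <- build_ramp(1.25, 50)
  b <- build_ramp(1.25 * 4, 50 * 4)
  expect_equal(unname(b$conc_by_transfer), unname(a$conc_by_transfer) * 4)
  expect_error(build_ramp(8, 4), "below the working")
  expect_error(build_ramp(1, 50, n_transfers = 5), "doubling phase")
})

# Experiment design ------------------------------------------------------------

test_that("default design has 80 replicates per treatment cell", {
  d <- build_design()
  expect_equal(nrow(d), 960)
  cells <- table(d$culture_type, d$antibiotic)
  expect_true(all(cells == 80))
  expect_equal(dim(cells), c(3L, 4L))
  expect_equal(sum(d$culture_type == "CO" & d$antibiotic == "KAN"), 80)
  # monocultures supplemented, cocultures not
  expect_true(all(d$supplemented[d$culture_type != "CO"]))
  expect_false(any(d$supplemented[d$culture_type == "CO"]))
  expect_equal(anyDuplicated(d$lineage_id), 0L)
})

test_that("design scales down to a single replicate per cell", {
  d <- build_design(n_lineages = 1, n_technical = 1)
  expect_equal(nrow(d), 12)
  expect_true(all(table(d$culture_type, d$antibiotic) == 1))
})
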