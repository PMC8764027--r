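#' Classify colony plate patterns into phenotypes
#'
#' A colony's growth pattern on the four selective media determines its
#' phenotype: growth on all four plates means a prototrophic revertant;
#' growth only on MMAB+Trp and LB means a tryptophan auxotroph; growth only
#' on MMAB+Tyr and LB a tyrosine auxotroph; any other pattern is ambiguous.
#' A colony that fails to grow on LB is nonviable and raises an error
#' (already enforced by the table schema).
#'
#' @param screen a `"colony"` table.
#' @return data.frame `population_id`, `colony_id`, `call` (one of
#'   `PROTOTROPH_REVERTANT`, `TRP_AUXOTROPH`, `TYR_AUXOTROPH`, `AMBIGUOUS`).
#' @examples
#' s <- data.frame(population_id = "P1", colony_id = "c1",
#'                 mmab = FALSE, mmab_trp = TRUE, mmab_tyr = FALSE, lb = TRUE)
#' classify_colonies(s)$call  # TRP_AUXOTROPH
#' @export
classify_colonies <- function(screen) {
  screen <- validate_table(screen, "colony")
  call <- rep("AMBIGUOUS", nrow(screen))
  call[screen$mmab & screen$mmab_trp & screen$mmab_tyr & screen$lb] <-
    "PROTOTROPH_REVERTANT"
  call[!screen$mmab & screen$mmab_trp & !screen$mmab_tyr & screen$lb] <-
    "TRP_AUXOTROPH"
  call[!screen$mmab & !screen$mmab_trp & screen$mmab_tyr & screen$lb] <-
    "TYR_AUXOTROPH"
  data.frame(population_id = screen$population_id,
             colony_id = screen$colony_id, call = call,
             stringsAsFactors = FALSE)
}

#' Population-level reversion table
#'
#' Aggregates phenotype calls over the populations of a treatment group into
#' auxotroph and revertant counts. Ambiguous colonies are excluded from the
#' denominator (their count is reported). When no revertant was detected the
#' proportion is not reported as 0 but flagged as below the screen's lower
#' detection limit.
#'
#' @param calls data.frame from [classify_colonies()].
#' @param group label stored in the result.
#' @param lower_limit lower detection limit (CFU/ml) used in the flag text.
#' @return List: `group`, `n_auxotroph`, `n_revertant`, `n_ambiguous`,
#'   `n_populations`, `proportion` (`NA` when below detection),
#'   `below_detection`, `note`.
#' @export
reversion_table <- function(calls, group = NA_character_,
                            lower_limit = 2.5e4) {
  if (nrow(calls) == 0) stop("no calls", call. = FALSE)
  n_amb <- sum(calls$call == "AMBIGUOUS")
  n_rev <- sum(calls$call == "PROTOTROPH_REVERTANT")
  n_aux <- sum(calls$call %in% c("TRP_AUXOTROPH", "TYR_AUXOTROPH"))
  if (n_rev + n_aux == 0) {
    stop("all colonies ambiguous in group ", group, call. = FALSE)
  }
  below <- n_rev == 0
  list(
    group = group, n_auxotroph = n_aux, n_revertant = n_rev,
    n_ambiguous = n_amb, n_populations = length(unique(calls$population_id)),
    proportion = if (below) NA_real_ else n_rev / (n_rev + n_aux),
    below_detection = below,
    note = if (below) {
      sprintf("no revertants detected: below the lower detection limit (%.2g CFU/ml)",
              lower_limit)
    } else NA_character_
  )
}

#' Two-sided Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson chi-square (no continuity correction) on the 2x2 table
#' `[[a, b], [c, d]]`, e.g. auxotroph/revertant counts of two treatment
#' groups. Both margins must be positive.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise).
#' @return List: `statistic`, `df` (1), `p`, `expected` (2x2 matrix).
#' @examples
#' chi2_2x2(20, 5, 5, 20)$statistic  # 18
#' @export
chi2_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square undefined: zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L, p = ct$p.value,
       expected = ct$expected)
}
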