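#' Build a doubling-then-linear antibiotic ramp schedule
#'
#' Generates the per-transfer antibiotic concentration for the ramping
#' experiment. Transfers 0 and 1 are antibiotic-free (equilibration).
#' Starting at transfer 2 the concentration doubles each transfer from
#' one-eighth of the sub-MIC (`s/8, s/4, s/2, s` at transfers 2--5). From
#' transfer 6 the increment is linear, ending slightly above the working
#' concentration (`end_factor * w`) at the final transfer.
#'
#' @param sub_mic sub-MIC `s` (ug/ml), from [determine_sub_mic()].
#' @param working_conc working concentration `w` (ug/ml); must exceed `s`.
#' @param n_transfers number of transfers (schedule covers `0:n_transfers`);
#'   must be at least 6 to fit the doubling phase.
#' @param end_factor multiple of `w` reached at the final transfer
#'   (default 1.1, i.e. 10\% above the working concentration).
#' @param antibiotic optional label stored in the result.
#' @return Object of class `"ramp_schedule"`: list with `antibiotic`,
#'   `sub_mic`, `working_conc`, `end_conc` and `conc_by_transfer` (named
#'   numeric vector, one entry per transfer `0:n_transfers`).
#' @examples
#' r <- build_ramp(1.25, 50, antibiotic = "KAN")
#' r$conc_by_transfer[c("2", "5", "15")]  # 0.15625, 1.25, 55
#' @export
build_ramp <- function(sub_mic, working_conc, n_transfers = 15L,
                       end_factor = 1.1, antibiotic = NA_character_) {
  if (!(sub_mic > 0)) stop("sub_mic must be positive", call. = FALSE)
  if (sub_mic >= working_conc) {
    stop(sprintf("sub-MIC (%g) must be below the working concentration (%g)",
                 sub_mic, working_conc), call. = FALSE)
  }
  n_transfers <- as.integer(n_transfers)
  if (n_transfers < 6L) {
    stop("n_transfers must be >= 6 to fit the doubling phase", call. = FALSE)
  }
  end_conc <- end_factor * working_conc
  conc <- numeric(n_transfers + 1L)
  conc[3:6] <- sub_mic / c(8, 4, 2, 1)              # transfers 2..5
  inc <- (end_conc - sub_mic) / (n_transfers - 5L)  # linear phase
  if (n_transfers >= 6L) {
    conc[7:(n_transfers + 1L)] <- sub_mic + inc * seq_len(n_transfers - 5L)
  }
  names(conc) <- 0:n_transfers
  structure(list(antibiotic = antibiotic, sub_mic = sub_mic,
                 working_conc = working_conc, end_conc = end_conc,
                 conc_by_transfer = conc),
            class = "ramp_schedule")
}

#' @export
print.ramp_schedule <- function(x, ...) {
  cat(sprintf("Antibiotic ramp%s: sub-MIC %g, working %g, end %g ug/ml\n",
              if (is.na(x$antibiotic)) "" else paste0(" (", x$antibiotic, ")"),
              x$sub_mic, x$working_conc, x$end_conc))
  print(round(x$conc_by_transfer, 5))
  invisible(x)
}

#' Default antibiotic panel
#'
#' Sub-MIC and working concentrations (ug/ml) and pharmacodynamic mode of the
#' four ramped antibiotics: ampicillin and kanamycin are bactericidal,
#' chloramphenicol and tetracycline bacteriostatic.
#'
#' @return data.frame with columns `antibiotic`, `sub_mic`, `working_conc`,
#'   `mode`.
#' @examples
#' antibiotic_panel()
#' @export
antibiotic_panel <- function() {
  data.frame(
    antibiotic = c("AMP", "KAN", "CHL", "TET"),
    sub_mic = c(0.75, 1.25, 3.25, 1.35),
    working_conc = c(100, 50, 25, 15),
    mode = c("bactericidal", "bactericidal", "bacteriostatic",
             "bacteriostatic"),
    stringsAsFactors = FALSE
  )
}

#' Ramp schedules for the default antibiotic panel
#'
#' @param n_transfers,end_factor passed to [build_ramp()].
#' @return Named list of `"ramp_schedule"` objects, one per antibiotic in
#'   [antibiotic_panel()].
#' @export
panel_ramps <- function(n_transfers = 15L, end_factor = 1.1) {
  panel <- antibiotic_panel()
  out <- lapply(seq_len(nrow(panel)), function(i) {
    build_ramp(panel$sub_mic[i], panel$working_conc[i],
               n_transfers = n_transfers, end_factor = end_factor,
               antibiotic = panel$antibiotic[i])
  })
  setNames(out, panel$antibiotic)
}
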