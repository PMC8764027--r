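#' Call the MIC from a dose--response curve
#'
#' The MIC is the first (smallest) antibiotic concentration at which the
#' measured OD600 does not reach the growth threshold (OD < 0.01). If every
#' concentration shows growth the result is right-censored at the top of the
#' grid. Non-monotone dose--response (growth above a sub-threshold
#' concentration) is called by the literal first-crossing rule and noted.
#'
#' @param plate a `"mic"` table for one replicate, or a data.frame with
#'   `concentration` and `od600` for a single increasing grid.
#' @param threshold OD600 growth threshold (default 0.01).
#' @return List: `mic` (ug/ml, `NA` if censored), `censored`, `label`
#'   (e.g. `"> 8"`), `grid`, `non_monotone`.
#' @examples
#' call_mic(data.frame(concentration = c(1, 2, 4, 8),
#'                     od600 = c(0.5, 0.3, 0.005, 0.002)))$mic  # 4
#' @export
call_mic <- function(plate, threshold = 0.01) {
  conc <- plate$concentration
  od <- plate$od600
  o <- order(conc)
  conc <- conc[o]; od <- od[o]
  if (any(diff(conc) <= 0)) stop("concentration grid must be strictly increasing",
                                 call. = FALSE)
  below <- od < threshold
  non_mono <- any(below) && any(!below[seq_len(length(below)) > which(below)[1]])
  if (!any(below)) {
    return(list(mic = NA_real_, censored = TRUE,
                label = paste(">", max(conc)), grid = conc,
                non_monotone = FALSE))
  }
  i <- which(below)[1]
  list(mic = conc[i], censored = FALSE, label = format(conc[i]), grid = conc,
       non_monotone = non_mono)
}

#' MIC calls for every replicate of a plate table
#'
#' @param plates a `"mic"` table (several replicates).
#' @param threshold OD600 growth threshold.
#' @return data.frame `replicate_id`, `mic`, `censored`, `label`.
#' @export
call_mic_all <- function(plates, threshold = 0.01) {
  plates <- validate_table(plates, "mic")
  ids <- unique(plates$replicate_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- call_mic(plates[plates$replicate_id == id, ], threshold)
    data.frame(replicate_id = id, mic = r$mic, censored = r$censored,
               label = r$label, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Resistance gain (delta MIC) of derived over ancestral populations
#'
#' The evolved resistance gain is the derived MIC minus the ancestral MIC.
#' Ancestral and derived replicates are unpaired, so each derived replicate
#' is compared against the ancestral group median. Censored MICs on either
#' side are excluded with a warning, and the numbers retained are reported.
#'
#' @param derived,ancestral data.frames as returned by [call_mic_all()]
#'   (columns `replicate_id`, `mic`, `censored`).
#' @param group optional group label stored in the result.
#' @return List: `delta` (data.frame `replicate_id`, `delta`), `group`,
#'   `ancestral_median`, `n_derived`, `n_ancestral`, `n_excluded`.
#' @export
delta_mic <- function(derived, ancestral, group = NA_character_) {
  n_exc <- sum(derived$censored) + sum(ancestral$censored)
  if (n_exc > 0) {
    warning(sprintf("excluding %d censored MIC value(s) from delta-MIC", n_exc),
            call. = FALSE)
  }
  der <- derived[!derived$censored, ]
  anc <- ancestral[!ancestral$censored, ]
  if (nrow(anc) == 0 || nrow(der) == 0) {
    stop("no uncensored MICs left on one side", call. = FALSE)
  }
  m_anc <- stats::median(anc$mic)
  list(
    delta = data.frame(replicate_id = der$replicate_id,
                       delta = der$mic - m_anc, stringsAsFactors = FALSE),
    group = group, ancestral_median = m_anc,
    n_derived = nrow(der), n_ancestral = nrow(anc), n_excluded = n_exc
  )
}
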