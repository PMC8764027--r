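#' Maximum growth rate from CFU growth curves
#'
#' Implements the mean-curve maximum-slope procedure: (1) average CFU across
#' all replicates of the treatment at each sampled time point; (2) find the
#' pair of consecutive time points with the maximal raw increase of that mean
#' curve (first such interval on ties); (3) report each replicate's growth
#' rate over that shared interval. Both the raw slope (CFU/ml/h) and the
#' specific (log) rate `(ln CFU(t2) - ln CFU(t1)) / (t2 - t1)` (1/h) are
#' emitted; a replicate with zero CFU inside the interval gets `NA` rates and
#' is flagged.
#'
#' @param curves a `"growth"` table for one treatment group (one strain, or
#'   pre-summed counts).
#' @return List: `interval` (`t1`, `t2` in hours), `mean_curve` (data.frame
#'   `time_h`, `mean_cfu`) and `rates` (data.frame `replicate_id`,
#'   `rate_log`, `rate_raw`, `yield72`, `flagged`).
#' @examples
#' g <- data.frame(replicate_id = rep(c("a", "b"), each = 3), strain = "TRP",
#'                 time_h = rep(c(0, 3, 6), 2),
#'                 cfu_per_ml = c(100, 200, 800, 100, 200, 800))
#' max_growth_rate(g)$rates$rate_log  # log(4)/3 for both
#' @export
max_growth_rate <- function(curves) {
  curves <- validate_table(curves, "growth")
  # sum strains within a replicate (relevant for coculture tables)
  agg <- stats::aggregate(cfu_per_ml ~ replicate_id + time_h, curves, sum)
  times <- sort(unique(agg$time_h))
  if (length(times) < 2) stop("need at least 2 time points", call. = FALSE)
  wide <- matrix(NA_real_, length(times), length(unique(agg$replicate_id)),
                 dimnames = list(times, sort(unique(agg$replicate_id))))
  wide[cbind(match(agg$time_h, times), match(agg$replicate_id, colnames(wide)))] <-
    agg$cfu_per_ml
  if (anyNA(wide)) stop("replicates do not share a common time grid", call. = FALSE)

  mean_curve <- rowMeans(wide)
  inc <- diff(mean_curve)
  i <- which.max(inc)  # first maximal increase
  t1 <- times[i]; t2 <- times[i + 1]

  cfu1 <- wide[i, ]; cfu2 <- wide[i + 1, ]
  flagged <- cfu1 <= 0 | cfu2 <= 0
  rate_log <- ifelse(flagged, NA_real_, (log(cfu2) - log(cfu1)) / (t2 - t1))
  rate_raw <- (cfu2 - cfu1) / (t2 - t1)
  yield <- wide[length(times), ]

  list(
    interval = c(t1 = t1, t2 = t2),
    mean_curve = data.frame(time_h = times, mean_cfu = unname(mean_curve)),
    rates = data.frame(replicate_id = colnames(wide),
                       rate_log = unname(rate_log),
                       rate_raw = unname(rate_raw),
                       yield72 = unname(yield),
                       flagged = unname(flagged),
                       stringsAsFactors = FALSE)
  )
}
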