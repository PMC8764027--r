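#' Determine the sub-MIC from a dose--response plate
#'
#' Applies the threshold-zone rules to replicate OD600 readings over an
#' increasing antibiotic concentration grid. The threshold zone is the OD
#' band (default 0.05 +/- 0.005) in which antibiotic pressure is maximal
#' while growth still allows sustained propagation. Zone membership uses
#' closed (inclusive) endpoints.
#'
#' Scanning concentrations in ascending order:
#' \itemize{
#'   \item If exactly one concentration has \emph{all} replicate ODs inside
#'     the zone, that concentration is the sub-MIC.
#'   \item If more than one concentration is fully inside, their arithmetic
#'     mean is the sub-MIC.
#'   \item If a concentration has only \emph{some} ODs inside and the next
#'     measured concentration has none inside, the mean of those two
#'     concentrations is the sub-MIC. If the next concentration also
#'     partially overlaps the zone, the contiguous run of partially
#'     overlapping concentrations is averaged.
#'   \item If the partial overlap occurs at the last measured concentration
#'     (no next), that concentration itself is the sub-MIC.
#' }
#'
#' @param plate `"mic"`-schema data.frame ([validate_table()]): replicate
#'   dose--response ODs. All replicates must share one concentration grid.
#' @param zone_center,zone_halfwidth threshold zone (OD600).
#' @return List with `sub_mic` (ug/ml), the `rule` applied
#'   (`"full"`, `"partial_mean"`, `"partial_last"`) and the per-concentration
#'   zone `status` (`"all"`, `"some"`, `"none"`).
#' @examples
#' plate <- data.frame(
#'   replicate_id = rep(c("r1", "r2"), each = 3),
#'   concentration = rep(c(1, 2, 4), 2),
#'   od600 = c(0.40, 0.049, 0.004, 0.35, 0.052, 0.003),
#'   supplemented = TRUE, culture_type = "TRP_mono"
#' )
#' determine_sub_mic(plate)$sub_mic  # 2
#' @export
determine_sub_mic <- function(plate, zone_center = 0.05, zone_halfwidth = 0.005) {
  plate <- validate_table(plate, "mic")
  lo <- zone_center - zone_halfwidth
  hi <- zone_center + zone_halfwidth
  concs <- sort(unique(plate$concentration))
  if (length(concs) < 2) stop("need at least 2 concentrations", call. = FALSE)

  status <- vapply(concs, function(cc) {
    od <- plate$od600[plate$concentration == cc]
    inside <- od >= lo & od <= hi
    if (all(inside)) "all" else if (any(inside)) "some" else "none"
  }, "")

  full <- concs[status == "all"]
  if (length(full) >= 1) {
    return(list(sub_mic = mean(full), rule = "full",
                status = setNames(status, concs)))
  }

  partial <- which(status == "some")
  if (length(partial) == 0) {
    od_dist <- abs(plate$od600 - zone_center)
    stop(sprintf(
      "no sub-MIC resolvable: no OD intersects the zone [%g, %g]; nearest OD %g at %g ug/ml",
      lo, hi, plate$od600[which.min(od_dist)],
      plate$concentration[which.min(od_dist)]), call. = FALSE)
  }

  i <- partial[1]
  if (i == length(concs)) {
    return(list(sub_mic = concs[i], rule = "partial_last",
                status = setNames(status, concs)))
  }
  # contiguous run of partially overlapping concentrations
  j <- i
  while (j < length(concs) && status[j + 1] == "some") j <- j + 1
  if (j > i) {
    # several adjacent partial overlaps: average the run
    list(sub_mic = mean(concs[i:j]), rule = "partial_mean",
         status = setNames(status, concs))
  } else {
    # single partial overlap, next measured concentration has none inside:
    # mean of the two
    list(sub_mic = mean(c(concs[i], concs[i + 1])), rule = "partial_mean",
         status = setNames(status, concs))
  }
}
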