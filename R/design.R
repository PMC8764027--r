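#' Enumerate the experiment design
#'
#' Builds the replicate table of the ramping experiment: every culture type
#' (two supplemented auxotroph monocultures and the unsupplemented coculture)
#' crossed with every ramped antibiotic, with `n_lineages` founder lineages
#' each split into `n_technical` technical replicates (default 16 x 5 = 80
#' replicates per treatment cell). Monocultures are supplemented with both
#' amino acids; cocultures rely on cross-feeding.
#'
#' @param n_lineages founder lineages per treatment cell (default 16).
#' @param n_technical technical replicates per lineage (default 5).
#' @param culture_types,antibiotics treatment factors (defaults: all three
#'   culture types, the four ramped antibiotics).
#' @return Object of class `"experiment_design"`: a data.frame with one row
#'   per replicate (`lineage_id`, `culture_type`, `antibiotic`, `lineage`,
#'   `technical`, `supplemented`).
#' @examples
#' d <- build_design()
#' nrow(d)                                   # 960
#' sum(d$culture_type == "CO" & d$antibiotic == "KAN")  # 80
#' @export
build_design <- function(n_lineages = 16L, n_technical = 5L,
                         culture_types = CULTURE_TYPES,
                         antibiotics = c("AMP", "KAN", "CHL", "TET")) {
  stopifnot(n_lineages >= 1L, n_technical >= 1L,
            all(culture_types %in% CULTURE_TYPES),
            all(antibiotics %in% ANTIBIOTICS))
  grid <- expand.grid(technical = seq_len(n_technical),
                      lineage = seq_len(n_lineages),
                      antibiotic = antibiotics,
                      culture_type = culture_types,
                      stringsAsFactors = FALSE)
  grid <- grid[c("culture_type", "antibiotic", "lineage", "technical")]
  grid$lineage_id <- sprintf("%s_%s_L%02d_T%d", grid$culture_type,
                             grid$antibiotic, grid$lineage, grid$technical)
  grid$supplemented <- grid$culture_type != "CO"
  out <- grid[c("lineage_id", "culture_type", "antibiotic", "lineage",
                "technical", "supplemented")]
  rownames(out) <- NULL
  class(out) <- c("experiment_design", "data.frame")
  out
}

#' @export
print.experiment_design <- function(x, ...) {
  cells <- table(x$culture_type, x$antibiotic)
  cat(sprintf("Experiment design: %d replicates in %d treatment cells\n",
              nrow(x), sum(cells > 0)))
  print(cells)
  invisible(x)
}
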