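#' Pairwise Mann--Whitney U comparisons with BH correction and letters
#'
#' Compares every pair of groups with a two-sided Mann--Whitney U test
#' (exact enumeration when both samples have 8 or fewer untied observations,
#' otherwise the continuity-corrected normal approximation with tie
#' correction), adjusts the p-values with the Benjamini--Hochberg step-up
#' procedure, and assigns a compact letter display: groups share a letter
#' if and only if their adjusted p-value is >= `alpha`.
#'
#' @param groups named list mapping group label -> numeric sample (each with
#'   at least 2 observations).
#' @param alpha significance level for the letter display (default 0.05).
#' @return List: `pairs` (data.frame `group1`, `group2`, `U`, `p_raw`,
#'   `p_bh`), `letters` (named character vector, one letter string per
#'   group) and `alpha`.
#' @examples
#' pairwise_compare(list(a = c(1, 2, 3), b = c(10, 11, 12)))$pairs$p_raw  # 0.1
#' @export
pairwise_compare <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  labs <- names(groups)
  cmb <- utils::combn(length(groups), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    x <- groups[[i]]; y <- groups[[j]]
    has_ties <- anyDuplicated(c(x, y)) > 0
    if (identical(sort(x), sort(y))) {
      # identical samples: U at its null mean, p = 1
      return(data.frame(group1 = labs[i], group2 = labs[j],
                        U = length(x) * length(y) / 2, p_raw = 1,
                        stringsAsFactors = FALSE))
    }
    exact <- min(length(x), length(y)) <= 8 && !has_ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    data.frame(group1 = labs[i], group2 = labs[j],
               U = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pairs$p_bh <- stats::p.adjust(pairs$p_raw, method = "BH")
  letters <- .letter_display(labs, pairs, alpha)
  list(pairs = pairs, letters = letters, alpha = alpha)
}

# Insert-and-absorb compact letter display: start with one letter covering
# all groups; for each significant pair split every letter set containing
# both; absorb sets that became subsets. Guarantees two groups share a
# letter iff their adjusted p >= alpha.
.letter_display <- function(labs, pairs, alpha) {
  sets <- list(labs)
  sig <- pairs[pairs$p_bh < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    g1 <- sig$group1[k]; g2 <- sig$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets (keep maximal sets only), drop empties
    new_sets <- new_sets[vapply(new_sets, length, 0L) > 0]
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[a] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order sets by first group appearance for stable lettering
  first <- vapply(sets, function(s) min(match(s, labs)), 0)
  sets <- sets[order(first)]
  out <- setNames(rep("", length(labs)), labs)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}
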