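#' Build the lineage x transfer density-profile matrix
#'
#' Pivots a transfer table into one row per lineage and one column per
#' transfer (OD600). Transfers after a lineage's death carry no
#' measurements and are imputed with `impute_value` (default 0: a dead
#' culture has no density), so extinct lineages stay in the clustering.
#'
#' @param table a `"transfer"` table.
#' @param impute_value OD600 filled in for post-extinction transfers.
#' @return Object of class `"profile_matrix"`: numeric matrix (rows named by
#'   lineage) with attributes `groups` (culture type per row) and
#'   `antibiotic`.
#' @export
build_profiles <- function(table, impute_value = 0) {
  table <- validate_table(table, "transfer")
  transfers <- 0:max(table$transfer)
  ids <- unique(table$lineage_id)
  mat <- matrix(impute_value, length(ids), length(transfers),
                dimnames = list(ids, transfers))
  groups <- character(length(ids))
  abs_ <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- table[table$lineage_id == ids[k], ]
    # contiguity from 0 is guaranteed by validation; anything after the last
    # recorded transfer is post-extinction and keeps the imputed value
    mat[k, rows$transfer + 1L] <- rows$od600
    groups[k] <- rows$culture_type[1]
    abs_[k] <- rows$antibiotic[1]
  }
  structure(mat, groups = setNames(groups, ids),
            antibiotic = setNames(abs_, ids), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Profile matrix: %d lineages x %d transfers\n", nrow(x), ncol(x)))
  print(table(attr(x, "groups")))
  invisible(x)
}

#' Gaussian-mixture clustering of density profiles
#'
#' Fits diagonal-covariance Gaussian mixtures by expectation--maximisation
#' for each candidate number of components and selects the number by the
#' Bayesian information criterion (via \pkg{mclust}, model `"VVI"`). Labels
#' are maximum-responsibility assignments. Identical rows (no variance)
#' short-circuit to a single cluster.
#'
#' @param profiles `"profile_matrix"` (or plain numeric matrix).
#' @param K_range candidate component counts (default `1:6`).
#' @param seed integer seed (the fit is deterministic given the data; the
#'   seed guards the subsampled initialisation used for large inputs).
#' @return List: `labels` (integer per row), `K`, `bic` (named by K),
#'   `model` (the \pkg{mclust} fit or `NULL` for the degenerate case).
#' @importFrom mclust Mclust mclustBIC priorControl
#' @export
fit_gmm <- function(profiles, K_range = 1:6, seed = 1L) {
  x <- unclass(profiles)
  attributes(x)[c("groups", "antibiotic")] <- NULL
  x <- as.matrix(x)
  if (nrow(x) < max(K_range) * 3) {
    stop("need at least 3 rows per candidate component", call. = FALSE)
  }
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    return(list(labels = rep(1L, nrow(x)), K = 1L,
                bic = c(`1` = NA_real_), model = NULL,
                note = "degenerate input: identical rows"))
  }
  set.seed(seed)
  # the conjugate prior acts as a data-driven variance floor: without it,
  # zero-variance columns (e.g. all-dead lineages imputed at one value)
  # make every K > 1 model singular
  fit <- suppressWarnings(
    mclust::Mclust(x, G = K_range, modelNames = "VVI",
                   prior = mclust::priorControl(), verbose = FALSE)
  )
  if (is.null(fit)) stop("mixture fit failed for all K", call. = FALSE)
  bic <- fit$BIC[, "VVI"]
  list(labels = as.integer(fit$classification), K = fit$G,
       bic = bic, model = fit)
}

#' Ward clustering tree of density profiles
#'
#' Agglomerative hierarchy (Ward linkage on Euclidean distances) over
#' lineage profiles, serialised as a Newick string with branch lengths
#' derived from merge heights. Leaves are named `lineage|group`.
#'
#' @param profiles `"profile_matrix"`.
#' @return List: `hclust` (the [stats::hclust] object), `phylo`
#'   (\pkg{ape} tree) and `newick` (string).
#' @export
cluster_tree <- function(profiles) {
  x <- as.matrix(unclass(profiles))
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  groups <- attr(profiles, "groups")
  labels <- if (is.null(groups)) rownames(x) else {
    paste(rownames(x), groups[rownames(x)], sep = "|")
  }
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  hc$labels <- labels
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy,
       newick = ape::write.tree(phy))
}
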