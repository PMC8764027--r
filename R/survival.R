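#' Extinction events from the transfer record
#'
#' One survival record per lineage: the event time is the first transfer at
#' which the OD600 fell strictly below the death threshold; lineages still
#' alive at their final recorded transfer are right-censored there. An OD
#' exactly at the threshold counts as alive.
#'
#' @param table a `"transfer"` table.
#' @param threshold OD600 death threshold (default 0.01).
#' @return data.frame `lineage_id`, `group` (culture type), `antibiotic`,
#'   `time` (transfer index), `event` (logical).
#' @export
call_events <- function(table, threshold = 0.01) {
  table <- validate_table(table, "transfer")
  ids <- unique(table$lineage_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- table[table$lineage_id == id, ]
    rows <- rows[order(rows$transfer), ]
    hit <- which(rows$od600 < threshold)
    if (length(hit) > 0) {
      data.frame(lineage_id = id, group = rows$culture_type[1],
                 antibiotic = rows$antibiotic[1],
                 time = rows$transfer[hit[1]], event = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(lineage_id = id, group = rows$culture_type[1],
                 antibiotic = rows$antibiotic[1],
                 time = max(rows$transfer), event = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Kaplan--Meier survival curve for one group
#'
#' Product-limit estimate of the probability that a lineage is still alive
#' after each transfer, with at-risk counts. `S(0) = 1` and the curve is
#' non-increasing; with no censoring it equals the empirical survival
#' function.
#'
#' @param records data.frame from [call_events()] (one group).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_curve <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1
  )
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test over lineage extinctions
#'
#' Standard log-rank test: at each distinct event time the observed number
#' of extinctions in group A is compared with its hypergeometric expectation
#' given the at-risk counts; the squared summed difference over the summed
#' variance is chi-square with 1 degree of freedom. Tied events use the
#' standard tied-event hypergeometric variance. With no events in either
#' group the statistic is 0 and p = 1.
#'
#' @param a,b data.frames from [call_events()] (the two groups).
#' @return List: `statistic`, `df` (1), `p`, `n` (per-group sizes),
#'   `events` (per-group event counts).
#' @export
logrank_test <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be nonempty", call. = FALSE)
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c("A", "B"), c(nrow(a), nrow(b)))
  n <- c(A = nrow(a), B = nrow(b))
  ev <- c(A = sum(a$event), B = sum(b$event))
  if (sum(event) == 0) {
    return(list(statistic = 0, df = 1L, p = 1, n = n, events = ev))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd$chisq)
  if (!is.finite(stat)) stat <- 0  # degenerate: no between-group variance
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = n, events = ev)
}

#' All pairwise log-rank tests between culture types
#'
#' @param records data.frame from [call_events()] (several groups).
#' @param group_col column holding the group label (default `"group"`).
#' @return data.frame `group1`, `group2`, `statistic`, `p`.
#' @export
pairwise_logrank <- function(records, group_col = "group") {
  labs <- unique(records[[group_col]])
  if (length(labs) < 2) stop("need at least 2 groups", call. = FALSE)
  cmb <- utils::combn(length(labs), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    g1 <- labs[cmb[1, k]]; g2 <- labs[cmb[2, k]]
    lr <- logrank_test(records[records[[group_col]] == g1, ],
                       records[records[[group_col]] == g2, ])
    data.frame(group1 = g1, group2 = g2, statistic = lr$statistic, p = lr$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
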