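# Shared fixtures, built in code.

# a small well-formed transfer table: n lineages, n_transfers+1 transfers,
# optional per-lineage death transfer (no records after death)
make_transfer_table <- function(ods, culture_type = "CO", antibiotic = "KAN",
                                conc = NULL) {
  # ods: named list lineage_id -> numeric OD vector (transfer 0..)
  rows <- lapply(names(ods), function(id) {
    od <- ods[[id]]
    n <- length(od)
    data.frame(
      lineage_id = id, culture_type = culture_type, antibiotic = antibiotic,
      transfer = seq_len(n) - 1L, od600 = od,
      concentration = if (is.null(conc)) rep(0, n) else conc[seq_len(n)],
      alive = c(rep(TRUE, n - 1), od[n] >= 0.01),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# dose-response plate on a shared grid; ods is a matrix with one row per
# replicate, one column per concentration
make_mic_plate <- function(grid, ods, supplemented = TRUE,
                           culture_type = "TRP_mono") {
  ods <- rbind(ods)
  do.call(rbind, lapply(seq_len(nrow(ods)), function(i) {
    data.frame(replicate_id = sprintf("r%d", i), concentration = grid,
               od600 = ods[i, ], supplemented = supplemented,
               culture_type = culture_type, stringsAsFactors = FALSE)
  }))
}

# planted two-blob profile matrix: n per blob, d dims, centres `sep` apart
# (Euclidean), unit within-blob sd
make_planted_blobs <- function(n = 30, d = 16, sep = 10, seed = 1) {
  set.seed(seed)
  shift <- sep / sqrt(d)
  x <- rbind(
    matrix(rnorm(n * d, 0, 1), n, d),
    matrix(rnorm(n * d, shift, 1), n, d)
  )
  rownames(x) <- sprintf("L%02d", seq_len(2 * n))
  list(x = x, labels = rep(1:2, each = n))
}

# exhaustive Mann-Whitney enumeration oracle: two-sided exact p
mwu_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# brute-force log-rank accumulation oracle (two groups, discrete times)
logrank_oracle <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB); event <- c(event <- c(eventA, eventB))
  grp <- rep(c(1, 2), c(length(timeA), length(timeB)))
  ts <- sort(unique(time[event]))
  num <- 0; var <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & grp == 1)
    num <- num + d1 - d * n1 / n
    if (n > 1) {
      var <- var + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (num^2) / var
}
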