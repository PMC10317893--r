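# Independent oracles used against the package implementation.
# These deliberately share no code with the R/ implementation.

# exact permutation p-value of the linear statistic sum(x*y) by full
# enumeration of all distinct assignments of a binary y (unit weights)
exact_perm_p <- function(x, y) {
  n <- length(y); k <- sum(y)
  pos <- utils::combn(n, k)
  Ts <- apply(pos, 2L, function(ix) sum(x[ix]))
  tobs <- sum(x[y == 1])
  mu <- mean(Ts)
  mean(abs(Ts - mu) >= abs(tobs - mu) - 1e-9)
}

# mid-p variant: ties at the observed statistic count half
exact_perm_midp <- function(x, y) {
  n <- length(y); k <- sum(y)
  pos <- utils::combn(n, k)
  Ts <- apply(pos, 2L, function(ix) sum(x[ix]))
  tobs <- sum(x[y == 1])
  mu <- mean(Ts)
  d <- abs(Ts - mu); dobs <- abs(tobs - mu)
  mean(d > dobs + 1e-9) + 0.5 * mean(abs(d - dobs) <= 1e-9)
}

# variance of the linear statistic over the full enumeration
exact_perm_var <- function(x, y) {
  n <- length(y); k <- sum(y)
  pos <- utils::combn(n, k)
  Ts <- apply(pos, 2L, function(ix) sum(x[ix]))
  mean((Ts - mean(Ts))^2)
}

# brute-force maximization of the standardized two-sample statistic over
# every admissible cutpoint, plain loops
brute_cutpoint <- function(x, y, minbucket) {
  W <- length(y)
  ybar <- mean(y)
  V <- mean((y - ybar)^2)
  u <- sort(unique(x))
  best <- NULL
  for (xi in u[-length(u)]) {
    wl <- sum(x <= xi)
    if (wl < minbucket || (W - wl) < minbucket) next
    v <- V * wl * (W - wl) / (W - 1)
    s <- abs(sum(y[x <= xi]) - ybar * wl) / sqrt(v)
    if (is.null(best) || s > best$statistic + 1e-12) {
      best <- list(cutpoint = xi, statistic = s)
    }
  }
  best
}

# all-pairs concordance count AUC, O(n^2)
brute_auc <- function(risks, truth) {
  pos <- risks[truth == 1]; neg <- risks[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a tiny hand-built valid cohort data.frame
toy_cohort_df <- function() {
  data.frame(
    age = c(45L, 60L, 33L),
    sex = c("F", "M", "F"),
    histology = c("PTC", "FTC", "PTC-FV"),
    t_stage = c(1L, 3L, 2L),
    n_stage = c(0L, 1L, 0L),
    ata_risk = c("low", "high", "intermediate"),
    tsh = c(64.5, 80, 31.2),
    tg = c(3, 23.3, 0.7),
    raiu = c(4.4, 2.0, 7.8),
    ptwbs = c("negative", "positive", "remnant"),
    center = c("C1", "C1", "C2"),
    stringsAsFactors = FALSE
  )
}

# small planted cohort for fitting tests
small_cohort <- function(n = 400, seed = 1) {
  simulate_cohort(cohort_config(n = n), seed = seed)
}
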