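# Permutation-framework association tests and cutpoint search.
#
# For a binary influence y and a transformed predictor g(x) (scalar for
# continuous/ordinal, k-dim indicator for nominal), the linear statistic is
#   T = sum_i w_i g(x_i) y_i,
# with conditional expectation and covariance under permutation of y:
#   ybar = sum(w y) / W,    V = sum(w (y - ybar)^2) / W,
#   mu   = ybar * sum(w g),
#   Cov  = W/(W-1) V sum(w g g') - 1/(W-1) V (sum(w g))(sum(w g))'.
# A scalar g gives |T - mu|/sqrt(Cov) with a two-sided normal p-value; a
# vector g gives the quadratic form (T-mu)' Cov^+ (T-mu) with a chi-square
# p-value on rank(Cov) degrees of freedom.

.pinv_tol <- 1e-8  # relative singular-value tolerance for the pseudoinverse

#' Encode a predictor for the linear-statistic framework
#'
#' Continuous and ordinal predictors map to their scalar score; unordered
#' factors with k levels map to a k-column indicator matrix (a 2-level
#' factor collapses to a scalar 0/1 score, which is equivalent after
#' standardization).
#'
#' @param x A numeric, ordered-factor or factor vector.
#' @return A numeric matrix with one row per record.
#' @export
encode_predictor <- function(x) {
  if (is.numeric(x)) return(matrix(as.numeric(x), ncol = 1L))
  if (is.ordered(x)) return(matrix(as.numeric(x), ncol = 1L))
  if (is.factor(x)) {
    lev <- levels(x)
    if (length(lev) == 2L) return(matrix(as.numeric(x == lev[2L]), ncol = 1L))
    m <- matrix(0, nrow = length(x), ncol = length(lev),
                dimnames = list(NULL, lev))
    m[cbind(seq_along(x), as.integer(x))] <- 1
    return(m)
  }
  if (is.logical(x)) return(matrix(as.numeric(x), ncol = 1L))
  stop("unsupported predictor type: ", class(x)[1L])
}

# conditional moments shared by association test and cutpoint search;
# returns list(T, mu, Cov) for an encoded g (n x k matrix)
.linstat_moments <- function(g, y, w) {
  W <- sum(w)
  ybar <- sum(w * y) / W
  V <- sum(w * (y - ybar)^2) / W
  Tg <- colSums(w * y * g)
  Sg <- colSums(w * g)
  Sgg <- crossprod(g, w * g)
  Cov <- (W / (W - 1)) * V * Sgg - (1 / (W - 1)) * V * tcrossprod(Sg)
  list(T = Tg, mu = ybar * Sg, Cov = Cov, V = V, W = W)
}

#' Permutation-framework association test
#'
#' Tests association between an encoded predictor and a binary endpoint
#' under the permutation (conditional) distribution of the linear
#' statistic. Degenerate inputs (constant x, pure y) return p = 1 with
#' statistic 0 by convention, so they are never selected for splitting.
#'
#' @param g Encoded predictor matrix from [encode_predictor()], or a
#'   numeric vector (treated as one column).
#' @param y Binary 0/1 endpoint vector.
#' @param w Non-negative case weights (default 1).
#' @return A list with `statistic`, `p_value` and `df` (0 for the scalar
#'   normal case).
#' @export
association_test <- function(g, y, w = rep(1, length(y))) {
  if (is.vector(g)) g <- matrix(as.numeric(g), ncol = 1L)
  if (any(w < 0)) stop("negative weights")
  keep <- w > 0
  if (sum(keep) < 2L) stop("need at least 2 records with positive weight")
  g <- g[keep, , drop = FALSE]; y <- y[keep]; w <- w[keep]
  mom <- .linstat_moments(g, y, w)
  if (mom$V <= 0) return(list(statistic = 0, p_value = 1, df = 0L))
  if (ncol(g) == 1L) {
    v <- mom$Cov[1L, 1L]
    if (v <= .pinv_tol * max(abs(g))^2) {
      return(list(statistic = 0, p_value = 1, df = 0L))
    }
    stat <- abs(mom$T - mom$mu) / sqrt(v)
    return(list(statistic = as.numeric(stat),
                p_value = 2 * stats::pnorm(-as.numeric(stat)), df = 0L))
  }
  # quadratic form with deterministic pseudoinverse
  ei <- eigen(mom$Cov, symmetric = TRUE)
  pos <- ei$values > .pinv_tol * max(ei$values, 0)
  rank <- sum(pos)
  if (rank == 0L) return(list(statistic = 0, p_value = 1, df = 0L))
  d <- mom$T - mom$mu
  z <- crossprod(ei$vectors[, pos, drop = FALSE], d)
  stat <- sum(z^2 / ei$values[pos])
  list(statistic = as.numeric(stat),
       p_value = stats::pchisq(stat, df = rank, lower.tail = FALSE),
       df = rank)
}

#' Best binary cutpoint for a split
#'
#' Scans candidate cutpoints at observed unique values (continuous/ordinal)
#' or all binary level partitions (nominal, k levels give 2^(k-1)-1
#' candidates), computing the standardized two-sample statistic
#' |T_A - mu_A| / sqrt(Cov_A) with the left-side indicator A = 1(x <= xi)
#' (or A = 1(level in subset)) as influence side. Candidates leaving a
#' child below `minbucket` weight are inadmissible. Ties break toward the
#' smaller cutpoint (first enumerated partition for nominal).
#'
#' @param x Predictor vector (numeric, ordered factor, or factor).
#' @param y Binary 0/1 endpoint.
#' @param w Case weights.
#' @param minbucket Minimum child weight.
#' @return `NULL` if no admissible candidate; otherwise a list with
#'   `statistic` and either `cutpoint` (largest left-going value) or
#'   `levels` (left-going level subset).
#' @export
find_cutpoint <- function(x, y, w = rep(1, length(y)), minbucket = 7) {
  keep <- w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  W <- sum(w)
  ybar <- sum(w * y) / W
  V <- sum(w * (y - ybar)^2) / W
  if (V <= 0) return(NULL)
  # standardized two-sample statistic for left-weight wl, left-sum tl
  std_stat <- function(tl, wl) {
    v <- V * wl * (W - wl) / (W - 1)
    ifelse(v > 0, abs(tl - ybar * wl) / sqrt(v), 0)
  }
  if (is.numeric(x) || is.ordered(x)) {
    xs <- if (is.ordered(x)) as.numeric(x) else x
    o <- order(xs)
    xo <- xs[o]
    cw <- cumsum(w[o])
    cwy <- cumsum((w * y)[o])
    # boundaries at the last occurrence of each unique value
    last <- which(diff(xo) > 0)           # split after position `last`
    if (length(last) == 0L) return(NULL)  # constant x
    wl <- cw[last]
    ok <- wl >= minbucket & (W - wl) >= minbucket
    if (!any(ok)) return(NULL)
    stat <- std_stat(cwy[last][ok], wl[ok])
    best <- which.max(stat)               # first max = smallest cutpoint
    cut <- xo[last][ok][best]
    out <- list(cutpoint = cut, statistic = stat[best])
    if (is.ordered(x)) out$cut_label <- levels(x)[cut]  # cutpoint is the score
    return(out)
  }
  if (is.factor(x)) {
    lev <- levels(x)[tabulate(as.integer(x), nbins = nlevels(x)) > 0]
    k <- length(lev)
    if (k < 2L) return(NULL)
    best <- NULL
    # enumerate subsets containing lev[1] to skip complements
    for (code in 0:(2^(k - 1L) - 1L)) {
      subset <- lev[c(TRUE, as.logical(bitwAnd(code, 2^(0:(k - 2L)))))]
      if (length(subset) == k) next
      A <- x %in% subset
      wl <- sum(w[A])
      if (wl < minbucket || (W - wl) < minbucket) next
      s <- std_stat(sum((w * y)[A]), wl)
      if (is.null(best) || s > best$statistic) {
        best <- list(levels = subset, statistic = s)
      }
    }
    return(best)
  }
  stop("unsupported predictor type: ", class(x)[1L])
}

#' Select the splitting variable at a node
#'
#' Runs [association_test()] for every candidate predictor, Bonferroni-
#' adjusts the smallest p-value over the m tested predictors, and selects
#' the argmin if the adjusted p-value passes `alpha`. Ties in adjusted
#' p-value break toward the canonical predictor order
#' (`tg_schema$predictors`), then declaration order.
#'
#' @param data data.frame of predictors (columns already typed).
#' @param y Binary 0/1 endpoint.
#' @param w Case weights.
#' @param alpha Significance level after adjustment.
#' @return `NULL` (stop signal) or a list with `variable`, `p_adj`,
#'   `p_raw`, `statistic`.
#' @export
select_split_variable <- function(data, y, w = rep(1, length(y)),
                                  alpha = 0.05) {
  vars <- names(data)
  if (length(vars) == 0L) stop("empty predictor list")
  pvals <- vapply(vars, function(v) {
    association_test(encode_predictor(data[[v]]), y, w)$p_value
  }, numeric(1))
  m <- length(vars)
  ord <- order(match(vars, tg_schema$predictors, nomatch = length(vars) + 1L))
  pvals <- pvals[ord]; vars <- vars[ord]
  i <- which.min(pvals)  # first min in canonical order
  p_adj <- unname(min(1, m * pvals[i]))
  if (p_adj > alpha) return(NULL)
  list(variable = vars[i], p_adj = p_adj, p_raw = unname(pvals[i]))
}
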