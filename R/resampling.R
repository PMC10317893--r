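# Stability-based variable retention and repeated stratified 70:30
# cross-validation with node-threshold aggregation.

.derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

#' Class-stratified bootstrap resample
#'
#' Samples records with replacement within each endpoint class, preserving
#' both class counts exactly ("maintaining the original proportion of the
#' endpoint"), then shuffles the row order deterministically.
#'
#' @param cohort A `tg_cohort` (or data.frame with a `ptwbs` column).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param fraction Resampled fraction of each class. The default 1 is a
#'   bootstrap at constant n; a value < 1 switches to subsampling without
#'   replacement.
#' @return A cohort of the same class composition.
#' @export
stratified_resample <- function(cohort, seed = NULL, fraction = 1) {
  y <- binarize_endpoint(cohort$ptwbs)
  if (length(unique(y)) < 2L) stop("both endpoint classes must be present")
  stopifnot(fraction > 0, fraction <= 1)
  draw <- function() {
    idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      k <- max(1L, round(fraction * length(ix)))
      sample(ix, k, replace = fraction == 1)
    }), use.names = FALSE)
    idx[sample.int(length(idx))]
  }
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stability-based variable selection
#'
#' Repeatedly refits the conditional inference tree on class-stratified
#' bootstrap resamples and records, per candidate predictor, the fraction
#' of iterations in which it appears in at least one split. Predictors
#' with frequency at or above `freq_threshold` form the retained set.
#'
#' @param cohort A `tg_cohort`.
#' @param predictors Candidate predictor names (default: the canonical
#'   nine).
#' @param iterations Number of resampled refits (default 1000).
#' @param freq_threshold Retention threshold on selection frequency
#'   (default 0.95).
#' @param seed Integer seed driving all resamples.
#' @param fraction Passed to [stratified_resample()].
#' @param ... Fit parameters passed to [tgtree()] (`alpha`, `minsplit`,
#'   `minbucket`, `maxdepth`).
#' @return A `tg_stability` list: `iterations`, `frequency` (named,
#'   sorted decreasing), `retained`, `threshold`, `skipped`.
#' @export
stability_selection <- function(cohort, predictors = tg_schema$predictors,
                                iterations = 1000L, freq_threshold = 0.95,
                                seed = 1L, fraction = 1, ...) {
  stopifnot(iterations >= 1)
  fml <- stats::reformulate(predictors, response = "ptwbs")
  seeds <- .derive_seeds(seed, iterations)
  counts <- stats::setNames(numeric(length(predictors)), predictors)
  skipped <- 0L
  for (i in seq_len(iterations)) {
    res <- stratified_resample(cohort, seed = seeds[i], fraction = fraction)
    fit <- tryCatch(tgtree(fml, data = res, ...), error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    used <- tree_variables(fit)
    counts[used] <- counts[used] + 1
  }
  done <- iterations - skipped
  if (done == 0L) stop("all iterations failed")
  freq <- sort(counts / done, decreasing = TRUE)
  structure(list(iterations = iterations,
                 frequency = freq,
                 retained = names(freq)[freq >= freq_threshold],
                 threshold = freq_threshold,
                 skipped = skipped,
                 seed = seed),
            class = "tg_stability")
}

#' @export
print.tg_stability <- function(x, ...) {
  cat(sprintf("Stability selection over %d stratified bootstrap iterations\n",
              x$iterations))
  if (x$skipped > 0L) cat(sprintf("  (%d iterations skipped)\n", x$skipped))
  tab <- data.frame(variable = names(x$frequency),
                    selection_pct = round(100 * x$frequency, 1))
  print(tab, row.names = FALSE)
  cat(sprintf("retained (frequency >= %g%%): %s\n", 100 * x$threshold,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  invisible(x)
}

# stratified train indices: per class, round(train_fraction * n_class)
.stratified_train_idx <- function(y, train_fraction) {
  unlist(lapply(split(seq_along(y), y), function(ix) {
    k <- round(train_fraction * length(ix))
    if (k == length(ix)) k <- length(ix) - 1L  # keep validation non-empty
    sample(ix, max(k, 1L))
  }), use.names = FALSE)
}

#' Canonical node cutoffs of a fitted tree
#'
#' Maps a fitted tree onto the published topology — root split on
#' `n_stage`; one Tg split in the node-positive branch; an upper and a
#' lower Tg split in the node-negative branch — and extracts the three Tg
#' cutoffs. A tree whose shape does not match is a structural mismatch
#' (data, not an error) and is excluded from per-node aggregation.
#'
#' @param tree A `tgtree`.
#' @return A list with `concordant` (logical) and `cutoffs` (named numeric
#'   `n1_tg`, `n0_hi`, `n0_lo`; `NA` when mismatched).
#' @export
extract_canonical_cutoffs <- function(tree) {
  mismatch <- list(concordant = FALSE,
                   cutoffs = c(n1_tg = NA_real_, n0_hi = NA_real_,
                               n0_lo = NA_real_))
  root <- tree$root
  if (root$terminal || root$predictor != "n_stage") return(mismatch)
  n0 <- root$left; n1 <- root$right
  tg_cuts <- function(node) {
    unlist(.walk(node, function(nd)
      if (!nd$terminal && nd$predictor == "tg") nd$cutpoint else NULL))
  }
  non_tg <- function(node) {
    any(unlist(.walk(node, function(nd)
      if (!nd$terminal && nd$predictor != "tg") TRUE else FALSE)))
  }
  if (n1$terminal || n1$predictor != "tg" || non_tg(n1)) return(mismatch)
  if (n0$terminal || n0$predictor != "tg" || non_tg(n0)) return(mismatch)
  c0 <- tg_cuts(n0)
  if (length(c0) != 2L) return(mismatch)
  list(concordant = TRUE,
       cutoffs = c(n1_tg = n1$cutpoint, n0_hi = max(c0), n0_lo = min(c0)))
}

.med_iqr <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Repeated stratified Monte Carlo cross-validation
#'
#' Runs `repeats` independent stratified 70:30 train/validation splits
#' (event proportion preserved in both parts to the nearest integer), fits
#' the tree on each training part, evaluates confusion metrics and AUC on
#' both parts under the 0.5-risk classification rule, extracts the
#' canonical node cutoffs from structurally concordant trees, and
#' aggregates everything as median (IQR).
#'
#' @param cohort A `tg_cohort`.
#' @param predictors Retained predictor names.
#' @param repeats Number of random splits (default 200).
#' @param train_fraction Training fraction in (0, 1) (default 0.70).
#' @param seed Integer seed.
#' @param ... Fit parameters passed to [tgtree()].
#' @return A `tg_cv_report` list with per-repeat tables and aggregates.
#' @export
mc_cross_validate <- function(cohort, predictors, repeats = 200L,
                              train_fraction = 0.70, seed = 1L, ...) {
  if (repeats < 1) stop("repeats must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1): the validation part must be non-empty")
  }
  if (length(predictors) == 0L) stop("retained predictor set is empty")
  fml <- stats::reformulate(predictors, response = "ptwbs")
  y <- binarize_endpoint(cohort$ptwbs)
  if (length(unique(y)) < 2L) stop("both endpoint classes must be present")
  seeds <- .derive_seeds(seed, repeats)

  metric_names <- c("accuracy", "ppv", "npv", "sensitivity", "specificity", "auc")
  per_metric <- function() matrix(NA_real_, nrow = repeats,
                                  ncol = length(metric_names),
                                  dimnames = list(NULL, metric_names))
  train_m <- per_metric(); valid_m <- per_metric()
  cuts <- matrix(NA_real_, nrow = repeats, ncol = 3L,
                 dimnames = list(NULL, c("n1_tg", "n0_hi", "n0_lo")))
  concordant <- logical(repeats)

  for (r in seq_len(repeats)) {
    tr_idx <- with_seed(seeds[r], .stratified_train_idx(y, train_fraction))
    train <- cohort[tr_idx, , drop = FALSE]
    valid <- cohort[-tr_idx, , drop = FALSE]
    fit <- tgtree(fml, data = train, ...)
    for (part in c("train", "valid")) {
      dat <- if (part == "train") train else valid
      truth <- binarize_endpoint(dat$ptwbs)
      pr <- predict(fit, dat, type = "all")
      m <- confusion_metrics(pr$class, truth, risks = pr$risk)
      vals <- unlist(m[metric_names])
      if (part == "train") train_m[r, ] <- vals else valid_m[r, ] <- vals
    }
    cc <- extract_canonical_cutoffs(fit)
    concordant[r] <- cc$concordant
    if (cc$concordant) cuts[r, ] <- cc$cutoffs
  }

  agg <- function(mat) t(apply(mat, 2L, .med_iqr))
  structure(list(repeats = repeats,
                 train_fraction = train_fraction,
                 seed = seed,
                 train_metrics = train_m,
                 validation_metrics = valid_m,
                 cutoffs = cuts,
                 concordant = concordant,
                 n_concordant = sum(concordant),
                 aggregates = list(train = agg(train_m),
                                   validation = agg(valid_m),
                                   cutoffs = agg(cuts))),
            class = "tg_cv_report")
}

#' @export
print.tg_cv_report <- function(x, ...) {
  cat(sprintf("Monte Carlo cross-validation: %d repeats at %.0f:%.0f\n",
              x$repeats, 100 * x$train_fraction, 100 * (1 - x$train_fraction)))
  fmt <- function(a) {
    data.frame(median = round(a[, "median"], 3),
               IQR = sprintf("(%.3g-%.3g)", a[, "q1"], a[, "q3"]))
  }
  cat("training metrics, median (IQR):\n"); print(fmt(x$aggregates$train))
  cat("validation metrics, median (IQR):\n"); print(fmt(x$aggregates$validation))
  cat(sprintf("canonical Tg cutoffs from %d/%d concordant trees, median (IQR):\n",
              x$n_concordant, x$repeats))
  print(fmt(x$aggregates$cutoffs))
  invisible(x)
}

#' Per-center model evaluation
#'
#' Applies a fixed model to each center's subset of the cohort (and to the
#' pooled cohort), reporting prevalence, accuracy, PPV, NPV and AUC per
#' center, mirroring a multicenter performance table. Centers with a
#' single endpoint class have an undefined AUC, reported as `NA`.
#'
#' @param model A `tgtree`.
#' @param cohort A `tg_cohort` with center labels.
#' @param na_risk Risk score substituted for risk-unavailable terminals in
#'   the AUC (default: the calibrated generator baseline); recorded in the
#'   `"na_risk"` attribute of the result when it was actually used.
#' @return data.frame with one row per center plus a `pooled` row.
#' @export
evaluate_by_center <- function(model, cohort,
                               na_risk = default_config()$model$risk_n1_lo) {
  if (all(is.na(cohort$center))) stop("cohort has no center labels")
  groups <- c(split(seq_len(nrow(cohort)), cohort$center),
              list(pooled = seq_len(nrow(cohort))))
  used_na_risk <- FALSE
  rows <- lapply(names(groups), function(g) {
    dat <- cohort[groups[[g]], , drop = FALSE]
    truth <- binarize_endpoint(dat$ptwbs)
    pr <- predict(model, dat, type = "all")
    if (anyNA(pr$risk)) {
      used_na_risk <<- TRUE
      pr$risk[is.na(pr$risk)] <- na_risk
    }
    m <- confusion_metrics(pr$class, truth,
                           risks = if (length(unique(truth)) > 1L) pr$risk)
    data.frame(center = g, n = nrow(dat), prevalence = m$prevalence,
               accuracy = m$accuracy, ppv = m$ppv, npv = m$npv, auc = m$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (used_na_risk) attr(out, "na_risk") <- na_risk
  out
}

#' Full analysis pipeline
#'
#' The two-stage procedure: stability-based variable retention over
#' stratified bootstrap refits, then repeated stratified 70:30
#' cross-validation on the retained set, a final full-data tree, and (when
#' center labels are present) per-center evaluation of the final tree.
#' If no variable reaches the retention threshold the pipeline stops after
#' stage one and returns the frequency table.
#'
#' @param cohort A `tg_cohort`.
#' @param predictors Candidate predictors (default: canonical nine).
#' @param iterations Stage-one bootstrap refits (default 1000).
#' @param freq_threshold Retention threshold (default 0.95).
#' @param repeats Stage-two CV repeats (default 200).
#' @param train_fraction Stage-two training fraction (default 0.70).
#' @param seed Integer seed for both stages.
#' @param ... Fit parameters passed to [tgtree()].
#' @return A `tg_pipeline` list: `stability`, and (when the retained set is
#'   non-empty) `cv`, `final_tree`, `by_center`.
#' @export
run_pipeline <- function(cohort, predictors = tg_schema$predictors,
                         iterations = 1000L, freq_threshold = 0.95,
                         repeats = 200L, train_fraction = 0.70,
                         seed = 1L, ...) {
  seeds <- .derive_seeds(seed, 2L)
  st <- stability_selection(cohort, predictors, iterations = iterations,
                            freq_threshold = freq_threshold,
                            seed = seeds[1], ...)
  out <- list(stability = st, seed = seed)
  if (length(st$retained) == 0L) {
    warning("no variable reached the retention threshold; stopping after stage one")
    return(structure(out, class = "tg_pipeline"))
  }
  out$cv <- mc_cross_validate(cohort, st$retained, repeats = repeats,
                              train_fraction = train_fraction,
                              seed = seeds[2], ...)
  out$final_tree <- tgtree(stats::reformulate(st$retained, response = "ptwbs"),
                           data = cohort, ...)
  if (!all(is.na(cohort$center))) {
    out$by_center <- evaluate_by_center(out$final_tree, cohort)
  }
  structure(out, class = "tg_pipeline")
}

#' @export
print.tg_pipeline <- function(x, ...) {
  print(x$stability)
  if (!is.null(x$cv)) { cat("\n"); print(x$cv) }
  if (!is.null(x$final_tree)) { cat("\nfinal full-data tree:\n"); print(x$final_tree) }
  if (!is.null(x$by_center)) { cat("\nper-center evaluation:\n"); print(x$by_center) }
  invisible(x)
}
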