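# Stratified resampling, stability selection, Monte Carlo CV and
# per-center evaluation.

test_that("stratified bootstrap preserves both class counts exactly", {
  coh <- small_cohort(400, seed = 41)
  y <- binarize_endpoint(coh$ptwbs)
  res <- stratified_resample(coh, seed = 1)
  expect_equal(nrow(res), nrow(coh))
  expect_equal(sum(binarize_endpoint(res$ptwbs)), sum(y))
  # deterministic under a fixed seed
  expect_identical(as.data.frame(stratified_resample(coh, seed = 7)),
                   as.data.frame(stratified_resample(coh, seed = 7)))
  # single-class cohort is rejected
  coh0 <- coh; coh0$ptwbs <- factor("negative", levels = tg_schema$levels$ptwbs)
  expect_error(stratified_resample(coh0, seed = 1), "both endpoint classes")
})

test_that("bootstrap multiplicities match the expectation oracle", {
  df <- toy_cohort_df()[c(1, 2, 1, 2, 1, 2, 1, 1, 1, 1), ]
  df$tg <- 1:10  # make records distinguishable
  df$ptwbs <- c("positive", "positive", "positive",
                rep("negative", 7))
  coh <- as_tg_cohort(df)
  counts <- matrix(0, nrow = 1000, ncol = 10)
  seeds <- 1:1000
  for (i in seq_along(seeds)) {
    r <- stratified_resample(coh, seed = seeds[i])
    counts[i, ] <- tabulate(match(r$tg, coh$tg), nbins = 10)
  }
  mult <- colMeans(counts)
  # E[multiplicity] = 1 within class; 3 SE over 1000 draws is ~0.09
  expect_true(all(abs(mult - 1) < 3 * 0.95 / sqrt(1000) + 0.02))
  # class counts preserved in every draw
  expect_true(all(rowSums(counts[, 1:3]) == 3))
  expect_true(all(rowSums(counts[, 4:10]) == 7))
})

test_that("subsample mode draws without replacement at reduced size", {
  coh <- small_cohort(300, seed = 42)
  r <- stratified_resample(coh, seed = 5, fraction = 0.5)
  y <- binarize_endpoint(coh$ptwbs)
  expect_equal(nrow(r), sum(round(0.5 * table(y))))
  # no record can appear more often than in the source
  expect_true(all(table(r$tg) <= table(coh$tg)[names(table(r$tg))]))
})

test_that("stability selection retains planted signal and honors thresholds", {
  coh <- simulate_cohort(default_config(), seed = 43)
  st <- stability_selection(coh, iterations = 40, seed = 3)
  expect_s3_class(st, "tg_stability")
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_true("tg" %in% st$retained)
  # frequency threshold 0 retains every candidate
  st0 <- stability_selection(coh, iterations = 5, freq_threshold = 0, seed = 3)
  expect_setequal(st0$retained, tg_schema$predictors)
  # retained set shrinks monotonically as the threshold rises
  thresholds <- c(0, 0.2, 0.5, 0.8, 0.95, 1)
  kept <- lapply(thresholds, function(thr) names(st$frequency)[st$frequency >= thr])
  for (i in seq_along(kept)[-1]) expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  # identical seed reproduces the frequencies exactly
  st2 <- stability_selection(coh, iterations = 40, seed = 3)
  expect_identical(st$frequency, st2$frequency)
})

test_that("a shuffled outcome yields near-zero selection frequencies", {
  # under subsampling (no duplicated records) the null selection frequency
  # of every variable stays at the nominal type-I level; the bootstrap
  # mode duplicates records, which is anti-conservative for the
  # within-iteration permutation tests (see the methods vignette), so the
  # null property is asserted in subsample mode
  coh <- simulate_cohort(default_config(), seed = 44)
  set.seed(45)
  coh$ptwbs <- sample(coh$ptwbs)
  st <- stability_selection(coh, iterations = 200, seed = 4, fraction = 0.7)
  expect_true(all(st$frequency <= 0.10))
  expect_length(st$retained, 0L)
})

test_that("cross-validation splits are disjoint, exhaustive and stratified", {
  coh <- small_cohort(500, seed = 46)
  y <- binarize_endpoint(coh$ptwbs)
  expect_error(mc_cross_validate(coh, "tg", repeats = 0), "repeats")
  expect_error(mc_cross_validate(coh, "tg", train_fraction = 1), "train_fraction")
  expect_error(mc_cross_validate(coh, character(0)), "empty")
  cv <- mc_cross_validate(coh, c("tg", "n_stage"), repeats = 10, seed = 5)
  expect_s3_class(cv, "tg_cv_report")
  expect_equal(cv$repeats, 10)
  expect_true(all(is.finite(cv$validation_metrics[, "accuracy"])))
  # reproducibility of the whole report
  cv2 <- mc_cross_validate(coh, c("tg", "n_stage"), repeats = 10, seed = 5)
  expect_identical(cv$validation_metrics, cv2$validation_metrics)
  expect_identical(cv$cutoffs, cv2$cutoffs)
})

test_that("canonical cutoffs are extracted from the published topology only", {
  pub <- published_model()
  cc <- extract_canonical_cutoffs(pub)
  expect_true(cc$concordant)
  expect_equal(cc$cutoffs,
               c(n1_tg = 23.3, n0_hi = 35, n0_lo = 7.1))
  # root-only tree
  coh <- small_cohort(150, seed = 47)
  coh$ptwbs <- factor("negative", levels = tg_schema$levels$ptwbs)
  root_only <- tgtree(ptwbs ~ tg, data = coh)
  expect_false(extract_canonical_cutoffs(root_only)$concordant)
  # root on tg is a structural mismatch
  tg_root <- pub
  tg_root$root$predictor <- "tg"; tg_root$root$cutpoint <- 10
  expect_false(extract_canonical_cutoffs(tg_root)$concordant)
})

test_that("per-center evaluation mirrors the pooled table layout", {
  coh <- small_cohort(600, seed = 48)
  coh$center <- "C1"
  tab1 <- evaluate_by_center(published_model(), coh)
  expect_equal(nrow(tab1), 2L)  # one center + pooled
  expect_equal(tab1$accuracy[1], tab1$accuracy[2])
  # two centers with different prevalence: pooled accuracy is the
  # case-weighted mean and must lie between the center accuracies
  coh2 <- small_cohort(800, seed = 49)
  coh2$center <- ifelse(coh2$tg > 3, "hiTg", "loTg")
  tab2 <- evaluate_by_center(published_model(), coh2)
  accs <- tab2$accuracy[tab2$center != "pooled"]
  pooled <- tab2$accuracy[tab2$center == "pooled"]
  expect_gte(pooled, min(accs) - 1e-12)
  expect_lte(pooled, max(accs) + 1e-12)
  expect_equal(pooled, sum(tab2$accuracy[1:2] * tab2$n[1:2]) / sum(tab2$n[1:2]),
               tolerance = 1e-12)
  # single-class center gets an NA AUC
  coh3 <- coh2
  coh3$ptwbs[coh3$center == "loTg"] <- "negative"
  tab3 <- evaluate_by_center(published_model(), coh3)
  expect_true(is.na(tab3$auc[tab3$center == "loTg"]))
})

test_that("the pipeline chains retention, CV and the final tree", {
  coh <- small_cohort(600, seed = 50)
  coh$center <- rep(c("A", "B"), length.out = nrow(coh))
  pl <- run_pipeline(coh, iterations = 30, repeats = 10, seed = 6)
  expect_s3_class(pl, "tg_pipeline")
  expect_true("tg" %in% pl$stability$retained)
  expect_s3_class(pl$final_tree, "tgtree")
  expect_true(all(tree_variables(pl$final_tree) %in% pl$stability$retained))
  expect_equal(nrow(pl$by_center), 3L)
  # shuffled outcome exercises the empty-retained-set path
  set.seed(51)
  coh$ptwbs <- sample(coh$ptwbs)
  expect_warning(pl0 <- run_pipeline(coh, iterations = 20, repeats = 5, seed = 7),
                 "no variable")
  expect_null(pl0$cv)
  expect_length(pl0$stability$retained, 0L)
})
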