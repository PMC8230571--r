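# synthetic feature table with gaussian feature families
synth_table <- function(n_per, labels, shift = 0, seed = 1, p = 5) {
  set.seed(seed)
  rows <- sum(n_per)
  x <- matrix(rnorm(rows * p), rows, p)
  lab <- rep(labels, n_per)
  x[lab == labels[1], 1] <- x[lab == labels[1], 1] + shift
  df <- as.data.frame(x)
  names(df) <- c("sag_mv_m200", "tau_ms_m050", "spike_count_p300",
                 "ap_width_ms_p300", "freq01_hz_p300")[seq_len(p)]
  df$group_label <- lab
  df
}

test_that("fold assignment covers every row once with balanced sizes", {
  f <- make_folds(100, 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  f2 <- make_folds(92, 10, seed = 2)
  expect_length(f2, 92)
  expect_identical(as.vector(sort(table(f2), decreasing = TRUE)),
                   c(10L, 10L, rep(9L, 8)))
  expect_identical(make_folds(57, 10, seed = 9), make_folds(57, 10, seed = 9))
  # stratified folds keep every class in every training split
  labs <- rep(c("a", "b", "c"), times = c(30, 20, 10))
  fs <- make_folds(60, 10, seed = 3, labels = labs)
  for (k in 1:10)
    expect_setequal(unique(labs[fs != k]), c("a", "b", "c"))
})

test_that("a perfectly separating feature yields perfect accuracy", {
  df <- synth_table(c(20, 20), c("WT-10m", "AD-10m"), shift = 50, p = 1)
  labs <- split_group_label(df$group_label)$genotype
  for (kind in c("bagged", "boosted")) {
    r <- train_eval(df, labs, kind = kind, seed = 1)
    expect_equal(r$accuracy, 1.0)
    expect_identical(sum(r$confusion), 40L)
  }
})

test_that("held-out discipline: every row predicted exactly once, when held out", {
  df <- synth_table(c(15, 15), c("WT-10m", "AD-10m"), shift = 2)
  labs <- split_group_label(df$group_label)$genotype
  r <- train_eval(df, labs, "bagged", seed = 4)
  expect_identical(r$predictions$row, 1:30)
  expect_identical(sort(unique(r$predictions$fold)), 1:10)
  expect_identical(as.integer(sum(r$confusion)), 30L)
  # margins equal class counts
  expect_identical(as.integer(rowSums(r$confusion)),
                   as.integer(table(labs)))
  # determinism per seed
  r2 <- train_eval(df, labs, "bagged", seed = 4)
  expect_identical(r$predictions, r2$predictions)
  expect_identical(r$accuracy, r2$accuracy)
})

test_that("permuted labels score at chance over repeated seeds", {
  df <- synth_table(c(20, 20), c("WT-10m", "AD-10m"), shift = 3, seed = 8)
  correct <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(s)
    labs <- sample(split_group_label(df$group_label)$genotype)
    r <- train_eval(df, labs, "bagged", n_estimators = 50, seed = s)
    correct <- correct + sum(r$predictions$truth == r$predictions$predicted)
    total <- total + nrow(df)
  }
  ci <- qnorm(0.975) * sqrt(0.25 / total)
  expect_gt(correct / total, 0.5 - ci - 0.02)
  expect_lt(correct / total, 0.5 + ci + 0.02)
})

test_that("separable synthetic cohorts classify above chance", {
  co <- small_cohort(n = 10, seed = 17)
  ft <- extract_feature_table(co$cells)
  labs <- split_group_label(ft$group_label)$genotype
  r <- train_eval(ft, labs, "bagged", seed = 5)
  n_correct <- sum(r$predictions$truth == r$predictions$predicted)
  p <- binom.test(n_correct, nrow(ft), 0.5, alternative = "greater")$p.value
  expect_lt(p, 0.05)
  # two groups with identical generative specs are indistinguishable
  g <- default_group_specs(cv = 0.1)[["WT-10m"]]
  gA <- g; gA$label <- "WT-10m"; gA$n_cells <- 10
  gB <- g; gB$label <- "AD-10m"; gB$n_cells <- 10
  con <- generate_cohort(cohort_spec(list(gA, gB),
                                     amplitudes = c(-200, -50, 300),
                                     dt = 0.05, seed = 19))
  ftn <- extract_feature_table(con$cells)
  labn <- split_group_label(ftn$group_label)$genotype
  rn <- train_eval(ftn, labn, "bagged", seed = 6)
  nc <- sum(rn$predictions$truth == rn$predictions$predicted)
  ci <- binom.test(nc, nrow(ftn), 0.5)$conf.int
  expect_true(ci[1] <= 0.5 & 0.5 <= ci[2])
})

test_that("the standard task battery reports all six rows with chance levels", {
  set.seed(2)
  n <- c(8, 8, 8, 8, 8, 8)
  labs <- rep(c("WT-1m", "AD-1m", "WT-4m", "AD-4m", "WT-10m", "AD-10m"), n)
  df <- synth_table(n, unique(labs), seed = 3)
  df$group_label <- labs
  df$sag_mv_m200 <- df$sag_mv_m200 +
    2 * (split_group_label(labs)$genotype == "AD")
  res <- run_classification_tasks(df, seed = 1, folds = 4)
  expect_equal(nrow(res), 6)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_identical(res$chance, c(0.5, 0.5, 0.5, 0.5, 1 / 3, 1 / 3))
  expect_true(all(res$classifier %in% c("bagged", "boosted")))
})
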