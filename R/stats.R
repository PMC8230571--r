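#' Two-group comparison with normality-based test routing
#'
#' Shapiro-Wilk normality check per group at `alpha_normal`; when both
#' groups look normal an (equal-variance) two-sided t-test is used,
#' otherwise a two-sided Mann-Whitney rank-sum test. No multiplicity
#' correction is applied.
#'
#' @param a,b numeric samples (NA dropped; n >= 3 per group required)
#' @param feature,current,age metadata echoed into the result
#' @param alpha significance level (default 0.05)
#' @param alpha_normal routing level for the normality check
#' @param var_equal use the equal-variance t statistic (default TRUE)
#' @return one-row data.frame (`ComparisonResult` schema): feature,
#'   current_pA, age, test, statistic, p_value, means/sds/ns, normality
#'   flags, significance
#' @export
compare_groups <- function(a, b, feature = NA_character_,
                           current = NA_real_, age = NA_character_,
                           alpha = 0.05, alpha_normal = 0.05,
                           var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  base <- data.frame(feature = feature, current_pA = current, age = age,
                     test = NA_character_, statistic = NA_real_,
                     p_value = NA_real_,
                     mean_a = if (length(a)) mean(a) else NA_real_,
                     sd_a = if (length(a) > 1) sd(a) else NA_real_,
                     n_a = length(a),
                     mean_b = if (length(b)) mean(b) else NA_real_,
                     sd_b = if (length(b) > 1) sd(b) else NA_real_,
                     n_b = length(b),
                     normal_a = NA, normal_b = NA,
                     significant = NA, stringsAsFactors = FALSE)
  if (length(a) < 3 || length(b) < 3) {
    base$test <- "untestable"
    return(base)
  }
  normal_of <- function(x) {
    if (length(unique(x)) == 1) return(TRUE)   # degenerate: no evidence against
    if (length(x) > 5000) x <- sample(x, 5000)
    tryCatch(shapiro.test(x)$p.value >= alpha_normal,
             error = function(e) FALSE)
  }
  na <- normal_of(a); nb <- normal_of(b)
  base$normal_a <- na; base$normal_b <- nb
  if (na && nb) {
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      base$test <- "t"; base$statistic <- 0; base$p_value <- 1
    } else {
      tt <- t.test(a, b, var.equal = var_equal)
      base$test <- "t"
      base$statistic <- unname(tt$statistic)
      base$p_value <- tt$p.value
    }
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
    base$test <- "rank-sum"
    base$statistic <- unname(wt$statistic)
    base$p_value <- wt$p.value
  }
  base$significant <- base$p_value <= alpha
  base
}

.feature_current <- function(col) {
  m <- regmatches(col, regexpr("[mp][0-9]{3}$", col))
  if (length(m) == 0) return(NA_real_)
  sign <- if (substr(m, 1, 1) == "m") -1 else 1
  sign * as.numeric(substr(m, 2, 4))
}

#' Per-feature, per-current genotype comparison grid
#'
#' For every age group and every numeric feature column, compares the WT
#' and AD samples with [compare_groups()]. Each age is tested
#' independently; no multiple-comparison correction is applied.
#'
#' @param ft feature table with a `group_label` column
#' @param features feature columns (default: all numeric feature columns)
#' @param alpha significance level
#' @param ... passed to [compare_groups()]
#' @return data.frame of comparison rows (one per feature x age)
#' @export
run_comparison_grid <- function(ft, features = NULL, alpha = 0.05, ...) {
  empty <- compare_groups(numeric(0), numeric(0))[0, ]
  if (is.null(ft) || nrow(ft) == 0) return(empty)
  stopifnot("group_label" %in% names(ft))
  if (is.null(features)) {
    skip <- c("cell_id", "group_label", "rmp_excluded")
    features <- setdiff(names(ft)[vapply(ft, is.numeric, TRUE)], skip)
  }
  ga <- split_group_label(ft$group_label)
  rows <- list()
  for (age in unique(ga$age)) {
    wa <- ga$age == age & ga$genotype == "WT"
    ad <- ga$age == age & ga$genotype == "AD"
    if (!any(wa) || !any(ad)) next
    for (col in features) {
      rows[[length(rows) + 1L]] <- compare_groups(
        ft[wa, col], ft[ad, col], feature = col,
        current = .feature_current(col), age = age, alpha = alpha, ...)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
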