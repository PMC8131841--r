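#' Validation-cohort statistics
#'
#' Nonparametric statistics for the validation stage of a biomarker study:
#' Mann-Whitney group comparison (the plasma concentrations are strongly
#' right-skewed), median/quartile summaries, Spearman correlation against
#' clinical covariates, and repeated stratified cross-validated ROC analysis
#' of a univariate logistic classifier.
#'
#' @name group_stats
NULL

#' Construct a biomarker cohort
#'
#' @param values per-subject concentrations (finite, non-negative).
#' @param labels per-subject group labels (e.g. HD, preHD, HS, PP).
#' @param subject subject identifiers.
#' @param covariates optional data.frame of per-subject numeric covariates
#'   (age, disease duration, UHDRS, CAG).
#' @return data.frame of class `biomarker_cohort` with columns `subject`,
#'   `value`, `label` and any covariates.
#' @export
biomarker_cohort <- function(values, labels, subject = NULL,
                             covariates = NULL) {
  if (length(values) != length(labels))
    stop("values and labels must have the same length")
  if (any(!is.finite(values)) || any(values < 0))
    stop("cohort values must be finite and non-negative")
  if (any(is.na(labels) | !nzchar(labels)))
    stop("every subject must be labeled")
  out <- data.frame(
    subject = subject %||% sprintf("S%03d", seq_along(values)),
    value = as.numeric(values), label = as.character(labels),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(out))
    out <- cbind(out, covariates)
  }
  class(out) <- c("biomarker_cohort", "data.frame")
  out
}

#' Read a cohort CSV
#'
#' Columns `subject`, `value`, `label`; any further numeric columns are kept
#' as covariates.
#' @param path CSV file.
#' @return A `biomarker_cohort`.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject", "value", "label"))
    if (!col %in% names(tab)) stop("cohort CSV is missing column: ", col)
  extra <- setdiff(names(tab), c("subject", "value", "label"))
  biomarker_cohort(tab$value, tab$label, subject = tab$subject,
                   covariates = if (length(extra)) tab[extra] else NULL)
}

#' Write a cohort CSV
#' @param cohort a `biomarker_cohort`.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The exact permutation distribution is used
#' when `n_x * n_y <= 400` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. The computation is
#' delegated to [stats::wilcox.test()] with the branch chosen by this rule.
#'
#' @param x,y numeric samples (non-empty).
#' @return List with `U` (number of `(x, y)` pairs with `x > y`, ties
#'   counting one half), `p` (two-sided), and `exact` (which branch ran).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1, exact = FALSE))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- unname(wt$p.value)
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = min(1, p), exact = exact)
}

#' Median and quartiles
#'
#' @param x non-empty numeric vector.
#' @param type `"linear"` for linear-interpolation quantiles (position
#'   `(n - 1) * q` in the sorted sample, [stats::quantile()] type 7) or
#'   `"tukey"` for Tukey hinges ([stats::fivenum()]).
#' @return Named vector `(median, q1, q3)`.
#' @examples
#' median_quartiles(c(1, 2, 3, 4))  # 2.5, 1.75, 3.25
#' @export
median_quartiles <- function(x, type = c("linear", "tukey")) {
  type <- match.arg(type)
  if (length(x) == 0L) stop("x must be non-empty")
  if (type == "linear") {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  } else {
    fv <- stats::fivenum(x)
    q <- fv[c(3L, 2L, 4L)]
  }
  c(median = q[[1L]], q1 = q[[2L]], q3 = q[[3L]])
}

#' Spearman rank correlation
#'
#' Tie-aware rank correlation via [stats::cor.test()]; the p-value is exact
#' for `n <= 9` without ties and a t approximation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return List with `rho`, `p`, `n` and `defined` (`FALSE` when either
#'   vector is constant, in which case `rho` is `NA`).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 9 && !ties))
  )
  list(rho = unname(ct$estimate), p = min(1, unname(ct$p.value)), n = n,
       defined = TRUE)
}

#' Rank-based area under the ROC curve
#'
#' AUC of a score for a binary outcome by the rank (Mann-Whitney) identity:
#' the probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores numeric classifier scores.
#' @param positive logical (or 0/1) outcome per score.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified fold assignment: shuffles within each class, then deals folds
stratified_folds <- function(positive, folds) {
  fold <- integer(length(positive))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(positive == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated cross-validated ROC analysis of a univariate logistic classifier
#'
#' Fits `outcome ~ value` by logistic regression on each training split of a
#' repeated stratified k-fold partition and scores the held-out subjects.
#' Per fold it records the test AUC and, at a predicted-probability
#' threshold of 0.5, sensitivity and specificity. The summary `auc` is the
#' mean over all folds (aggregated with equal weight; small test folds make
#' per-fold metrics deliberately variable — that variability is part of what
#' the analysis reports at pilot sample sizes).
#'
#' @param cohort a [biomarker_cohort()] (or data.frame with `value`, `label`).
#' @param positive_classes labels counted as the positive (disease) class.
#' @param folds number of folds (default 3).
#' @param repeats number of independent fold partitions.
#' @param seed integer; identical seeds give identical results.
#' @return Object of class `cv_roc`: `auc` (mean fold AUC), `fold_metrics`
#'   (data.frame with repeat, fold, auc, sensitivity, specificity),
#'   `full_data_auc` (AUC of the model fit once to all subjects), `folds`,
#'   `repeats`, `seed`.
#' @export
cv_roc <- function(cohort, positive_classes, folds = 3L, repeats = 10L,
                   seed = NULL) {
  stopifnot(is.data.frame(cohort), all(c("value", "label") %in% names(cohort)))
  positive <- cohort$label %in% positive_classes
  if (!any(positive) || all(positive))
    stop("both classes must be present in the cohort")
  if (min(sum(positive), sum(!positive)) < folds)
    stop("a class has fewer members than folds; use fewer folds")
  value <- cohort$value

  full_fit <- suppressWarnings(
    stats::glm(positive ~ value, family = stats::binomial()))
  full_auc <- roc_auc(stats::predict(full_fit, type = "response"), positive)

  metrics <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(repeats), function(rep_i) {
      fold <- stratified_folds(positive, folds)
      do.call(rbind, lapply(seq_len(folds), function(f) {
        train <- fold != f
        fit <- suppressWarnings(
          stats::glm(positive[train] ~ value[train],
                     family = stats::binomial()))
        prob <- stats::plogis(stats::coef(fit)[[1L]] +
                                stats::coef(fit)[[2L]] * value[!train])
        truth <- positive[!train]
        pred_pos <- prob >= 0.5
        data.frame(
          rep = rep_i, fold = f,
          auc = if (any(truth) && any(!truth)) roc_auc(prob, truth)
                else NA_real_,
          sensitivity = if (any(truth)) mean(pred_pos[truth]) else NA_real_,
          specificity = if (any(!truth)) mean(!pred_pos[!truth]) else NA_real_
        )
      }))
    }))
  })
  structure(list(
    auc = mean(metrics$auc, na.rm = TRUE),
    fold_metrics = metrics,
    full_data_auc = full_auc,
    folds = as.integer(folds), repeats = as.integer(repeats), seed = seed
  ), class = "cv_roc")
}

#' @export
print.cv_roc <- function(x, ...) {
  cat(sprintf("Cross-validated univariate logistic ROC (%d-fold x %d repeats)\n",
              x$folds, x$repeats))
  cat(sprintf("  mean fold AUC = %.3f (fold range %.3f-%.3f)\n", x$auc,
              min(x$fold_metrics$auc, na.rm = TRUE),
              max(x$fold_metrics$auc, na.rm = TRUE)))
  cat(sprintf("  full-data AUC = %.3f\n", x$full_data_auc))
  cat(sprintf("  mean sensitivity %.3f / specificity %.3f at p = 0.5\n",
              mean(x$fold_metrics$sensitivity, na.rm = TRUE),
              mean(x$fold_metrics$specificity, na.rm = TRUE)))
  invisible(x)
}

#' Group summary table with Mann-Whitney p against a reference group
#'
#' Produces the conventional validation-cohort report: per-group median and
#' quartiles of the biomarker plus a two-sided Mann-Whitney p-value of each
#' group against the reference group.
#'
#' @param cohort a [biomarker_cohort()].
#' @param reference reference group label (e.g. healthy subjects).
#' @param type quantile convention, see [median_quartiles()].
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`,
#'   `p_vs_reference` (`NA` for the reference row).
#' @export
group_comparison <- function(cohort, reference, type = "linear") {
  stopifnot(is.data.frame(cohort), all(c("value", "label") %in% names(cohort)))
  if (!reference %in% cohort$label)
    stop("reference group '", reference, "' not present")
  groups <- unique(cohort$label)
  groups <- c(reference, setdiff(groups, reference))
  ref_values <- cohort$value[cohort$label == reference]
  do.call(rbind, lapply(groups, function(g) {
    v <- cohort$value[cohort$label == g]
    mq <- median_quartiles(v, type = type)
    data.frame(group = g, n = length(v), median = mq[["median"]],
               q1 = mq[["q1"]], q3 = mq[["q3"]],
               p_vs_reference = if (g == reference) NA_real_
                                else mann_whitney(v, ref_values)$p)
  }))
}
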