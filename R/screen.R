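#' Two-control differential-expression signature screen
#'
#' The exploratory stage of a case/two-control biomarker design: per-probe
#' fold changes and Welch t-tests of the case group against each control
#' group separately, with a probe declared a signature hit only when it
#' passes the fold-change and p-value gates against *both* controls in a
#' concordant direction and survives Benjamini-Hochberg false-discovery
#' control in both comparisons. The second control group (here, psychiatric
#' patients sharing the cases' medication) guards against treatment
#' confounding.
#'
#' @name screen
NULL

#' Construct an expression study
#'
#' @param matrix numeric probes x samples matrix with probe row names and
#'   sample column names.
#' @param groups named character vector mapping every sample to one of the
#'   three group labels.
#' @param labels length-3 character vector naming the case group and the two
#'   control groups, in that order.
#' @param log2_scale set `FALSE` if values are on the linear scale; they are
#'   then log2-transformed (requires positive values).
#' @return Object of class `expression_study`.
#' @export
expression_study <- function(matrix, groups,
                             labels = c("CASE", "CONTROL_A", "CONTROL_B"),
                             log2_scale = TRUE) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("probe_", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)))
    stop("expression matrix must have sample column names")
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (!log2_scale) {
    if (any(matrix <= 0)) stop("linear-scale values must be positive")
    matrix <- log2(matrix)
  }
  groups <- groups[colnames(matrix)]
  if (anyNA(groups))
    stop("every sample needs a group assignment")
  if (length(labels) != 3L)
    stop("labels must name the case group and two control groups")
  bad <- setdiff(unique(groups), labels)
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  sizes <- table(factor(groups, levels = labels))
  if (any(sizes < 2L))
    stop("each group needs at least 2 samples; sizes: ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  structure(list(matrix = matrix, groups = groups,
                 case = labels[[1L]], controls = labels[2:3]),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  sizes <- table(x$groups)
  cat(sprintf("Expression study: %d probes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

# vectorized Welch t-test of case vs one control group over all probe rows
welch_rows <- function(mat, case_cols, ctrl_cols) {
  na <- length(case_cols); nb <- length(ctrl_cols)
  xa <- mat[, case_cols, drop = FALSE]; xb <- mat[, ctrl_cols, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1  # constant probes carry no evidence
  list(log2fc = ma - mb, t = tstat, df = df, p = p)
}

# ratio >= 1 reported as +ratio, ratio < 1 as -1/ratio ("-1.5" = 1.5-fold down)
signed_fold_change <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Per-probe fold change and p-value for case vs one control group
#'
#' Fold change is `2^(mean case - mean control)` on the log2 scale, reported
#' in the signed linear convention (a ratio below 1 is reported as minus its
#' reciprocal, so 1.5-fold down prints as -1.5). The p-value is a Welch
#' two-sample t-test on the log2 values.
#'
#' @param study an [expression_study()].
#' @param control which control group to compare against (label, or 1/2).
#' @return data.frame with `probe`, `log2fc`, `fc` (signed linear), `t`,
#'   `df`, `p`, in the study's probe order.
#' @export
probe_stats <- function(study, control = 1L) {
  stopifnot(inherits(study, "expression_study"))
  if (is.numeric(control)) control <- study$controls[[control]]
  if (!control %in% study$controls)
    stop("'", control, "' is not a control group of this study")
  case_cols <- which(study$groups == study$case)
  ctrl_cols <- which(study$groups == control)
  w <- welch_rows(study$matrix, case_cols, ctrl_cols)
  data.frame(probe = rownames(study$matrix), log2fc = w$log2fc,
             fc = signed_fold_change(w$log2fc), t = w$t, df = w$df, p = w$p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' [stats::p.adjust()] kept as the screen's named gate.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen for an HD-specific two-control signature
#'
#' A probe is a hit iff, against *both* control groups: the absolute signed
#' fold change exceeds `fc_threshold`, the Welch p-value is below
#' `p_threshold`, the fold-change direction is concordant, and the
#' Benjamini-Hochberg q-value (computed per comparison across all probes) is
#' at most `fdr_threshold`.
#'
#' @param study an [expression_study()].
#' @param fc_threshold absolute signed linear fold-change gate (default 1.5).
#' @param p_threshold per-comparison p-value gate (default 0.05).
#' @param fdr_threshold per-comparison BH q-value gate (default 0.25).
#' @return data.frame of class `signature_hits`, sorted by the worse of the
#'   two p-values: `probe`, `fc_vs_a`, `p_vs_a`, `q_vs_a`, `fc_vs_b`,
#'   `p_vs_b`, `q_vs_b`, `q` (max of the two q-values), `direction`.
#' @export
screen_signature <- function(study, fc_threshold = 1.5, p_threshold = 0.05,
                             fdr_threshold = 0.25) {
  stopifnot(inherits(study, "expression_study"))
  sa <- probe_stats(study, 1L)
  sb <- probe_stats(study, 2L)
  qa <- bh_fdr(sa$p)
  qb <- bh_fdr(sb$p)
  hit <- abs(sa$fc) > fc_threshold & abs(sb$fc) > fc_threshold &
    sa$p < p_threshold & sb$p < p_threshold &
    sign(sa$fc) == sign(sb$fc) &
    qa <= fdr_threshold & qb <= fdr_threshold
  out <- data.frame(
    probe = sa$probe, fc_vs_a = sa$fc, p_vs_a = sa$p, q_vs_a = qa,
    fc_vs_b = sb$fc, p_vs_b = sb$p, q_vs_b = qb,
    q = pmax(qa, qb),
    direction = ifelse(sa$fc >= 0, "up", "down"),
    row.names = NULL
  )[hit, , drop = FALSE]
  out <- out[order(pmax(out$p_vs_a, out$p_vs_b)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_hits", "data.frame")
  attr(out, "thresholds") <- c(fc = fc_threshold, p = p_threshold,
                               fdr = fdr_threshold)
  out
}

#' Read an expression study from TSV files
#'
#' The expression file has probe identifiers in the first column and one
#' column per sample; the groups file has columns `sample` and `group`.
#'
#' @param expr_path,groups_path file paths.
#' @param ... passed to [expression_study()] (e.g. `labels`, `log2_scale`).
#' @return An `expression_study`.
#' @export
read_expression_study <- function(expr_path, groups_path, ...) {
  expr <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  rownames(mat) <- expr[[1L]]
  grp <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in c("sample", "group"))
    if (!col %in% names(grp)) stop("groups file is missing column: ", col)
  groups <- stats::setNames(grp$group, grp$sample)
  expression_study(mat, groups, ...)
}

#' Write an expression study to TSV files
#'
#' @param study an `expression_study`.
#' @param expr_path,groups_path output paths.
#' @export
write_expression_study <- function(study, expr_path, groups_path) {
  stopifnot(inherits(study, "expression_study"))
  tab <- data.frame(probe = rownames(study$matrix), study$matrix,
                    check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(study$groups), group = unname(study$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}
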