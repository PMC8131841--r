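#' Droplet digital PCR quantification
#'
#' In droplet digital PCR a reaction is partitioned into ~20,000 droplets,
#' each read out as positive (contains at least one template copy) or
#' negative. If copies land in droplets as a Poisson process with mean
#' `lambda` copies per droplet, the positive fraction is `p = 1 - exp(-lambda)`,
#' so `lambda = -log(1 - p)` inverts the saturation and the absolute
#' concentration is `lambda / droplet volume` in copies per microliter of
#' PCR mixture.
#'
#' @name ddpcr
NULL

# Default droplet volume in microliters (0.85 nL). The reader hardware does
# not report it; it is a multiplicative constant, so within-study comparisons
# are invariant to the exact value.
DEFAULT_DROPLET_VOLUME_UL <- 0.00085

#' Construct a droplet panel
#'
#' @param positives number of positive droplets `k`.
#' @param total total accepted droplets `m` (> 0, `k <= m`).
#' @param well_id well label.
#' @param droplet_volume_ul droplet volume in microliters.
#' @return Object of class `droplet_panel`.
#' @export
droplet_panel <- function(positives, total, well_id = "A01",
                          droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL) {
  stopifnot(length(positives) == 1L, length(total) == 1L)
  if (total <= 0 || total != round(total))
    stop("total droplet count must be a positive integer")
  if (positives < 0 || positives > total || positives != round(positives))
    stop("positives must be an integer in [0, total]")
  if (droplet_volume_ul <= 0) stop("droplet volume must be positive")
  structure(list(well_id = as.character(well_id),
                 positives = as.integer(positives),
                 total = as.integer(total),
                 droplet_volume_ul = droplet_volume_ul),
            class = "droplet_panel")
}

#' @export
print.droplet_panel <- function(x, ...) {
  cat(sprintf("ddPCR panel %s: %d / %d droplets positive\n",
              x$well_id, x$positives, x$total))
  invisible(x)
}

#' Poisson absolute quantification of a droplet panel
#'
#' Estimates the mean copies per droplet `lambda = -log(1 - k/m)` and the
#' concentration `lambda / droplet volume` in copies per microliter of PCR
#' mixture. The 95% confidence interval is the exact (Clopper-Pearson)
#' binomial interval on the positive fraction, propagated through the
#' monotone Poisson inversion; it is valid at `k = 0` (zero estimate,
#' positive upper bound) and near saturation. A fully saturated panel
#' (`k = m`) flags `saturated` and reports an infinite point estimate and
#' upper bound with a finite lower bound.
#'
#' @param panel a [droplet_panel()].
#' @param conf_level confidence level for the interval.
#' @return Object of class `mir_quant`: `lambda_per_droplet`,
#'   `copies_per_ul`, `ci95` (length-2 vector on the copies/ul scale),
#'   `saturated`, plus the inputs.
#' @examples
#' quantify(droplet_panel(2000, 20000))  # lambda = -log(0.9), ~124 copies/ul
#' @export
quantify <- function(panel, conf_level = 0.95) {
  stopifnot(inherits(panel, "droplet_panel"))
  k <- panel$positives; m <- panel$total; v <- panel$droplet_volume_ul
  p_hat <- k / m
  saturated <- k == m
  lambda <- if (saturated) Inf else -log1p(-p_hat)
  alpha <- 1 - conf_level
  p_lo <- if (k == 0L) 0 else stats::qbeta(alpha / 2, k, m - k + 1)
  p_hi <- if (k == m) 1 else stats::qbeta(1 - alpha / 2, k + 1, m - k)
  lam_lo <- -log1p(-p_lo)
  lam_hi <- if (p_hi >= 1) Inf else -log1p(-p_hi)
  structure(list(
    lambda_per_droplet = lambda,
    copies_per_ul = lambda / v,
    ci95 = c(low = lam_lo / v, high = lam_hi / v),
    saturated = saturated,
    positives = k, total = m, droplet_volume_ul = v,
    conf_level = conf_level
  ), class = "mir_quant")
}

#' @export
print.mir_quant <- function(x, ...) {
  cat(sprintf("ddPCR quantification: %d/%d positive droplets\n",
              x$positives, x$total))
  if (x$saturated)
    cat(sprintf("  saturated panel; copies/ul >= %.4g (lower %g%% bound)\n",
                x$ci95[["low"]], 100 * x$conf_level))
  else
    cat(sprintf("  lambda = %.6g copies/droplet; %.4g copies/ul (%g%% CI %.4g-%.4g)\n",
                x$lambda_per_droplet, x$copies_per_ul, 100 * x$conf_level,
                x$ci95[["low"]], x$ci95[["high"]]))
  invisible(x)
}

#' Quantify several wells of the same target as one pooled panel
#'
#' Sums positives and totals across wells and applies [quantify()]; exactly
#' equivalent to quantifying the pooled panel. All wells must share one
#' droplet volume, since pooling counts across different partition volumes
#' has no single Poisson inversion.
#'
#' @param panels list of [droplet_panel()] objects.
#' @param conf_level confidence level.
#' @return A `mir_quant` for the pooled counts.
#' @export
quantify_merged <- function(panels, conf_level = 0.95) {
  stopifnot(length(panels) > 0L,
            all(vapply(panels, inherits, TRUE, "droplet_panel")))
  vols <- vapply(panels, `[[`, 0, "droplet_volume_ul")
  if (length(unique(vols)) != 1L)
    stop("cannot merge panels with different droplet volumes")
  pooled <- droplet_panel(
    positives = sum(vapply(panels, `[[`, 0L, "positives")),
    total = sum(vapply(panels, `[[`, 0L, "total")),
    well_id = "pooled", droplet_volume_ul = vols[[1L]]
  )
  quantify(pooled, conf_level = conf_level)
}

#' Read droplet counts from CSV
#'
#' Expects columns `well`, `positives`, `total` and optionally `target`.
#'
#' @param path CSV file.
#' @param droplet_volume_ul droplet volume applied to every well.
#' @return List of `droplet_panel` objects, named by well; the optional
#'   `target` column is attached as an attribute for merging.
#' @export
read_droplet_csv <- function(path,
                             droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL) {
  if (!file.exists(path)) stop("no such droplet CSV: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("well", "positives", "total"))
    if (!col %in% names(tab)) stop("droplet CSV is missing column: ", col)
  panels <- lapply(seq_len(nrow(tab)), function(i)
    droplet_panel(tab$positives[i], tab$total[i], well_id = tab$well[i],
                  droplet_volume_ul = droplet_volume_ul))
  names(panels) <- tab$well
  attr(panels, "target") <- if ("target" %in% names(tab)) tab$target else NULL
  panels
}

#' Quantify a droplet CSV well-by-well
#'
#' @param path input CSV (see [read_droplet_csv()]).
#' @param droplet_volume_ul droplet volume.
#' @param merge_by_target if `TRUE` and a `target` column is present, wells
#'   of the same target are pooled with [quantify_merged()].
#' @return data.frame with the input columns plus `lambda`, `copies_per_ul`,
#'   `ci_low`, `ci_high`, `saturated`.
#' @export
quantify_csv <- function(path, droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                         merge_by_target = FALSE) {
  panels <- read_droplet_csv(path, droplet_volume_ul)
  targets <- attr(panels, "target")
  if (merge_by_target) {
    if (is.null(targets)) stop("merge_by_target requires a 'target' column")
    groups <- split(panels, targets)
    res <- lapply(groups, quantify_merged)
    out <- data.frame(target = names(groups),
                      positives = vapply(groups, function(g)
                        sum(vapply(g, `[[`, 0L, "positives")), 0),
                      total = vapply(groups, function(g)
                        sum(vapply(g, `[[`, 0L, "total")), 0))
  } else {
    res <- lapply(panels, quantify)
    out <- data.frame(well = names(panels),
                      positives = vapply(panels, `[[`, 0L, "positives"),
                      total = vapply(panels, `[[`, 0L, "total"))
    if (!is.null(targets)) out$target <- targets
  }
  out$lambda <- vapply(res, `[[`, 0, "lambda_per_droplet")
  out$copies_per_ul <- vapply(res, `[[`, 0, "copies_per_ul")
  out$ci_low <- vapply(res, function(r) r$ci95[["low"]], 0)
  out$ci_high <- vapply(res, function(r) r$ci95[["high"]], 0)
  out$saturated <- vapply(res, `[[`, TRUE, "saturated")
  rownames(out) <- NULL
  out
}
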