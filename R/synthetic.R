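#' Seeded synthetic-data generators
#'
#' Each generator emulates the statistical structure one pipeline stage
#' assumes, so every stage can be exercised end-to-end without external
#' downloads: binomially thinned droplet panels for the Poisson
#' quantification, log-normal plasma concentrations for the group
#' statistics, a probes-x-samples matrix with planted case effects for the
#' signature screen, and random directed multigraph interactomes with a
#' tunable excess of set1-to-set2 links for the overconnectivity test.
#' All generators are pure functions of their arguments and seed.
#'
#' @name synthetic
NULL

#' Simulate a droplet panel
#'
#' Droplet occupancy is Poisson with mean `true_lambda` copies per droplet,
#' so each of the `m` droplets is positive independently with probability
#' `1 - exp(-true_lambda)` and the positive count is binomial.
#'
#' @param true_lambda true mean copies per droplet (>= 0).
#' @param m number of droplets (default 20000, a typical accepted-droplet
#'   count).
#' @param seed integer seed.
#' @param droplet_volume_ul droplet volume.
#' @param well_id well label.
#' @return A [droplet_panel()].
#' @export
gen_droplets <- function(true_lambda, m = 20000L, seed = NULL,
                         droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                         well_id = "sim") {
  stopifnot(true_lambda >= 0, m > 0)
  k <- with_seed(seed, stats::rbinom(1L, m, 1 - exp(-true_lambda)))
  droplet_panel(k, m, well_id = well_id,
                droplet_volume_ul = droplet_volume_ul)
}

#' Simulate a biomarker cohort
#'
#' Per-subject concentrations are log-normal around each group's target
#' median: `value = exp(Normal(log(median), sigma_log))`, so the group
#' median equals the target in expectation and the distribution carries the
#' right-skew typical of plasma miRNA levels. The default group structure
#' mirrors a validation cohort of 26 manifest HD, 7 premanifest carriers,
#' 25 healthy and 24 psychiatric controls with medians 4.1, 5.8, 0.69 and
#' 1.4 copies/ul.
#'
#' @param group_medians named numeric vector of target medians (> 0).
#' @param group_sizes named integer vector, same names.
#' @param sigma_log log-scale standard deviation (default 1.2, chosen so the
#'   simulated quartile spread matches the several-fold interquartile ranges
#'   seen in plasma miRNA cohorts).
#' @param seed integer seed.
#' @return A [biomarker_cohort()].
#' @export
gen_cohort <- function(group_medians = c(HD = 4.1, preHD = 5.8, HS = 0.69,
                                         PP = 1.4),
                       group_sizes = c(HD = 26L, preHD = 7L, HS = 25L,
                                       PP = 24L),
                       sigma_log = 1.2, seed = NULL) {
  stopifnot(all(group_medians > 0), all(group_sizes >= 1),
            setequal(names(group_medians), names(group_sizes)))
  group_sizes <- group_sizes[names(group_medians)]
  with_seed(seed, {
    labels <- rep(names(group_sizes), group_sizes)
    values <- exp(stats::rnorm(length(labels),
                               mean = log(group_medians[labels]),
                               sd = sigma_log))
    biomarker_cohort(values, labels)
  })
}

#' Simulate a three-group expression study with planted signature probes
#'
#' Baseline probe means are Normal(7, 1) on the log2 scale with i.i.d.
#' Normal noise per sample. A planted probe has a log2 case effect relative
#' to each control group: the case group is shifted by `effect_a`, and the
#' second control group is shifted by `effect_a - effect_b`, which realizes
#' case-minus-A `= effect_a` and case-minus-B `= effect_b` simultaneously.
#'
#' @param n_probes number of probes.
#' @param group_sizes length-3 vector: case and two control group sizes
#'   (default 9, 8, 5, the exploratory-cohort layout).
#' @param planted data.frame with columns `probe` (row index), `effect_a`,
#'   `effect_b` (log2 effects vs each control); `NULL` for a null study.
#' @param noise_sd per-sample log2 noise standard deviation (default 0.5, a
#'   typical between-subject spread for plasma arrays).
#' @param seed integer seed.
#' @param labels group labels, case first.
#' @return An [expression_study()]; the planting table is attached as
#'   attribute `"planted"`.
#' @export
gen_expression <- function(n_probes = 500L, group_sizes = c(9L, 8L, 5L),
                           planted = NULL, noise_sd = 0.5, seed = NULL,
                           labels = c("CASE", "CONTROL_A", "CONTROL_B")) {
  stopifnot(length(group_sizes) == 3L, all(group_sizes >= 2L))
  if (!is.null(planted)) {
    stopifnot(all(c("probe", "effect_a", "effect_b") %in% names(planted)))
    if (any(planted$probe < 1L | planted$probe > n_probes))
      stop("planted probe index out of range")
  }
  n_samples <- sum(group_sizes)
  groups <- rep(labels, group_sizes)
  with_seed(seed, {
    baseline <- stats::rnorm(n_probes, mean = 7, sd = 1)
    mat <- matrix(baseline, n_probes, n_samples) +
      matrix(stats::rnorm(n_probes * n_samples, sd = noise_sd),
             n_probes, n_samples)
    if (!is.null(planted)) {
      case_cols <- groups == labels[[1L]]
      b_cols <- groups == labels[[3L]]
      for (i in seq_len(nrow(planted))) {
        p <- planted$probe[i]
        mat[p, case_cols] <- mat[p, case_cols] + planted$effect_a[i]
        mat[p, b_cols] <- mat[p, b_cols] +
          (planted$effect_a[i] - planted$effect_b[i])
      }
    }
    rownames(mat) <- sprintf("probe_%04d", seq_len(n_probes))
    colnames(mat) <- sprintf("s%02d", seq_len(n_samples))
    study <- expression_study(mat, stats::setNames(groups, colnames(mat)),
                              labels = labels)
    attr(study, "planted") <- planted
    study
  })
}

#' Simulate a directed interactome with two gene sets
#'
#' Edge endpoints are uniform over the gene universe, except that the
#' probability mass of the set1-source/set2-target cell is multiplied by
#' `enrichment`, planting an excess of set1-to-set2 links (`enrichment = 1`
#' is the null). Each edge is labeled `transcription_regulation` with
#' probability `txreg_fraction` and `binding` otherwise. The network is
#' returned as a multigraph (no deduplication), so the background `N` equals
#' `n_edges`. The two sets are sampled disjointly.
#'
#' @param n_genes,n_edges universe and network size.
#' @param set1_size,set2_size sizes of the two disjoint sets.
#' @param enrichment multiplicative weight (>= 1) on set1-to-set2 edges.
#' @param txreg_fraction fraction of transcription-regulation edges.
#' @param seed integer seed.
#' @return List with `network` (an `interaction_network`), `set1`, `set2`
#'   (`gene_set`s), and `truth` (the generator parameters).
#' @export
gen_network <- function(n_genes = 500L, n_edges = 2000L, set1_size = 50L,
                        set2_size = 50L, enrichment = 1, txreg_fraction = 0.5,
                        seed = NULL) {
  stopifnot(enrichment >= 1, txreg_fraction >= 0, txreg_fraction <= 1)
  if (set1_size + set2_size > n_genes)
    stop("set sizes exceed the gene universe")
  genes <- sprintf("G%05d", seq_len(n_genes))
  with_seed(seed, {
    picked <- sample(genes, set1_size + set2_size)
    s1 <- picked[seq_len(set1_size)]
    s2 <- picked[set1_size + seq_len(set2_size)]
    p12 <- (set1_size / n_genes) * (set2_size / n_genes)
    w12 <- enrichment * p12 / (enrichment * p12 + (1 - p12))
    in_cell <- stats::runif(n_edges) < w12
    n1 <- sum(in_cell)
    src <- tgt <- character(n_edges)
    src[in_cell] <- sample(s1, n1, replace = TRUE)
    tgt[in_cell] <- sample(s2, n1, replace = TRUE)
    # remaining edges: uniform endpoint pairs outside the set1->set2 cell
    need <- which(!in_cell)
    while (length(need) > 0L) {
      u <- sample(genes, length(need), replace = TRUE)
      v <- sample(genes, length(need), replace = TRUE)
      ok <- !(u %in% s1 & v %in% s2)
      src[need[ok]] <- u[ok]
      tgt[need[ok]] <- v[ok]
      need <- need[!ok]
    }
    mech <- ifelse(stats::runif(n_edges) < txreg_fraction,
                   "transcription_regulation", "binding")
    list(
      network = interaction_network(
        data.frame(source = src, target = tgt, mechanism = mech,
                   stringsAsFactors = FALSE),
        dedup = FALSE),
      set1 = gene_set(s1, "set1"),
      set2 = gene_set(s2, "set2"),
      truth = list(n_genes = n_genes, n_edges = n_edges,
                   enrichment = enrichment,
                   txreg_fraction = txreg_fraction)
    )
  })
}
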