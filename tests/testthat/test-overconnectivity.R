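test_that("hypergeometric tail matches the combinatorial sum oracle", {
  expect_identical(hypergeometric_sf(0, 100, 10, 10), 1)
  expect_equal(hypergeometric_sf(2, 10, 4, 3), oracle_hyper_sf(2, 10, 4, 3),
               tolerance = 1e-14)

  # exhaustive scan over small populations, upper and lower tails
  for (N in c(1, 5, 12, 25)) {
    for (R in 0:N) for (n in seq(0, N, by = max(1, N %/% 5))) {
      for (x in max(0, n + R - N):min(R, n)) {
        expect_lt(abs(hypergeometric_sf(x, N, R, n) -
                        oracle_hyper_sf(x, N, R, n)), 1e-12)
        expect_lt(abs(hypergeometric_sf(x, N, R, n, lower_tail = TRUE) -
                        oracle_hyper_cdf(x, N, R, n)), 1e-12)
      }
    }
  }
  # outside the support
  expect_identical(hypergeometric_sf(0, 10, 4, 3), 1)
  expect_identical(hypergeometric_sf(4, 10, 4, 3), 0)
  expect_error(hypergeometric_sf(1, 10, 11, 3), "<= N")
})

test_that("log-space tail agrees with stats::phyper at large scale", {
  set.seed(21)
  for (i in 1:25) {
    N <- sample(1e4:1e6, 1)
    R <- sample.int(N, 1)
    n <- sample.int(N, 1)
    x <- sample(max(0, n + R - N):min(R, n), 1)
    expect_equal(hypergeometric_sf(x, N, R, n),
                 phyper(x - 1, R, N - R, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("overconnectivity result satisfies its algebraic invariants", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(20:2000, 1)
    R <- sample.int(N - 1, 1)
    n <- sample.int(N - 1, 1)
    a <- sample(max(0, n + R - N):min(R, n), 1)
    res <- overconnectivity_test(link_counts(a, R, n, N))
    expect_equal(res$exp, n * R / N)
    expect_equal(res$ratio * res$exp, a, tolerance = 1e-9)
    if (!res$degenerate)
      expect_equal(sign(res$z), sign(a - res$exp))
    expect_identical(res$tail, if (a >= res$exp) "upper" else "lower")
    expect_true(res$p > 0 && res$p <= 1)
  }

  # upper-tail p is non-increasing in actual with margins fixed
  p <- vapply(0:10, function(a) hypergeometric_sf(a, 50, 12, 20), 0)
  expect_true(all(diff(p) <= 0))

  # null center: actual exactly at n*R/N
  res <- overconnectivity_test(link_counts(6, 12, 25, 50))  # 25*12/50 = 6
  expect_equal(res$z, 0)
  expect_equal(res$ratio, 1)
})

test_that("degenerate margins give a flagged, crash-free result", {
  res <- overconnectivity_test(link_counts(0, 0, 10, 50))
  expect_true(res$degenerate)
  expect_true(is.na(res$z))
  expect_equal(res$p, 1)
  res2 <- overconnectivity_test(link_counts(10, 50, 10, 50))  # R = N
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
})

test_that("report rounding follows the conventional table format", {
  res <- overconnectivity_test(link_counts(2516, 41663, 33446, 615471))
  rep <- overconnectivity_report(res)
  expect_equal(rep$Exp, 2264)
  expect_equal(rep$Ratio, 1.111)
  expect_equal(rep$z.score, 5.639)
  expect_equal(rep$P.value, 1.48e-08)
})

test_that("permutation null saturates under strong planted enrichment", {
  g <- gen_network(n_genes = 200, n_edges = 1500, set1_size = 40,
                   set2_size = 40, enrichment = 8, txreg_fraction = 1,
                   seed = 5)
  pn <- permutation_null(g$network, g$set1, g$set2,
                         mode = "transcription_regulation_only",
                         n_perm = 200, seed = 9)
  expect_equal(pn$p_empirical, 1 / 201)
  expect_equal(length(pn$null_actual), 200L)

  # seeded runs are reproducible
  pn2 <- permutation_null(g$network, g$set1, g$set2,
                          mode = "transcription_regulation_only",
                          n_perm = 200, seed = 9)
  expect_identical(pn$null_actual, pn2$null_actual)
  expect_identical(pn$p_empirical, pn2$p_empirical)

  expect_error(
    permutation_null(g$network, gene_set(paste0("X", 1:9999)), g$set2,
                     n_perm = 100),
    "universe")
})

test_that("empirical and analytic p-values agree across random instances", {
  # enrichment spans the null through twofold so the p-values spread over
  # their dynamic range; 5000 permutations keep the empirical floor
  # (1/(n_perm+1)) below most analytic p-values, since rank agreement is
  # uninformative among instances stuck at the floor
  set.seed(77)
  pa <- pe <- numeric(50)
  for (i in 1:50) {
    g <- gen_network(n_genes = 120, n_edges = 800, set1_size = 30,
                     set2_size = 30, enrichment = runif(1, 1, 2),
                     txreg_fraction = 1, seed = 1000 + i)
    obs <- overconnectivity_test(
      count_links(g$network, g$set1, g$set2,
                  "transcription_regulation_only"))
    pn <- permutation_null(g$network, g$set1, g$set2,
                           mode = "transcription_regulation_only",
                           n_perm = 5000, seed = 2000 + i)
    pa[i] <- obs$p
    pe[i] <- pn$p_empirical
  }
  expect_gt(cor(pa, pe, method = "spearman"), 0.9)
})

test_that("analytic null moments match the permutation null loosely", {
  # genes are permuted while the analytic model draws links conditional on
  # the observed margins, so agreement is approximate by construction:
  # |mean(null actual) - exp| below 0.5 sd on average over datasets
  ratio <- vapply(1:10, function(s) {
    g <- gen_network(n_genes = 150, n_edges = 1200, set1_size = 40,
                     set2_size = 40, enrichment = 1, txreg_fraction = 1,
                     seed = 16 + s)
    obs <- overconnectivity_test(
      count_links(g$network, g$set1, g$set2,
                  "transcription_regulation_only"))
    pn <- permutation_null(g$network, g$set1, g$set2,
                           mode = "transcription_regulation_only",
                           n_perm = 1000, seed = 116 + s)
    abs(mean(pn$null_actual) - obs$exp) / sd(pn$null_actual)
  }, 0)
  expect_lt(mean(ratio), 0.5)
})
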