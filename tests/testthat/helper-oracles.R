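# Independent brute-force oracles. These deliberately avoid the package's
# code paths: direct combinatorial sums, per-edge loops, quadratic step-up,
# full enumeration of label assignments.

# P(X >= x), X ~ Hypergeometric(N, R, n), by direct summation of choose()
oracle_hyper_sf <- function(x, N, R, n) {
  k_min <- max(0, n + R - N)
  k_max <- min(R, n)
  if (x <= k_min) return(1)
  if (x > k_max) return(0)
  k <- x:k_max
  sum(choose(R, k) * choose(N - R, n - k)) / choose(N, n)
}

# P(X <= x) by direct summation (avoids cancellation in 1 - upper tail)
oracle_hyper_cdf <- function(x, N, R, n) {
  k_min <- max(0, n + R - N)
  k_max <- min(R, n)
  if (x >= k_max) return(1)
  if (x < k_min) return(0)
  k <- k_min:x
  sum(choose(R, k) * choose(N - R, n - k)) / choose(N, n)
}

# per-edge classification loop over an edge data.frame
oracle_count_links <- function(edges, s1, s2, mode,
                               txreg_label = "transcription_regulation") {
  e1 <- new.env(hash = TRUE); for (g in s1) assign(g, TRUE, envir = e1)
  e2 <- new.env(hash = TRUE); for (g in s2) assign(g, TRUE, envir = e2)
  actual <- R <- n <- N <- 0L
  for (i in seq_len(nrow(edges))) {
    if (mode == "transcription_regulation_only" &&
        edges$mechanism[i] != txreg_label) next
    N <- N + 1L
    u <- edges$source[i]; v <- edges$target[i]
    u1 <- exists(u, envir = e1, inherits = FALSE)
    v1 <- exists(v, envir = e1, inherits = FALSE)
    u2 <- exists(u, envir = e2, inherits = FALSE)
    v2 <- exists(v, envir = e2, inherits = FALSE)
    if (mode == "all_interactions") {
      if (u1 || v1) R <- R + 1L
      if (u2 || v2) n <- n + 1L
      if ((u1 && v2) || (u2 && v1)) actual <- actual + 1L
    } else {
      if (u1) R <- R + 1L
      if (v2) n <- n + 1L
      if (u1 && v2) actual <- actual + 1L
    }
  }
  c(actual = actual, R = R, n = n, N = N)
}

# textbook quadratic-time Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  ord <- order(p)
  for (pos in seq_len(m)) {
    i <- ord[pos]
    # q_i = min over j with rank >= rank(i) of p_j * m / rank(j)
    best <- Inf
    for (pos2 in pos:m) {
      j <- ord[pos2]
      best <- min(best, p[j] * m / pos2)
    }
    q[i] <- min(1, best)
  }
  q
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  u_stat <- function(xi) sum(outer(pool[xi], pool[-xi], ">")) +
    0.5 * sum(outer(pool[xi], pool[-xi], "=="))
  combos <- utils::combn(nx + ny, nx)
  u_null <- apply(combos, 2, u_stat)
  u_obs <- u_stat(seq_len(nx))
  m <- ncol(combos)
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# a small random directed labeled multigraph for property tests
random_edges <- function(n_edges, n_genes,
                         mechs = c("binding", "transcription_regulation")) {
  genes <- paste0("g", seq_len(n_genes))
  data.frame(source = sample(genes, n_edges, replace = TRUE),
             target = sample(genes, n_edges, replace = TRUE),
             mechanism = sample(mechs, n_edges, replace = TRUE),
             stringsAsFactors = FALSE)
}
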