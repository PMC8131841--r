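test_that("edge-list reading deduplicates triples and keeps directions", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tmechanism",
               "A\tB\tbinding",
               "A\tB\tbinding",
               "B\tC\tbinding"), tsv)
  net <- read_edge_list(tsv, quiet = TRUE)
  expect_equal(net$n_links, 2L)
  expect_equal(net$n_raw, 3L)

  # both directions of a pair are distinct edges
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tmechanism",
               "A\tB\tbinding",
               "B\tA\tbinding"), tsv2)
  expect_equal(read_edge_list(tsv2, quiet = TRUE)$n_links, 2L)

  # multigraph mode keeps every record
  expect_equal(read_edge_list(tsv, dedup = FALSE, quiet = TRUE)$n_links, 3L)
})

test_that("retained edge count equals an independent set-of-triples count", {
  rows <- c("A\tB\tbinding", "A\tB\tbinding",          # exact duplicates
            "C\tD\tbinding", "C\tD\tbinding",
            "E\tF\tbinding", "E\tF\ttranscription_regulation",  # mech variants
            "G\tH\tbinding", "H\tG\tbinding",
            "A\tC\tbinding", "B\tD\tbinding")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tmechanism", rows), tsv)
  net <- read_edge_list(tsv, quiet = TRUE)
  expect_equal(net$n_links, length(unique(rows)))
})

test_that("edge-list errors distinguish configuration and input problems", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto\tmech", "A\tB\tx"), tsv)
  expect_error(read_edge_list(tsv, quiet = TRUE), "source")
  expect_silent(net <- read_edge_list(tsv, source_col = "from",
                                      target_col = "to",
                                      mechanism_col = "mech", quiet = TRUE))
  expect_equal(net$n_links, 1L)

  empty <- tempfile(fileext = ".tsv")
  writeLines("source\ttarget\tmechanism", empty)
  expect_error(read_edge_list(empty, quiet = TRUE), "no rows")
  expect_error(read_edge_list(tempfile(), quiet = TRUE), "no such")
})

test_that("column remapping can come from a YAML config file", {
  skip_if_not_installed("yaml")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto\tmech", "A\tB\tx", "B\tC\ty"), tsv)
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("source_col: from", "target_col: to", "mechanism_col: mech"),
             cfg)
  expect_equal(read_edge_list(tsv, config = cfg, quiet = TRUE)$n_links, 2L)
})

test_that("gene sets collapse duplicates with a count and read both formats", {
  plain <- tempfile(fileext = ".txt")
  writeLines(c("A", "B", "A"), plain)
  expect_warning(gs <- read_gene_set(plain), "1 duplicate")
  expect_setequal(gs$members, c("A", "B"))

  gmt <- tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tC", gmt)
  gs <- read_gene_set(gmt)
  expect_equal(gs$name, "S1")
  expect_setequal(gs$members, c("A", "B", "C"))

  # large fixture: member count equals an independent unique count
  set.seed(11)
  ids <- paste0("GENE", sample(1:483, 483))
  lines <- c(ids, sample(ids, 17))                # 17 duplicates, 500 lines
  big <- tempfile(fileext = ".txt")
  writeLines(sample(lines), big)
  expect_warning(gs <- read_gene_set(big), "17 duplicate")
  expect_equal(length(gs$members), length(unique(toupper(lines))))

  empty <- tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_warning(gs <- read_gene_set(empty), "no members")
  expect_equal(length(gs$members), 0L)
})

test_that("saturated and empty set link counts hit their closed forms", {
  set.seed(3)
  edges <- random_edges(40, 12)
  net <- interaction_network(edges, dedup = FALSE)
  all_genes <- gene_set(network_genes(net))
  cnt <- count_links(net, all_genes, all_genes, "all_interactions")
  expect_equal(cnt$actual, net$n_links)
  expect_equal(cnt$R, net$n_links)
  expect_equal(cnt$n, net$n_links)

  cnt0 <- count_links(net, gene_set(character(0)), all_genes)
  expect_equal(cnt0$actual, 0L)
  expect_equal(cnt0$R, 0L)

  empty_net <- interaction_network(
    data.frame(source = character(0), target = character(0),
               mechanism = character(0)))
  expect_error(count_links(empty_net, all_genes, all_genes), "empty network")
})

test_that("count_links matches the per-edge enumeration oracle (both modes)", {
  edges <- data.frame(
    source    = c("A", "A", "B", "C", "D", "E", "F", "A", "G", "B", "C", "C"),
    target    = c("D", "E", "D", "F", "A", "B", "G", "A", "G", "E", "D", "D"),
    mechanism = c("transcription_regulation", "binding",
                  "transcription_regulation", "binding", "binding",
                  "transcription_regulation", "binding", "binding",
                  "binding", "transcription_regulation",
                  "transcription_regulation", "binding"),
    stringsAsFactors = FALSE)
  net <- interaction_network(edges, dedup = FALSE)
  s1 <- gene_set(c("A", "B", "C"))
  s2 <- gene_set(c("D", "E", "F", "G"))
  for (mode in c("all_interactions", "transcription_regulation_only")) {
    got <- count_links(net, s1, s2, mode)
    want <- oracle_count_links(net$edges, s1$members, s2$members, mode)
    expect_equal(got$actual, unname(want["actual"]))
    expect_equal(got$R, unname(want["R"]))
    expect_equal(got$n, unname(want["n"]))
    expect_equal(got$N, unname(want["N"]))
  }
})

test_that("link-count bounds and swap symmetry hold over random graphs", {
  set.seed(101)
  for (i in 1:40) {
    n_genes <- sample(8:40, 1)
    edges <- random_edges(sample(10:200, 1), n_genes)
    net <- interaction_network(edges, dedup = sample(c(TRUE, FALSE), 1))
    genes <- network_genes(net)
    k1 <- sample.int(min(6, length(genes)), 1)
    k2 <- sample.int(min(6, length(genes) - k1), 1)
    picked <- sample(genes, k1 + k2)       # disjoint sets
    s1 <- gene_set(picked[seq_len(k1)])
    s2 <- gene_set(picked[k1 + seq_len(k2)])
    for (mode in c("all_interactions", "transcription_regulation_only")) {
      cnt <- count_links(net, s1, s2, mode)
      expect_true(cnt$actual >= max(0, cnt$n + cnt$R - cnt$N))
      expect_true(cnt$actual <= min(cnt$R, cnt$n))
      expect_true(max(cnt$R, cnt$n) <= cnt$N)
      want <- oracle_count_links(net$edges, s1$members, s2$members, mode)
      expect_equal(cnt$actual, unname(want["actual"]))
    }
    # symmetrized mode: swapping the sets swaps the margins, actual invariant
    a <- count_links(net, s1, s2, "all_interactions")
    b <- count_links(net, s2, s1, "all_interactions")
    expect_equal(a$actual, b$actual)
    expect_equal(a$R, b$n)
    expect_equal(a$n, b$R)
  }
})

test_that("edge-list write and re-read preserves N and the edge multiset", {
  set.seed(7)
  net <- interaction_network(random_edges(60, 15), dedup = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  net2 <- read_edge_list(path, quiet = TRUE)
  expect_equal(net2$n_links, net$n_links)
  key <- function(e) sort(paste(e$source, e$target, e$mechanism))
  expect_equal(key(net2$edges), key(net$edges))

  gs <- gene_set(c("A", "B", "C"), name = "S1")
  for (fmt in c("plain", "gmt")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_gene_set(gs, p, fmt)
    expect_equal(read_gene_set(p, format = fmt)$members, gs$members)
  }
})
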