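#' Directed interaction networks and gene sets
#'
#' A directed interaction network is the background "database" against which
#' link overconnectivity is assessed: a multiset of directed, mechanism-labeled
#' edges between gene identifiers (for example the BioGRID interactions of a
#' gene of interest). The total number of retained links defines the
#' background size `N` of the hypergeometric model.
#'
#' @name network
NULL

#' Construct a directed interaction network
#'
#' @param edges data.frame with character columns `source`, `target`,
#'   `mechanism`. Unknown mechanism labels are preserved verbatim.
#' @param dedup if `TRUE` (default) duplicate `(source, target, mechanism)`
#'   triples are collapsed to one edge; if `FALSE` every record is kept and
#'   the network is treated as a multigraph. The background `N` always equals
#'   the number of retained edges, so it matches the counting rule used for
#'   the between-set link counts.
#' @param case_normalize if `TRUE` (default) gene identifiers are upper-cased
#'   before comparison, the usual convention for human gene symbols.
#' @return An object of class `interaction_network`: a list with `edges`
#'   (data.frame of retained edges), `n_links` (the background `N`),
#'   `n_raw` (records before deduplication) and the configuration flags.
#' @examples
#' net <- interaction_network(data.frame(
#'   source = c("A", "B"), target = c("B", "A"), mechanism = "binding"))
#' net$n_links  # both directions are distinct edges
#' @export
interaction_network <- function(edges, dedup = TRUE, case_normalize = TRUE) {
  required <- c("source", "target", "mechanism")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0L)
    stop("edge table is missing column(s): ", paste(missing_cols, collapse = ", "))
  edges <- data.frame(
    source = as.character(edges$source),
    target = as.character(edges$target),
    mechanism = as.character(edges$mechanism),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
    stop("gene identifiers must be non-empty strings")
  if (case_normalize) {
    edges$source <- toupper(edges$source)
    edges$target <- toupper(edges$target)
  }
  n_raw <- nrow(edges)
  if (dedup) {
    key <- paste(edges$source, edges$target, edges$mechanism, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(edges = edges, n_links = nrow(edges), n_raw = n_raw,
         dedup = dedup, case_normalize = case_normalize),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Directed interaction network: %d links (%d raw records%s)\n",
              x$n_links, x$n_raw,
              if (x$dedup) ", deduplicated" else ", multigraph"))
  cat(sprintf("  genes: %d; mechanisms: %s\n",
              length(network_genes(x)),
              paste(utils::head(sort(unique(x$edges$mechanism)), 5L),
                    collapse = ", ")))
  invisible(x)
}

#' Gene universe of a network
#'
#' @param network an `interaction_network`.
#' @return Character vector of all distinct gene identifiers appearing as a
#'   source or target.
#' @export
network_genes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  sort(unique(c(network$edges$source, network$edges$target)))
}

#' Read a directed edge list from TSV
#'
#' Expects a tab-separated file with a header line; comment lines starting
#' with `#` are skipped. Column names are remappable so that simplified
#' BioGRID-style exports with different headers can be read directly, either
#' through the `*_col` arguments or a YAML config file holding the same keys
#' (`source_col`, `target_col`, `mechanism_col`, `dedup`, `case_normalize`).
#'
#' @param path file path.
#' @param source_col,target_col,mechanism_col column names in the file.
#' @param dedup,case_normalize see [interaction_network()].
#' @param config optional path to a YAML file; values there override the
#'   defaults but explicit arguments win.
#' @param quiet suppress the raw-vs-retained message.
#' @return An `interaction_network`.
#' @export
read_edge_list <- function(path, source_col = "source", target_col = "target",
                           mechanism_col = "mechanism", dedup = TRUE,
                           case_normalize = TRUE, config = NULL,
                           quiet = FALSE) {
  if (!file.exists(path)) stop("no such edge-list file: ", path)
  if (!is.null(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read a config file")
    cfg <- yaml::yaml.load_file(config)
    if (missing(source_col)) source_col <- cfg$source_col %||% source_col
    if (missing(target_col)) target_col <- cfg$target_col %||% target_col
    if (missing(mechanism_col)) mechanism_col <- cfg$mechanism_col %||% mechanism_col
    if (missing(dedup)) dedup <- cfg$dedup %||% dedup
    if (missing(case_normalize)) case_normalize <- cfg$case_normalize %||% case_normalize
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L) stop("edge-list file has a header but no rows: ", path)
  for (col in c(source_col, target_col, mechanism_col))
    if (!col %in% names(tab))
      stop("configured column '", col, "' not found in ", path,
           " (columns: ", paste(names(tab), collapse = ", "), ")")
  net <- interaction_network(
    data.frame(source = tab[[source_col]], target = tab[[target_col]],
               mechanism = tab[[mechanism_col]], stringsAsFactors = FALSE),
    dedup = dedup, case_normalize = case_normalize
  )
  if (!quiet)
    message(sprintf("read %d records, retained %d links", net$n_raw, net$n_links))
  net
}

#' Write a network back to edge-list TSV
#'
#' Inverse of [read_edge_list()]; a write followed by a re-read preserves the
#' edge multiset and `N`.
#' @param network an `interaction_network`.
#' @param path output file.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param members character vector of gene identifiers; duplicates are
#'   collapsed with a warning counting them.
#' @param name set label.
#' @param case_normalize upper-case identifiers (default `TRUE`, matching
#'   [interaction_network()]).
#' @return Object of class `gene_set`: list with `name` and sorted unique
#'   `members`. An empty set is valid.
#' @export
gene_set <- function(members, name = "gene_set", case_normalize = TRUE) {
  members <- as.character(members)
  members <- members[nzchar(members)]
  if (case_normalize) members <- toupper(members)
  dup <- sum(duplicated(members))
  if (dup > 0L)
    warning(sprintf("%d duplicate identifier(s) collapsed in gene set '%s'",
                    dup, name))
  structure(list(name = name, members = sort(unique(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a gene set from a plain list or GMT file
#'
#' Plain format is one identifier per line (blank lines and `#` comments
#' skipped). GMT is the usual tab-separated record `name, description,
#' member...`; by default the first record is returned, or the record whose
#' name equals `set_name`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"plain"` or `"gmt"`.
#' @param set_name for GMT files, the record to extract.
#' @param case_normalize see [gene_set()].
#' @return A `gene_set`. An empty member list yields a warning and an empty
#'   set, not an error.
#' @export
read_gene_set <- function(path, format = c("auto", "plain", "gmt"),
                          set_name = NULL, case_normalize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such gene-set file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "plain"
  if (format == "plain") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
      warning("gene-set file has no members: ", path)
    gs <- gene_set(lines, name = sub("\\.[^.]*$", "", basename(path)),
                   case_normalize = case_normalize)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty GMT file: ", path)
    recs <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(recs, length, 1L) < 3L
    if (all(bad)) stop("no valid GMT records (need >= 3 tab-separated fields)")
    recs <- recs[!bad]
    names(recs) <- vapply(recs, `[[`, "", 1L)
    rec <- if (is.null(set_name)) recs[[1L]] else {
      if (!set_name %in% names(recs))
        stop("GMT record '", set_name, "' not found in ", path)
      recs[[set_name]]
    }
    members <- rec[-(1:2)]
    if (length(members) == 0L)
      warning("GMT record '", rec[[1L]], "' has no members")
    gs <- gene_set(members, name = rec[[1L]], case_normalize = case_normalize)
  }
  gs
}

#' Write a gene set
#'
#' @param set a `gene_set`.
#' @param path output file.
#' @param format `"plain"` (one id per line) or `"gmt"` (single record).
#' @export
write_gene_set <- function(set, path, format = c("plain", "gmt")) {
  stopifnot(inherits(set, "gene_set"))
  format <- match.arg(format)
  if (format == "plain") writeLines(set$members, path)
  else writeLines(paste(c(set$name, "na", set$members), collapse = "\t"), path)
  invisible(path)
}

#' Link counts between two gene sets
#'
#' Bundles the four counts of the overconnectivity contingency: `actual`
#' links between the sets, the margins `R` (outgoing links of set 1) and `n`
#' (incoming links of set 2), and the background `N`.
#'
#' @param actual,R,n,N non-negative integer counts with
#'   `0 <= actual <= min(R, n) <= N`.
#' @param mode counting mode the counts were produced under.
#' @return Object of class `link_counts`.
#' @export
link_counts <- function(actual, R, n, N,
                        mode = c("all_interactions",
                                 "transcription_regulation_only")) {
  mode <- match.arg(mode)
  vals <- c(actual = actual, R = R, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("link counts must be non-negative integers")
  if (actual > min(R, n) || max(R, n) > N)
    stop(sprintf("inconsistent link counts: need actual <= min(R, n) <= N, got (%d, %d, %d, %d)",
                 actual, R, n, N))
  structure(list(actual = as.integer(actual), R = as.integer(R),
                 n = as.integer(n), N = as.integer(N), mode = mode),
            class = "link_counts")
}

#' @export
print.link_counts <- function(x, ...) {
  cat(sprintf("Link counts (%s): Actual=%d, R=%d, n=%d, N=%d\n",
              x$mode, x$actual, x$R, x$n, x$N))
  invisible(x)
}

#' Count interaction links between two gene sets
#'
#' The counting semantics mirror the two report styles of link-enrichment
#' analysis against a directed interactome:
#'
#' * `mode = "all_interactions"`: `R` is the number of edges incident to set 1
#'   (source or target in set 1), `n` the number incident to set 2, and
#'   `actual` the number of edges joining a set-1 member to a set-2 member in
#'   either orientation. `N` is the full network size.
#' * `mode = "transcription_regulation_only"`: edges are first restricted to
#'   the transcription-regulation mechanism label; then `R` counts edges whose
#'   source is in set 1, `n` edges whose target is in set 2, `actual` edges
#'   from set 1 to set 2, and `N` is the number of transcription-regulation
#'   edges.
#'
#' Self-loops and edges internal to an overlap of the two sets are counted
#' like any other edge. Each edge contributes once to every count it
#' qualifies for.
#'
#' @param network an `interaction_network`; must be non-empty.
#' @param set1,set2 `gene_set` objects (or character vectors). Either may be
#'   empty, giving zero counts on the corresponding margin.
#' @param mode counting mode, see above.
#' @param txreg_label mechanism label treated as transcription regulation.
#' @return A [link_counts()] object.
#' @examples
#' net <- interaction_network(data.frame(
#'   source = c("A", "B", "C"), target = c("B", "C", "A"),
#'   mechanism = c("binding", "transcription_regulation", "binding")))
#' count_links(net, gene_set("A"), gene_set("B"))
#' @export
count_links <- function(network, set1, set2,
                        mode = c("all_interactions",
                                 "transcription_regulation_only"),
                        txreg_label = "transcription_regulation") {
  stopifnot(inherits(network, "interaction_network"))
  mode <- match.arg(mode)
  if (network$n_links == 0L) stop("cannot count links in an empty network")
  if (!inherits(set1, "gene_set")) set1 <- gene_set(set1, "set1")
  if (!inherits(set2, "gene_set")) set2 <- gene_set(set2, "set2")
  edges <- network$edges
  if (mode == "transcription_regulation_only")
    edges <- edges[edges$mechanism == txreg_label, , drop = FALSE]
  src1 <- edges$source %in% set1$members
  tgt1 <- edges$target %in% set1$members
  src2 <- edges$source %in% set2$members
  tgt2 <- edges$target %in% set2$members
  if (mode == "all_interactions") {
    R <- sum(src1 | tgt1)
    n <- sum(src2 | tgt2)
    actual <- sum((src1 & tgt2) | (src2 & tgt1))
  } else {
    R <- sum(src1)
    n <- sum(tgt2)
    actual <- sum(src1 & tgt2)
  }
  link_counts(actual, R, n, nrow(edges), mode = mode)
}
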