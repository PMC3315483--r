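#' Thresholded correlation networks
#'
#' A `cor_network` is a signed, undirected graph over metabolite nodes.  It is
#' a list with components `nodes` (a `data.frame` with at least `metabolite`,
#' plus optional `tissue`, `season`, `compound_class`), `edges` (a `data.frame`
#' with `node_a`, `node_b`, `r`, `p`, `sign`), and `thresholds`
#' (`c(r_min =, p_max =)`).  Every edge satisfies `|r| >= r_min`,
#' `p <= p_max`, `sign == sign(r)`; there are no self-edges and the edge set
#' is undirected (each unordered pair appears once).
#'
#' @param nodes Node metadata `data.frame` (or character vector of names).
#' @param edges Edge `data.frame` with columns `node_a`, `node_b`, `r`, `p`.
#' @param thresholds Numeric `c(r_min, p_max)` recorded with the network.
#' @return A validated `cor_network` object.
#' @export
cor_network <- function(nodes, edges, thresholds = c(r_min = 0.3, p_max = 0.01)) {
  if (is.character(nodes))
    nodes <- data.frame(metabolite = nodes, stringsAsFactors = FALSE)
  if (!"metabolite" %in% names(nodes)) .fail("nodes need a 'metabolite' column")
  if (anyDuplicated(nodes$metabolite)) .fail("duplicated node names")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        r = numeric(), p = numeric(), sign = integer(),
                        stringsAsFactors = FALSE)
  } else {
    if (!all(c("node_a", "node_b", "r", "p") %in% names(edges)))
      .fail("edges need columns node_a, node_b, r, p")
    if (any(edges$node_a == edges$node_b)) .fail("self-edges are not allowed")
    unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$metabolite)
    if (length(unknown) > 0L)
      .fail("edge endpoint(s) not in node set: ", paste(unknown, collapse = ", "))
    # canonical orientation + uniqueness of unordered pairs
    flip <- edges$node_a > edges$node_b
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    if (anyDuplicated(paste(edges$node_a, edges$node_b, sep = "\r")))
      .fail("duplicated undirected edge(s)")
    edges$sign <- as.integer(sign(edges$r))
    r_min <- unname(thresholds[1]); p_max <- unname(thresholds[2])
    bad <- which(abs(edges$r) < r_min | edges$p > p_max)
    if (length(bad) > 0L)
      .fail("edge(s) violating thresholds at row(s): ",
            paste(bad, collapse = ", "))
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = c(r_min = unname(thresholds[1]),
                                p_max = unname(thresholds[2]))),
            class = "cor_network")
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf(
    "cor_network: %d nodes, %d edges (%d negative); |r| >= %g, p <= %g\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$sign < 0),
    x$thresholds["r_min"], x$thresholds["p_max"]))
  invisible(x)
}

#' Convert a correlation network to an igraph graph
#'
#' Node metadata and the `r`, `p`, `sign` edge attributes are carried over.
#' Topology measures treat the graph as simple and undirected; edge sign is
#' kept as an attribute only.
#'
#' @param net A [cor_network()].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cor_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$metabolite,
                          net$nodes[setdiff(names(net$nodes), "metabolite")],
                          stringsAsFactors = FALSE))
}

#' Write or read a correlation network
#'
#' `"edge-list"` writes a tab-delimited table `node_a, node_b, r, p, sign`
#' (r and p at full precision, so a read-back reproduces the input), preceded
#' by `# r_min`/`# p_max` header comments; an edgeless network yields a
#' header-only file.  `"graphml"` delegates to [igraph::write_graph()].
#'
#' @param net A [cor_network()].
#' @param path Output file path.
#' @param format `"edge-list"` or `"graphml"`.
#' @return `write_network()`: the path, invisibly.  `read_network_edgelist()`:
#'   a `cor_network` (node metadata beyond names is not stored in edge lists,
#'   so nodes are reconstructed from `nodes` if given, else from endpoints).
#' @export
write_network <- function(net, path, format = c("edge-list", "graphml")) {
  stopifnot(inherits(net, "cor_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# r_min\t%.17g", net$thresholds["r_min"]),
               sprintf("# p_max\t%.17g", net$thresholds["p_max"]),
               paste(c("node_a", "node_b", "r", "p", "sign"), collapse = "\t")),
             con)
  if (nrow(net$edges) > 0L) {
    writeLines(sprintf("%s\t%s\t%.17g\t%.17g\t%d",
                       net$edges$node_a, net$edges$node_b,
                       net$edges$r, net$edges$p, net$edges$sign), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @param nodes Optional node metadata to attach on read.
#' @export
read_network_edgelist <- function(path, nodes = NULL) {
  if (!file.exists(path)) .fail("no such file: ", path)
  hdr <- readLines(path, n = 2L)
  thr <- vapply(strsplit(hdr, "\t"), function(x) as.numeric(x[2]), 0)
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(tab$node_a, tab$node_b)))
  cor_network(nodes, tab, thresholds = c(r_min = thr[1], p_max = thr[2]))
}
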