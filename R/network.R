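#' Construct a PPI network from an edge table
#'
#' Builds the undirected, confidence-scored protein-protein interaction
#' network used throughout the package. Self-loops are dropped (a protein is
#' never compared against itself), duplicate edges are collapsed keeping the
#' maximum confidence, and an adjacency index is precomputed so that random
#' walks and transition-probability queries are cheap.
#'
#' @param edges data.frame with at least two character columns (interacting
#'   node ids). An optional third column `confidence` (in `[0, 1]`) defaults
#'   to 1; an optional `weight` column (strictly positive) defaults to 1.
#' @param use_confidence_weight if `TRUE`, edge confidences are used as walk
#'   weights `w_vx`; the default treats the network as unweighted (`w_vx = 1`).
#' @return An object of class `ppi_network`: a list with `nodes` (sorted
#'   character vector), `edges` (canonicalised data.frame with columns
#'   `node_a`, `node_b`, `confidence`, `weight`), and internal adjacency
#'   indices.
#' @export
ppi_network <- function(edges, use_confidence_weight = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("`edges` must be a data.frame with at least two columns")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  conf <- if ("confidence" %in% names(edges)) {
    as.numeric(edges[["confidence"]])
  } else if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) {
    as.numeric(edges[[3L]])
  } else {
    rep(1, length(a))
  }
  if (anyNA(a) || anyNA(b) || anyNA(conf)) stop("edge table contains missing values")
  if (any(conf < 0 | conf > 1)) stop("confidence scores must lie in [0, 1]")

  keep <- a != b                       # self-loops dropped
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  swap <- a > b                        # canonical orientation: node_a < node_b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    ord <- order(key, -conf)           # duplicates collapsed, max confidence kept
    first <- !duplicated(key[ord])
    sel <- ord[first]
    a <- a[sel]; b <- b[sel]; conf <- conf[sel]
  }
  w <- if (use_confidence_weight) conf else rep(1, length(a))
  if (any(w <= 0)) stop("edge weights must be strictly positive")

  nodes <- sort(unique(c(a, b)))
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  f <- factor(c(ia, ib), levels = seq_along(nodes))
  adj_idx <- split(c(ib, ia), f)
  adj_w <- split(c(w, w), f)
  names(adj_idx) <- names(adj_w) <- nodes

  structure(
    list(
      nodes = nodes,
      edges = data.frame(node_a = a, node_b = b, confidence = conf, weight = w,
                         stringsAsFactors = FALSE),
      adj_idx = adj_idx,
      adj_w = adj_w
    ),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (length(x$nodes) >= 2L) cat(sprintf(", density %.4g", edge_density(x)))
  cat("\n")
  invisible(x)
}

#' Neighbors of a node
#'
#' @param net a `ppi_network`
#' @param v node identifier
#' @return character vector of adjacent node ids (possibly empty)
#' @export
graph_neighbors <- function(net, v) {
  stopifnot(inherits(net, "ppi_network"))
  iv <- match(v, net$nodes)
  if (is.na(iv)) stop(sprintf("node '%s' is not in the network", v))
  net$nodes[net$adj_idx[[iv]]]
}

#' Load a PPI network from a tab-separated edge list
#'
#' Reads an edge list with columns `protein_a<TAB>protein_b[<TAB>confidence]`,
#' drops self-loops, collapses duplicate edges (maximum confidence is kept)
#' and removes interactions whose confidence falls below the threshold. Rows
#' without a confidence column are treated as confidence 1. Edges at exactly
#' the threshold are retained (only scores strictly lower are filtered).
#'
#' @param path path to the TSV file. A header line is detected automatically
#'   (a third field that does not parse as a number).
#' @param confidence_threshold minimum confidence retained, in `[0, 1]`.
#'   Default 0.1, the conventional low-confidence cutoff for curated
#'   interaction databases.
#' @param use_confidence_weight passed to [ppi_network()].
#' @return a `ppi_network` containing the retained edges; its node set is the
#'   set of endpoints of retained edges.
#' @export
load_edge_list <- function(path, confidence_threshold = 0.1,
                           use_confidence_weight = FALSE) {
  if (!is.numeric(confidence_threshold) || length(confidence_threshold) != 1L ||
      confidence_threshold < 0 || confidence_threshold > 1) {
    stop("`confidence_threshold` must be a single number in [0, 1]")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s' contains no edges", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)

  start <- 1L
  p1 <- parts[[1L]]
  if (length(p1) >= 3L && is.na(suppressWarnings(as.numeric(p1[3L])))) {
    start <- 2L                        # header line
  } else if (length(p1) >= 2L &&
             all(tolower(p1[1:2]) %in% c("protein_a", "protein_b", "node_a",
                                         "node_b", "source", "target"))) {
    start <- 2L
  }
  if (start > length(parts)) stop(sprintf("'%s' contains no edges", path))

  n <- length(parts) - start + 1L
  a <- b <- character(n)
  conf <- numeric(n)
  for (k in seq_len(n)) {
    ln <- k + start - 1L
    p <- parts[[ln]]
    if (length(p) < 2L || !nzchar(p[1L]) || !nzchar(p[2L])) {
      stop(sprintf("malformed edge row at line %d of '%s'", ln, path))
    }
    a[k] <- p[1L]
    b[k] <- p[2L]
    if (length(p) >= 3L) {
      cv <- suppressWarnings(as.numeric(p[3L]))
      if (is.na(cv)) stop(sprintf("malformed confidence at line %d of '%s'", ln, path))
      conf[k] <- cv
    } else {
      conf[k] <- 1
    }
  }
  if (any(conf < 0 | conf > 1)) {
    bad <- which(conf < 0 | conf > 1)[1L] + start - 1L
    stop(sprintf("confidence out of [0, 1] at line %d of '%s'", bad, path))
  }
  keep <- conf >= confidence_threshold & a != b
  if (!any(keep)) {
    stop(sprintf("no edges remain after filtering '%s' at confidence >= %g",
                 path, confidence_threshold))
  }
  ppi_network(data.frame(node_a = a[keep], node_b = b[keep],
                         confidence = conf[keep], stringsAsFactors = FALSE),
              use_confidence_weight = use_confidence_weight)
}

#' Write a network back to a tab-separated edge list
#'
#' The output has a header and one `node_a<TAB>node_b<TAB>confidence` row per
#' edge; reloading it with [load_edge_list()] at threshold 0 round-trips the
#' network exactly.
#'
#' @param net a `ppi_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges[, c("node_a", "node_b", "confidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge density of a network
#'
#' The number of edges divided by the number of possible edges,
#' `|E| / (|V| (|V|-1) / 2)`.
#'
#' @param net a `ppi_network`
#' @return density in `[0, 1]`
#' @seealso [pair_density()] for the same quantity from raw counts.
#' @export
edge_density <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  pair_density(length(net$nodes), nrow(net$edges))
}

#' Edge density from node and edge counts
#'
#' @param n_nodes number of nodes (>= 2)
#' @param n_edges number of edges
#' @return `n_edges / (n_nodes * (n_nodes - 1) / 2)`
#' @export
pair_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) stop("edge density is undefined for fewer than 2 nodes")
  n_edges / (n_nodes * (n_nodes - 1) / 2)
}

#' Convert to an igraph object
#'
#' @param net a `ppi_network`
#' @return an undirected `igraph` graph with `confidence` and `weight` edge
#'   attributes
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Read a measured-protein to network-node mapping table
#'
#' @param path TSV with columns `measured_id<TAB>base_node` and a header.
#' @return data.frame with columns `measured_id`, `base_node`
#' @export
read_protein_mapping <- function(path) {
  m <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("mapping table needs columns measured_id, base_node")
  names(m)[1:2] <- c("measured_id", "base_node")
  if (anyDuplicated(m$measured_id)) {
    stop("every measured_id must map to exactly one base node")
  }
  m[, c("measured_id", "base_node")]
}

# Resolve measured identifiers to network base nodes. With no mapping table,
# identifiers are taken as node ids, and phospho-forms are recognised by a
# trailing "P<residue><position>" block (e.g. STAT3PY705 -> STAT3) only when
# the stripped id is itself a network node.
resolve_mapping <- function(measured_ids, mapping = NULL, net = NULL) {
  measured_ids <- as.character(measured_ids)
  if (!is.null(mapping)) {
    if (anyDuplicated(mapping$measured_id)) {
      stop("every measured_id must map to exactly one base node")
    }
    base <- mapping$base_node[match(measured_ids, mapping$measured_id)]
    base[is.na(base)] <- measured_ids[is.na(base)]   # ids absent from table: identity
  } else {
    base <- measured_ids
    stripped <- sub("P([STY][0-9]+)+$", "", measured_ids)
    is_candidate <- stripped != measured_ids & nzchar(stripped)
    if (!is.null(net)) {
      ok <- is_candidate & stripped %in% net$nodes
    } else {
      ok <- is_candidate & stripped %in% measured_ids
    }
    base[ok] <- stripped[ok]
  }
  data.frame(measured_id = measured_ids, base_node = base,
             is_phospho = base != measured_ids,
             stringsAsFactors = FALSE)
}

#' Map measured proteins onto network nodes
#'
#' Measured identifiers (including phosphorylated forms such as `STAT3PY705`)
#' are mapped to their base network node, either through an explicit mapping
#' table or, when none is given, by identity with a phospho-suffix heuristic
#' (`<base>P<residues>` maps to `<base>` when that node exists). The mapped
#' set constitutes the measured node set `U` used for neighborhood pairing.
#'
#' @param measured_ids character vector of measured protein identifiers
#' @param mapping optional data.frame with columns `measured_id`, `base_node`
#'   (see [read_protein_mapping()])
#' @param net a `ppi_network`
#' @return list with `mapped` (named character vector: measured id ->
#'   base node, for ids whose base node is in the network) and `unmapped`
#'   (character vector of identifiers without a network node)
#' @export
map_measured <- function(measured_ids, mapping = NULL, net) {
  stopifnot(inherits(net, "ppi_network"))
  res <- resolve_mapping(measured_ids, mapping, net)
  ok <- res$base_node %in% net$nodes
  mapped <- res$base_node[ok]
  names(mapped) <- res$measured_id[ok]
  list(mapped = mapped, unmapped = res$measured_id[!ok])
}
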