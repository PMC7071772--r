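# Median-joining haplotype networks over a window of biallelic sites.
#
# Observed haplotypes are collapsed into frequency-annotated nodes,
# connected by an epsilon-relaxed minimum spanning network, and enriched
# with inferred median vectors (site-wise majorities of connected triples)
# until no cost-minimal median is new; obsolete medians are then pruned.
# Only binary (ancestral/derived) states are supported.

#' Collapse haplotype rows into distinct frequency-annotated sequences
#'
#' @param haps A [haplotype_matrix()].
#' @return `data.frame` with one row per distinct bit string: `bits`,
#'   `is_median` (all `FALSE`), one `count_<pop>` column per population,
#'   and `count_total`. Counts sum to the number of haplotype rows.
#'   Ordered lexicographically by bits.
#' @export
collapse_haplotypes <- function(haps) {
  stopifnot(inherits(haps, "haplotype_matrix"))
  if (nrow(haps$mat) == 0L) stop("haplotype matrix is empty")
  bits <- apply(haps$mat, 1, paste0, collapse = "")
  pops <- sort(unique(haps$pop_labels))
  ub <- sort(unique(bits))
  out <- data.frame(bits = ub, is_median = FALSE, stringsAsFactors = FALSE)
  for (p in pops) {
    out[[paste0("count_", p)]] <-
      as.integer(vapply(ub, function(b) sum(bits == b & haps$pop_labels == p),
                        numeric(1)))
  }
  out$count_total <- as.integer(rowSums(
    out[, paste0("count_", pops), drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Site-wise majority (median vector) of three binary sequences
#'
#' The quasi-median of three binary haplotypes: at every site the state
#' shared by at least two of the three inputs. This string minimizes the
#' summed Hamming distance to the triple.
#'
#' @param a,b,c Equal-length bit strings over \{0, 1\}.
#' @return The majority bit string.
#' @examples
#' median_vector("011", "101", "110")  # "111"
#' @export
median_vector <- function(a, b, c) {
  if (nchar(a) != nchar(b) || nchar(a) != nchar(c)) {
    stop("sequences must have equal length")
  }
  ai <- .bits_to_int(a); bi <- .bits_to_int(b); ci <- .bits_to_int(c)
  paste0(as.integer(ai + bi + ci >= 2), collapse = "")
}

.bits_to_int <- function(x) as.integer(strsplit(x, "", fixed = TRUE)[[1]])

.bits_matrix <- function(bits) {
  do.call(rbind, lapply(bits, .bits_to_int))
}

.hamming <- function(bits) {
  m <- .bits_matrix(bits)
  as.matrix(stats::dist(m, method = "manhattan"))
}

# Union-find components for n nodes given an edge index matrix.
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Epsilon-relaxed minimum spanning network over a distance matrix.
# Distinct weights are processed in increasing order (Kruskal-style); a
# link of weight d is kept when its endpoints are not yet connected by
# kept links of weight <= d - 1 - epsilon. epsilon = 0 yields the classic
# minimum spanning network (union of all minimum spanning trees).
.msn <- function(D, epsilon = 0L) {
  n <- nrow(D)
  empty <- data.frame(i = integer(), j = integer(), weight = numeric())
  if (n <= 1L) return(empty)
  pr <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[upper.tri(D)]
  acc <- logical(length(w))
  for (d in sort(unique(w))) {
    snap <- acc & (w <= d - 1 - epsilon)
    comp <- .components(n, pr[snap, , drop = FALSE])
    sel <- which(w == d)
    acc[sel] <- comp[pr[sel, 1]] != comp[pr[sel, 2]]
  }
  data.frame(i = pr[acc, 1], j = pr[acc, 2], weight = w[acc])
}

# Total length of a minimum spanning tree of a dense distance matrix
# (Prim's algorithm).
.mst_length <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]
  total <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  total
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining iteration over binary haplotypes:
#' (1) pairwise Hamming distances; (2) epsilon-relaxed minimum spanning
#' network; (3) for each connected triple (a node and two of its network
#' neighbours) whose site-wise majority is not yet a node, add that median
#' vector as a new zero-count node; (4) repeat
#' until no new medians appear (a safety cap of `max_cycles` full cycles
#' guards pathological inputs and is logged if hit); (5) prune obsolete
#' median nodes — medians of degree <= 2 whose removal does not increase
#' the minimum-spanning length of the remaining nodes. Ties are broken by
#' lexicographic bit-string order throughout, so the result is
#' deterministic for a fixed input ordering.
#'
#' @param nodes A `data.frame` from [collapse_haplotypes()], or a
#'   character vector of distinct bit strings.
#' @param epsilon Non-negative integer relaxation parameter (default 0,
#'   the usual default of median-joining software).
#' @param max_cycles Safety cap on add-medians cycles (default 10).
#' @return Object of class `mj_network`: `nodes` (observed + median rows;
#'   medians carry zero counts), `edges` (`i`, `j` node row indices,
#'   `weight` = Hamming distance), `epsilon`.
#' @export
build_mj_network <- function(nodes, epsilon = 0L, max_cycles = 10L) {
  if (is.character(nodes)) {
    nodes <- data.frame(bits = nodes, is_median = FALSE,
                        count_total = 1L, stringsAsFactors = FALSE)
  }
  if (nrow(nodes) == 0L) stop("at least one haplotype node is required")
  if (anyDuplicated(nodes$bits)) stop("duplicate bit strings among nodes")
  if (length(unique(nchar(nodes$bits))) != 1L) {
    stop("inconsistent bit-string lengths")
  }
  if (epsilon < 0) stop("epsilon must be a non-negative integer")
  nodes <- nodes[order(nodes$bits), , drop = FALSE]
  rownames(nodes) <- NULL
  bits <- nodes$bits

  for (cycle in seq_len(max_cycles)) {
    D <- .hamming(bits)
    E <- .msn(D, epsilon)
    # candidate medians from two-link triples
    adj <- lapply(seq_along(bits), function(i) {
      sort(c(E$j[E$i == i], E$i[E$j == i]))
    })
    cand_bits <- character(0)
    for (u in seq_along(bits)) {
      nb <- adj[[u]]
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2L)
      for (k in seq_len(ncol(prs))) {
        m <- median_vector(bits[u], bits[prs[1, k]], bits[prs[2, k]])
        if (m %in% bits || m %in% cand_bits) next
        cand_bits <- c(cand_bits, m)
      }
    }
    if (length(cand_bits) == 0L) break
    bits <- c(bits, sort(cand_bits))
    if (cycle == max_cycles) {
      message("median-joining: reached the cycle cap (", max_cycles,
              ") before convergence")
    }
  }

  # prune obsolete medians: degree <= 2 and removal does not lengthen the
  # minimum spanning tree of the remaining nodes
  is_median <- !(bits %in% nodes$bits)
  repeat {
    D <- .hamming(bits)
    E <- .msn(D, epsilon)
    deg <- tabulate(c(E$i, E$j), nbins = length(bits))
    mst_now <- .mst_length(D)
    cand <- which(is_median & deg <= 2L)
    cand <- cand[order(bits[cand])]
    removed <- FALSE
    for (k in cand) {
      Dk <- D[-k, -k, drop = FALSE]
      if (.mst_length(Dk) <= mst_now) {
        bits <- bits[-k]
        is_median <- is_median[-k]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  D <- .hamming(bits)
  E <- .msn(D, epsilon)
  count_cols <- grep("^count_", names(nodes), value = TRUE)
  out_nodes <- data.frame(bits = bits, is_median = is_median,
                          stringsAsFactors = FALSE)
  m <- match(bits, nodes$bits)
  for (col in count_cols) {
    v <- nodes[[col]][m]
    v[is.na(v)] <- 0L
    out_nodes[[col]] <- as.integer(v)
  }
  structure(list(nodes = out_nodes, edges = E, epsilon = as.integer(epsilon)),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf(
    "mj_network: %d observed + %d median nodes, %d edges (epsilon = %d)\n",
    sum(!x$nodes$is_median), sum(x$nodes$is_median), nrow(x$edges),
    x$epsilon))
  invisible(x)
}

#' Convert a median-joining network to an igraph graph
#'
#' @param net An `mj_network`.
#' @return An undirected `igraph` graph with vertex attributes `name`
#'   (bits), `is_median`, the `count_<pop>` columns, and edge attribute
#'   `weight` (Hamming distance).
#' @export
as_igraph_mj <- function(net) {
  stopifnot(inherits(net, "mj_network"))
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes$bits)
  g <- igraph::set_vertex_attr(g, "is_median",
                               value = as.integer(net$nodes$is_median))
  for (col in grep("^count_", names(net$nodes), value = TRUE)) {
    g <- igraph::set_vertex_attr(g, col, value = net$nodes[[col]])
  }
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j),
                           weight = net$edges$weight)
  }
  g
}

#' Export a median-joining network to GraphML or DOT
#'
#' Output is byte-identical for identical inputs (no timestamps or other
#' run-dependent content).
#'
#' @param net An `mj_network`.
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- as_igraph_mj(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Write the node table of a network as TSV
#'
#' One row per node with its bit string, per-population counts and median
#' flag; carries everything needed to re-plot the network with
#' population pie charts.
#'
#' @param net An `mj_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(net, path) {
  utils::write.table(net$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
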