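#' Pairwise mutational distances between haplotypes
#'
#' Distances count the alignment columns at which two haplotypes carry
#' different unambiguous bases. Under the `"strict"` policy, columns where
#' either sequence has an ambiguity code, `N`, or a gap are skipped for that
#' pair (pairwise deletion). Under `"ignore-ambiguous-sites"` those columns
#' were already removed when the table was built, so every retained column
#' contributes.
#'
#' @param table A `hap_table` from [hap_collapse()].
#' @return An integer matrix (haplotypes x haplotypes) of mutational steps,
#'   with haplotype labels as dimnames and the number of compared sites in
#'   attribute `compared_sites`.
#' @export
#' @examples
#' aln <- hap_alignment(c("a", "b"), c("ACGT", "ACGA"))
#' hap_distances(hap_collapse(aln))
hap_distances <- function(table) {
  validate_hap_table(table)
  kept <- attr(table, "kept_sites")
  mat <- seq_char_matrix(table$sequence)[, kept, drop = FALSE]
  nH <- nrow(table)
  unamb <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nH)
  d <- matrix(0L, nH, nH, dimnames = list(table$haplotype, table$haplotype))
  if (nH >= 2) {
    for (i in seq_len(nH - 1)) {
      for (j in seq(i + 1, nH)) {
        comparable <- unamb[i, ] & unamb[j, ]
        steps <- sum(comparable & mat[i, ] != mat[j, ])
        d[i, j] <- d[j, i] <- as.integer(steps)
      }
    }
  }
  attr(d, "compared_sites") <- length(kept)
  d
}

#' Build a minimum spanning haplotype network
#'
#' Computes a minimum spanning tree of the haplotype distance matrix with
#' Kruskal's algorithm, using deterministic tie-breaking (edges sorted by
#' weight, then by node indices), then flags as *alternative* every non-tree
#' pair whose distance does not exceed the largest weight on the tree path
#' between its endpoints by more than `epsilon`. With `epsilon = 0` the
#' alternative links are exactly the equal-cost connections that a different
#' tie-break could have chosen, i.e. the classic minimum spanning network.
#'
#' Edge weights are retained for export only; no downstream diversity metric
#' depends on them (only on which edges subtend each haplotype).
#'
#' @param dist Symmetric, non-negative distance matrix with zero diagonal
#'   (e.g. from [hap_distances()]).
#' @param counts Optional integer vector of individuals per haplotype, in
#'   matrix order (taken from a `hap_table`'s `count` column by
#'   [hap_complexity()]).
#' @param epsilon Non-negative integer slack for alternative links; default 0
#'   (only exact ties).
#' @param count_alternative Should alternative links contribute to node
#'   degrees (and hence to haplotype classes)? Default `TRUE`, matching
#'   network drawings that display alternative links.
#' @return A `hap_network`: a list with `nodes` (tibble: `node`, `count`),
#'   `edges` (tibble: `from`, `to`, `weight`, `alternative`), and the
#'   `count_alternative` flag.
#' @export
build_msn <- function(dist, counts = NULL, epsilon = 0L,
                      count_alternative = TRUE) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop_hapnet("Distance matrix must be square.", "bad_distances")
  }
  if (any(dist < 0)) {
    stop_hapnet("Distance matrix has negative entries.", "bad_distances")
  }
  if (any(abs(dist - t(dist)) > 1e-9)) {
    stop_hapnet("Distance matrix is not symmetric.", "bad_distances")
  }
  if (any(diag(dist) != 0)) {
    stop_hapnet("Distance matrix diagonal must be zero.", "bad_distances")
  }
  if (epsilon < 0) {
    stop_hapnet("`epsilon` must be >= 0.", "bad_input")
  }
  nH <- nrow(dist)
  labels <- rownames(dist) %||% paste0("H", seq_len(nH))
  if (!is.null(counts) && length(counts) != nH) {
    stop_hapnet("`counts` must have one entry per haplotype.", "bad_input")
  }
  counts <- counts %||% rep(1L, nH)

  if (nH < 2) {
    return(new_hap_network(
      nodes = tibble(node = labels, count = as.integer(counts)),
      edges = tibble(from = character(), to = character(),
                     weight = integer(), alternative = logical()),
      count_alternative = count_alternative
    ))
  }

  pairs <- which(upper.tri(dist), arr.ind = TRUE)
  ord <- order(dist[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  w <- dist[pairs]

  # Kruskal with union-find; deterministic given the sort above.
  parent <- seq_len(nH)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(nrow(pairs))
  taken <- 0L
  for (k in seq_len(nrow(pairs))) {
    ru <- find(pairs[k, 1])
    rv <- find(pairs[k, 2])
    if (ru != rv) {
      parent[ru] <- rv
      in_tree[k] <- TRUE
      taken <- taken + 1L
      if (taken == nH - 1L) break
    }
  }

  tree <- pairs[in_tree, , drop = FALSE]
  tree_w <- w[in_tree]
  adj <- vector("list", nH)
  for (k in seq_len(nrow(tree))) {
    u <- tree[k, 1]; v <- tree[k, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, tree_w[k]))
    adj[[v]] <- rbind(adj[[v]], c(u, tree_w[k]))
  }

  # Largest edge weight on the unique tree path between u and v (DFS).
  path_max <- function(u, v) {
    best <- rep(-Inf, nH)
    best[u] <- 0
    stack <- u
    while (length(stack)) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (r in seq_len(NROW(adj[[x]]))) {
        nb <- adj[[x]][r, 1]
        if (is.finite(best[nb])) next
        best[nb] <- max(best[x], adj[[x]][r, 2])
        if (nb == v) return(best[nb])
        stack <- c(stack, nb)
      }
    }
    best[v]
  }

  alt <- logical(nrow(pairs))
  for (k in which(!in_tree)) {
    if (w[k] <= path_max(pairs[k, 1], pairs[k, 2]) + epsilon) alt[k] <- TRUE
  }

  keep <- in_tree | alt
  edges <- tibble(
    from = labels[pairs[keep, 1]],
    to = labels[pairs[keep, 2]],
    weight = as.integer(w[keep]),
    alternative = !in_tree[keep]
  )
  new_hap_network(
    nodes = tibble(node = labels, count = as.integer(counts)),
    edges = edges,
    count_alternative = count_alternative
  )
}

new_hap_network <- function(nodes, edges, count_alternative) {
  structure(
    list(nodes = nodes, edges = edges,
         count_alternative = isTRUE(count_alternative)),
    class = "hap_network"
  )
}

#' Node degrees of a haplotype network
#'
#' The degree of a haplotype is its number of subtending branches: incident
#' spanning edges plus, when the network counts them, incident alternative
#' links.
#'
#' @param network A `hap_network`.
#' @param count_alternative Override the network's stored flag.
#' @return A tibble with columns `node`, `count`, `degree`.
#' @export
hap_degrees <- function(network, count_alternative = NULL) {
  validate_hap_network(network)
  count_alt <- count_alternative %||% network$count_alternative
  edges <- network$edges
  if (!count_alt) edges <- edges[!edges$alternative, , drop = FALSE]
  ends <- c(edges$from, edges$to)
  deg <- table(factor(ends, levels = network$nodes$node))
  tibble(
    node = network$nodes$node,
    count = network$nodes$count,
    degree = as.integer(deg)
  )
}

#' Read a haplotype network from edge-list and counts files
#'
#' Lets the diversity metrics be computed on networks built elsewhere (any
#' construction method), bypassing sequence input entirely.
#'
#' @param edges_path TSV with columns `u`, `v`, `weight`, and optionally
#'   `alternative` (logical or 0/1; absent means all spanning edges).
#' @param counts_path TSV with columns `node`, `individuals`.
#' @param count_alternative Should alternative links count toward degrees?
#' @return A validated `hap_network`.
#' @export
read_network <- function(edges_path, counts_path, count_alternative = TRUE) {
  for (p in c(edges_path, counts_path)) {
    if (!file.exists(p)) stop_hapnet(paste0("File not found: ", p), "io")
  }
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("node", "individuals") %in% names(counts))) {
    stop_hapnet("Counts file must have columns node, individuals.",
                "network_schema")
  }
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("u", "v") %in% names(edges))) {
    stop_hapnet("Edge file must have columns u, v[, weight, alternative].",
                "network_schema")
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1L
  if (!"alternative" %in% names(edges)) edges$alternative <- FALSE
  net <- new_hap_network(
    nodes = tibble(node = as.character(counts$node),
                   count = as.integer(counts$individuals)),
    edges = tibble(from = as.character(edges$u),
                   to = as.character(edges$v),
                   weight = as.integer(edges$weight),
                   alternative = as.logical(edges$alternative)),
    count_alternative = count_alternative
  )
  validate_hap_network(net)
  net
}

#' Write a haplotype network to TSV files
#'
#' @param network A `hap_network`.
#' @param edges_path,counts_path Output TSV paths (either may be `NULL` to
#'   skip).
#' @return `network`, invisibly.
#' @export
write_network <- function(network, edges_path, counts_path = NULL) {
  validate_hap_network(network)
  if (!is.null(edges_path)) {
    e <- network$edges
    readr::write_tsv(
      tibble(u = e$from, v = e$to, weight = e$weight,
             alternative = e$alternative),
      edges_path, progress = FALSE
    )
  }
  if (!is.null(counts_path)) {
    readr::write_tsv(
      tibble(node = network$nodes$node,
             individuals = network$nodes$count),
      counts_path, progress = FALSE
    )
  }
  invisible(network)
}

#' Export a haplotype network as GML
#'
#' Node counts are written as a `count` attribute; alternative links as an
#' `alternative` edge attribute.
#'
#' @param network A `hap_network`.
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_network_gml <- function(network, path) {
  validate_hap_network(network)
  nodes <- network$nodes
  edges <- network$edges
  idx <- stats::setNames(seq_len(nrow(nodes)) - 1L, nodes$node)
  lines <- c("graph [", "  directed 0")
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines, "  node [",
               paste0("    id ", idx[[nodes$node[i]]]),
               paste0("    label \"", nodes$node[i], "\""),
               paste0("    count ", nodes$count[i]),
               "  ]")
  }
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, "  edge [",
               paste0("    source ", idx[[edges$from[i]]]),
               paste0("    target ", idx[[edges$to[i]]]),
               paste0("    weight ", edges$weight[i]),
               paste0("    alternative ", as.integer(edges$alternative[i])),
               "  ]")
  }
  writeLines(c(lines, "]"), path)
  invisible(network)
}

validate_hap_network <- function(network) {
  if (!inherits(network, "hap_network")) {
    stop_hapnet("Expected a `hap_network`.", "bad_input")
  }
  nodes <- network$nodes$node
  edges <- network$edges
  if (anyDuplicated(nodes)) {
    stop_hapnet("Duplicate node labels.", "network_invalid")
  }
  if (any(network$nodes$count < 1)) {
    stop_hapnet("Every node needs at least one individual.", "network_invalid")
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes)
  if (length(unknown) > 0) {
    stop_hapnet(
      paste0("Edge references unknown node(s): ",
             paste(unknown, collapse = ", ")),
      "network_invalid"
    )
  }
  if (any(edges$from == edges$to)) {
    stop_hapnet("Self-loop edges are not allowed.", "network_invalid")
  }
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) {
    stop_hapnet("Duplicate edges between the same node pair.",
                "network_invalid")
  }
  span <- edges[!edges$alternative, , drop = FALSE]
  nH <- length(nodes)
  if (nH >= 2) {
    if (nrow(span) != nH - 1L) {
      stop_hapnet(
        paste0("Spanning edges must form a tree: expected ", nH - 1L,
               " non-alternative edges, found ", nrow(span), "."),
        "network_invalid"
      )
    }
    # nH - 1 edges form a tree iff they connect all nodes.
    parent <- stats::setNames(nodes, nodes)
    find <- function(x) {
      while (parent[[x]] != x) x <- parent[[x]]
      x
    }
    for (i in seq_len(nrow(span))) {
      ru <- find(span$from[i]); rv <- find(span$to[i])
      if (ru == rv) {
        stop_hapnet("Spanning edges contain a cycle.", "network_invalid")
      }
      parent[[ru]] <- rv
    }
    roots <- unique(vapply(nodes, find, character(1)))
    if (length(roots) != 1L) {
      stop_hapnet("Network is disconnected over spanning edges.",
                  "network_invalid")
    }
  }
  invisible(network)
}

#' @export
print.hap_network <- function(x, ...) {
  n_alt <- sum(x$edges$alternative)
  cat("# Haplotype network: ", nrow(x$nodes), " haplotypes, ",
      sum(x$nodes$count), " individuals\n", sep = "")
  cat("# Edges: ", nrow(x$edges) - n_alt, " spanning + ", n_alt,
      " alternative (", if (x$count_alternative) "counted" else "not counted",
      " in degrees)\n", sep = "")
  invisible(x)
}
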