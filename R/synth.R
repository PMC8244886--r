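#' Specify a haplotype-network topology to realize as sequences
#'
#' A network spec is a tree over haplotype indices `1..k` plus the number of
#' individuals carried by each haplotype. [hap_realize()] turns it into an
#' alignment whose haplotype network is exactly this tree.
#'
#' @param edges Two-column matrix or data frame of tree edges
#'   (parent, child) over haplotype indices. May be empty for a
#'   single-haplotype spec.
#' @param counts Positive integer vector: individuals per haplotype; its
#'   length fixes the number of haplotypes.
#' @param steps Mutational steps per edge (all `>= 1`); default 1 each.
#' @param seq_padding Extra invariant sites appended to every sequence.
#' @param name Optional fixture name carried into realized ids.
#' @return A `hap_spec` object.
#' @seealso [hap_realize()], [model_fixtures()]
#' @export
#' @examples
#' hap_spec(cbind(1, 2:6), counts = c(6, 3, 3, 3, 3, 3), name = "star")
hap_spec <- function(edges, counts, steps = NULL, seq_padding = 0L,
                     name = NULL) {
  if (!is_count_vector(counts)) {
    stop_hapnet("`counts` must be positive integers (one per haplotype).",
                "bad_spec")
  }
  k <- length(counts)
  edges <- as.matrix(edges)
  if (length(edges) == 0) edges <- matrix(integer(), ncol = 2)
  if (ncol(edges) != 2) {
    stop_hapnet("`edges` must have two columns (parent, child).", "bad_spec")
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) != k - 1L) {
    stop_hapnet(
      paste0("A tree over ", k, " haplotypes needs ", k - 1L,
             " edges, got ", nrow(edges), "."),
      "bad_spec"
    )
  }
  if (k > 1) {
    if (any(edges < 1 | edges > k)) {
      stop_hapnet("Edge endpoints must be haplotype indices 1..k.",
                  "bad_spec")
    }
    # k-1 edges connecting all k nodes <=> spanning tree.
    parent <- seq_len(k)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    for (i in seq_len(nrow(edges))) {
      ru <- find(edges[i, 1]); rv <- find(edges[i, 2])
      if (ru == rv) stop_hapnet("Spec edges contain a cycle.", "bad_spec")
      parent[ru] <- rv
    }
    if (length(unique(vapply(seq_len(k), find, integer(1)))) != 1L) {
      stop_hapnet("Spec tree is disconnected.", "bad_spec")
    }
  }
  steps <- steps %||% rep(1L, nrow(edges))
  if (length(steps) != nrow(edges) ||
      (nrow(edges) > 0 && !is_count_vector(steps))) {
    stop_hapnet("`steps` must be positive integers, one per edge.",
                "bad_spec")
  }
  structure(
    list(edges = edges, counts = as.integer(counts),
         steps = as.integer(steps), seq_padding = as.integer(seq_padding),
         name = name),
    class = "hap_spec"
  )
}

#' @export
print.hap_spec <- function(x, ...) {
  cat("# Network spec", if (!is.null(x$name)) paste0(" '", x$name, "'"),
      ": ", length(x$counts), " haplotypes, ", sum(x$counts),
      " individuals, ", sum(x$steps), " mutational steps\n", sep = "")
  invisible(x)
}

#' Realize a network spec as a sequence alignment
#'
#' Each tree edge is assigned its own block of unique alignment sites; the
#' child haplotype differs from its parent only at those sites (the base
#' cycles A -> C -> G -> T against an all-`A` background). Because no site
#' is reused, the Hamming distance between any two haplotypes equals the
#' number of steps on the tree path between them, the minimum spanning tree
#' of the realized sequences is unique and equal to the spec tree, and the
#' full pipeline recovers the requested degree sequence exactly.
#'
#' Individuals are replicated per the spec counts with ids
#' `"H<haplotype>_<replicate>"`; each individual is labeled as its own
#' population (model datasets conventionally give every individual a
#' distinct population). A single invariant site is always appended so even
#' a one-haplotype spec yields a writable alignment.
#'
#' @param spec A [hap_spec].
#' @return A [hap_alignment] with `sum(spec$counts)` records.
#' @export
#' @examples
#' hap_realize(model_fixtures()$star21)
hap_realize <- function(spec) {
  if (!inherits(spec, "hap_spec")) {
    stop_hapnet("Expected a `hap_spec`.", "bad_input")
  }
  k <- length(spec$counts)
  n_sites <- sum(spec$steps) + spec$seq_padding + 1L
  base_cycle <- c(A = "C", C = "G", G = "T", T = "A")
  seqs <- matrix("A", nrow = k, ncol = n_sites)

  if (k > 1) {
    site_from <- cumsum(c(1L, spec$steps))[seq_len(nrow(spec$edges))]
    adj <- vector("list", k)
    for (i in seq_len(nrow(spec$edges))) {
      u <- spec$edges[i, 1]; v <- spec$edges[i, 2]
      adj[[u]] <- c(adj[[u]], i)
      adj[[v]] <- c(adj[[v]], i)
    }
    visited <- logical(k)
    visited[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (i in adj[[u]]) {
        v <- setdiff(spec$edges[i, ], u)
        if (visited[v]) next
        sites <- seq(site_from[i], length.out = spec$steps[i])
        seqs[v, ] <- seqs[u, ]
        seqs[v, sites] <- base_cycle[seqs[u, sites]]
        visited[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }

  hap_seq <- apply(seqs, 1, paste, collapse = "")
  ids <- unlist(lapply(seq_len(k), function(h) {
    paste0("H", h, "_", seq_len(spec$counts[h]))
  }))
  hap_alignment(
    id = ids,
    sequence = rep(hap_seq, spec$counts),
    population = ids
  )
}

#' Model-network fixture specs
#'
#' Named specs for the model networks used throughout the package:
#'
#' * `star21` — a star: one 5-branch hub (6 individuals) with five 1-branch
#'   tips (3 individuals each); classes `(1:15, 5:6)`, n = 21.
#' * `branched21` — one 4-branch hub (3), one 2-branch internal node (3), four
#'   1-branch tips (3, 3, 3, 6); classes `(1:15, 2:3, 4:3)`, n = 21.
#' * `even48` — a 4-haplotype path with 12 individuals per
#'   haplotype: two classes of 24 individuals each, n = 48.
#'
#' For parameterized families (class-count and evenness sweeps, random
#' trees) see [spec_star()], [spec_chain()], and [spec_random_tree()].
#'
#' @return A named list of [hap_spec] objects.
#' @export
model_fixtures <- function() {
  list(
    star21 = hap_spec(
      cbind(1L, 2:6), counts = c(6L, rep(3L, 5)), name = "star21"
    ),
    branched21 = hap_spec(
      rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(1L, 5L), c(5L, 6L)),
      counts = c(3L, 3L, 3L, 3L, 3L, 6L), name = "branched21"
    ),
    even48 = hap_spec(
      rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
      counts = rep(12L, 4), name = "even48"
    )
  )
}

#' Star topology spec
#'
#' One hub connected to `n_leaves` tips; with at least two leaves this
#' yields two haplotype classes (the 1-branch tips and the hub).
#'
#' @param n_leaves Number of tips (>= 1).
#' @param hub_count Individuals on the hub.
#' @param leaf_counts Individuals per tip, recycled to `n_leaves`.
#' @return A [hap_spec].
#' @export
spec_star <- function(n_leaves, hub_count = 1L, leaf_counts = 1L) {
  leaf_counts <- rep_len(as.integer(leaf_counts), n_leaves)
  hap_spec(
    cbind(1L, seq_len(n_leaves) + 1L),
    counts = c(as.integer(hub_count), leaf_counts),
    name = paste0("star", n_leaves)
  )
}

#' Path (chain) topology spec
#'
#' Haplotypes in a line; the two ends form the 1-branch class and the
#' interior the 2-branch class.
#'
#' @param n_haplotypes Number of haplotypes (>= 2).
#' @param counts Individuals per haplotype, recycled.
#' @return A [hap_spec].
#' @export
spec_chain <- function(n_haplotypes, counts = 1L) {
  counts <- rep_len(as.integer(counts), n_haplotypes)
  hap_spec(
    cbind(seq_len(n_haplotypes - 1L), seq_len(n_haplotypes - 1L) + 1L),
    counts = counts,
    name = paste0("chain", n_haplotypes)
  )
}

#' Random tree spec
#'
#' Grows a random tree by attaching each new haplotype to a uniformly
#' chosen existing one (a random recursive tree). Useful for property
#' tests and for networks where every individual is its own haplotype.
#'
#' @param n_haplotypes Number of haplotypes (>= 1).
#' @param counts Individuals per haplotype, recycled; default 1 each.
#' @param seed Integer seed controlling the attachment choices.
#' @param max_steps Edge step counts are drawn uniformly from
#'   `1:max_steps`; default 1 (all single-step edges).
#' @return A [hap_spec].
#' @export
spec_random_tree <- function(n_haplotypes, counts = 1L, seed = 1L,
                             max_steps = 1L) {
  counts <- rep_len(as.integer(counts), n_haplotypes)
  if (n_haplotypes == 1) {
    return(hap_spec(matrix(integer(), ncol = 2), counts = counts,
                    name = "tree1"))
  }
  edges <- withr::with_seed(seed, {
    parents <- vapply(seq(2L, n_haplotypes), function(v) {
      sample.int(v - 1L, 1L)
    }, integer(1))
    cbind(parents, seq(2L, n_haplotypes))
  })
  steps <- withr::with_seed(seed + 1L, {
    sample.int(max_steps, n_haplotypes - 1L, replace = TRUE)
  })
  hap_spec(edges, counts = counts, steps = steps,
           name = paste0("tree", n_haplotypes, "_seed", seed))
}

#' Serialize / deserialize a network spec as JSON
#'
#' @param spec A [hap_spec].
#' @param path JSON file path.
#' @return `write_spec()`: the spec, invisibly; `read_spec()`: a
#'   [hap_spec].
#' @export
write_spec <- function(spec, path) {
  if (!inherits(spec, "hap_spec")) {
    stop_hapnet("Expected a `hap_spec`.", "bad_input")
  }
  jsonlite::write_json(
    list(
      edges = unname(apply(spec$edges, 1, as.list)),
      counts = spec$counts,
      steps = spec$steps,
      seq_padding = spec$seq_padding,
      name = spec$name
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(spec)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) {
    stop_hapnet(paste0("File not found: ", path), "io")
  }
  x <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop_hapnet(paste0("Cannot parse spec JSON: ", conditionMessage(e)),
                  "bad_spec")
    }
  )
  if (is.null(x$counts)) {
    stop_hapnet("Spec JSON must contain `counts`.", "bad_spec")
  }
  edges <- x$edges
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(integer(), ncol = 2)
  } else if (is.data.frame(edges)) {
    edges <- as.matrix(edges)
  } else if (is.list(edges)) {
    edges <- do.call(rbind, lapply(edges, unlist))
  }
  hap_spec(edges, counts = unlist(x$counts),
           steps = if (is.null(x$steps) || length(x$steps) == 0) NULL
                   else unlist(x$steps),
           seq_padding = x$seq_padding %||% 0L,
           name = x$name)
}
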