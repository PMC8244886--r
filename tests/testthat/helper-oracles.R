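# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: diversity by explicit pair enumeration, MST by
# exhaustive spanning-tree enumeration.

# Probability that two individuals drawn without replacement fall in
# different groups, by enumerating every unordered pair.
pair_enumeration_diversity <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  pairs <- utils::combn(length(labels), 2)
  mean(labels[pairs[1, ]] != labels[pairs[2, ]])
}

# Minimum spanning tree weight by brute force over all (k-1)-edge subsets.
brute_force_mst_weight <- function(d) {
  k <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  m <- nrow(pairs)
  best <- Inf
  subsets <- utils::combn(m, k - 1)
  for (s in seq_len(ncol(subsets))) {
    sel <- subsets[, s]
    parent <- seq_len(k)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    acyclic <- TRUE
    for (e in sel) {
      ru <- find(pairs[e, 1]); rv <- find(pairs[e, 2])
      if (ru == rv) { acyclic <- FALSE; break }
      parent[ru] <- rv
    }
    if (!acyclic) next
    best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
  }
  best
}

# Random class/haplotype count vector with sum n.
random_counts <- function(n, max_groups) {
  k <- sample.int(min(max_groups, n), 1)
  if (k == 1) return(n)
  cuts <- sort(sample.int(n - 1, k - 1))
  diff(c(0, cuts, n))
}

# Alignment fixture shared across tests: the three-class model
# network realized through the synthetic generator.
branched21_alignment <- function() hap_realize(model_fixtures()$branched21)

expect_hapnet_error <- function(expr, class) {
  expect_error(expr, class = paste0("hapnetdiv_", class))
}
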