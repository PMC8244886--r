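test_that("hamming distances follow pairwise deletion under strict policy", {
  d1 <- hap_distances(hap_collapse(hap_alignment(c("a", "b"),
                                                 c("ACGT", "ACGA"))))
  expect_equal(unname(d1["H1", "H2"]), 1L)

  d4 <- hap_distances(hap_collapse(hap_alignment(c("a", "b"),
                                                 c("ACGT", "TGCA"))))
  expect_equal(max(d4), 4L)

  # N column skipped for that pair only
  dn <- hap_distances(hap_collapse(hap_alignment(c("a", "b"),
                                                 c("ACNT", "ACGA"))))
  expect_equal(unname(dn["H1", "H2"]), 1L)
})

test_that("two haplotypes yield a single edge and degree 1 on both", {
  d <- matrix(c(0L, 3L, 3L, 0L), 2, dimnames = list(c("H1", "H2"),
                                                    c("H1", "H2")))
  net <- build_msn(d, counts = c(2L, 1L))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3L)
  expect_equal(hap_degrees(net)$degree, c(1L, 1L))
})

test_that("star distances recover hub degree 5", {
  aln <- hap_realize(model_fixtures()$star21)
  tab <- hap_collapse(aln)
  net <- build_msn(hap_distances(tab), counts = tab$count)
  deg <- hap_degrees(net)
  expect_equal(sort(deg$degree), c(1L, 1L, 1L, 1L, 1L, 5L))
  # the hub is the count-6 haplotype
  expect_equal(deg$count[deg$degree == 5], 6L)
})

test_that("equal-cost ties become alternative links", {
  d <- matrix(1L, 3, 3, dimnames = list(paste0("H", 1:3), paste0("H", 1:3)))
  diag(d) <- 0L
  net <- build_msn(d)
  expect_equal(sum(!net$edges$alternative), 2L)
  expect_equal(sum(net$edges$alternative), 1L)
  expect_equal(hap_degrees(net)$degree, c(2L, 2L, 2L))
  expect_equal(hap_degrees(net, count_alternative = FALSE)$degree |> sort(),
               c(1L, 1L, 2L))
})

test_that("degenerate distance input is rejected", {
  m <- matrix(c(0L, 1L, 2L, 0L), 2)
  expect_hapnet_error(build_msn(m), "bad_distances")
  m2 <- matrix(c(0L, -1L, -1L, 0L), 2)
  expect_hapnet_error(build_msn(m2), "bad_distances")
})

test_that("MST weight matches brute-force enumeration for small networks", {
  for (k in 5:7) {
    d <- withr::with_seed(100 + k, {
      m <- matrix(sample.int(9, k * k, replace = TRUE), k)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 0L
      m
    })
    net <- build_msn(d)
    span <- net$edges[!net$edges$alternative, ]
    expect_equal(sum(span$weight), brute_force_mst_weight(d),
                 info = paste("k =", k))
  }
})

test_that("MST weight matches igraph on larger random matrices", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    k <- 12
    d <- withr::with_seed(seed, {
      m <- matrix(sample.int(20, k * k, replace = TRUE), k)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 0L
      m
    })
    net <- build_msn(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ref <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(net$edges$weight[!net$edges$alternative]), ref)
  }
})

test_that("degree multiset is invariant under node relabeling", {
  aln <- branched21_alignment()
  tab <- hap_collapse(aln)
  d <- hap_distances(tab)
  perm <- withr::with_seed(3, sample.int(nrow(d)))
  d2 <- d[perm, perm]
  deg1 <- sort(hap_degrees(build_msn(d))$degree)
  deg2 <- sort(hap_degrees(build_msn(d2))$degree)
  expect_equal(deg1, deg2)
})

test_that("degrees sum to twice the number of retained edges", {
  for (seed in 1:10) {
    spec <- spec_random_tree(sample(3:12, 1), counts = 1L, seed = seed)
    tab <- hap_collapse(hap_realize(spec))
    net <- build_msn(hap_distances(tab), counts = tab$count)
    expect_equal(sum(hap_degrees(net)$degree), 2L * nrow(net$edges))
  }
})

test_that("external networks are validated on read", {
  edges <- withr::local_tempfile(fileext = ".tsv")
  counts <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("u\tv\tweight", "H1\tH2\t1"), edges)
  writeLines(c("node\tindividuals", "H1\t4", "H2\t3"), counts)
  net <- read_network(edges, counts)
  expect_equal(sum(net$nodes$count), 7L)
  expect_equal(nrow(net$edges), 1L)

  writeLines(c("u\tv\tweight", "H1\tH3\t1"), edges)
  expect_hapnet_error(read_network(edges, counts), "network_invalid")

  # 4-cycle: all spanning -> not a tree; flagging one alternative fixes it
  writeLines(c("node\tindividuals", paste0("H", 1:4, "\t1")), counts)
  writeLines(c("u\tv\tweight\talternative",
               "H1\tH2\t1\tFALSE", "H2\tH3\t1\tFALSE",
               "H3\tH4\t1\tFALSE", "H4\tH1\t1\tFALSE"), edges)
  expect_hapnet_error(read_network(edges, counts), "network_invalid")
  writeLines(c("u\tv\tweight\talternative",
               "H1\tH2\t1\tFALSE", "H2\tH3\t1\tFALSE",
               "H3\tH4\t1\tFALSE", "H4\tH1\t1\tTRUE"), edges)
  cyc <- read_network(edges, counts)
  expect_equal(hap_degrees(cyc)$degree, rep(2L, 4))
})

test_that("network TSV and GML exports round-trip / are well-formed", {
  tab <- hap_collapse(branched21_alignment())
  net <- build_msn(hap_distances(tab), counts = tab$count)
  e <- withr::local_tempfile(fileext = ".tsv")
  c2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, e, c2)
  back <- read_network(e, c2)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  gml <- withr::local_tempfile(fileext = ".gml")
  write_network_gml(net, gml)
  txt <- readLines(gml)
  expect_equal(sum(grepl("^  node \\[", txt)), nrow(net$nodes))
  expect_equal(sum(grepl("^  edge \\[", txt)), nrow(net$edges))
  skip_if_not_installed("igraph")
  g <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
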