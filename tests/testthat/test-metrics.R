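pipeline_classes <- function(spec) {
  tab <- hap_collapse(hap_realize(spec))
  net <- build_msn(hap_distances(tab), counts = tab$count)
  hap_class_decomposition(net)
}

test_that("class decomposition reproduces the three-class reference breakdown", {
  cls <- pipeline_classes(model_fixtures()$branched21)
  expect_equal(cls$n_branches, c(1L, 2L, 4L))
  expect_equal(cls$n_haplotypes, c(4L, 1L, 1L))
  expect_equal(cls$n_individuals, c(15L, 3L, 3L))
  expect_equal(sum(cls$freq), 1)
  expect_equal(attr(cls, "n_classes"), 3L)
})

test_that("two-haplotype and cycle networks form a single class", {
  cls2 <- pipeline_classes(spec_chain(2, counts = c(3, 4)))
  expect_equal(nrow(cls2), 1L)
  expect_equal(cls2$n_branches, 1L)
  expect_equal(cls2$n_individuals, 7L)

  # pure cycle: every haplotype has exactly two branches
  d <- matrix(1L, 4, 4, dimnames = list(paste0("H", 1:4), paste0("H", 1:4)))
  diag(d) <- 0L
  d["H1", "H3"] <- d["H3", "H1"] <- 2L
  d["H2", "H4"] <- d["H4", "H2"] <- 2L
  net <- build_msn(d, counts = rep(2L, 4))
  cls <- hap_class_decomposition(net)
  expect_equal(cls$n_branches, 2L)
  expect_equal(cls$n_haplotypes, 4L)
  expect_equal(hap_bd(cls), 0)
})

test_that("Hd matches its closed form and boundary cases", {
  expect_equal(hap_hd(21L), 0)
  expect_equal(hap_hd(rep(1L, 21)), 1)
  expect_equal(hap_hd(c(6L, 3L, 3L, 3L, 3L, 3L)), 6 / 7, tolerance = 1e-12)
  expect_hapnet_error(hap_hd(1L), "undefined_metric")
  expect_equal(hap_hd(1L, allow_degenerate = TRUE), 0)
  expect_hapnet_error(hap_hd(c(2L, 2L), n = 5L), "bad_input")
})

test_that("Nd reproduces the worked example and degenerate readings", {
  expect_equal(hap_nd(c(1, 2, 4), c(4, 1, 1)), 0.4, tolerance = 1e-12)
  # 4-cycle: all degrees 2
  expect_equal(hap_nd(2, 4), 0, tolerance = 1e-12)
  # two-haplotype network: Nd = 1, outside any probability reading
  expect_equal(hap_nd(1, 2), 1, tolerance = 1e-12)
  expect_hapnet_error(hap_nd(1, 1), "undefined_metric")
  expect_hapnet_error(hap_nd(c(1, 1), c(2, 2)), "bad_input")
})

test_that("HNd is the plain product of its components", {
  expect_equal(hap_hnd(0, 0.7), 0)
  expect_equal(hap_hnd(0.7, 0), 0)
  expect_equal(hap_hnd(6 / 7, 0.4), 0.342857, tolerance = 1e-6)
})

test_that("Bd reproduces the worked examples", {
  expect_equal(hap_bd(c(15L, 3L, 3L)), 0.4714286, tolerance = 1e-7)
  expect_equal(hap_bd(c(15L, 6L)), 0.4285714, tolerance = 1e-7)
  expect_equal(hap_bd(42L), 0)
  expect_equal(hap_bd(c(24L, 24L)), 0.5106383, tolerance = 1e-7)
})

test_that("HBd uses a single sample-size correction by default", {
  hap <- c(6L, 3L, 3L, 3L, 3L, 3L)
  expect_equal(hap_hbd(hap, c(15L, 6L)), 0.3498542, tolerance = 1e-7)
  # three-class model structure: full precision 0.38484 (the commonly
  # cited rounded value 0.39 disagrees with these inputs)
  expect_equal(hap_hbd(hap, c(15L, 3L, 3L)),
               (360 / 441) * (198 / 441) * 21 / 20, tolerance = 1e-12)
  expect_equal(hap_hbd(21L, 21L), 0)
  # double-corrected variant is Hd * Bd
  expect_equal(
    hap_hbd(hap, c(15L, 6L), both_corrected = TRUE),
    hap_hd(hap) * hap_bd(c(15L, 6L)),
    tolerance = 1e-12
  )
})

test_that("Hd and Bd equal the pair-enumeration oracle on random counts", {
  withr::with_seed(2024, {
    for (rep in 1:60) {
      counts <- random_counts(sample(2:60, 1), max_groups = 12)
      oracle <- pair_enumeration_diversity(counts)
      expect_equal(hap_hd(counts), oracle, tolerance = 1e-12)
      expect_equal(hap_bd(counts), oracle, tolerance = 1e-12)
    }
  })
})

test_that("coarsening and product inequalities hold on random partitions", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(4:60, 1)
      hap_counts <- random_counts(n, max_groups = 10)
      # classes coarsen haplotypes: merge random groups of haplotypes
      k <- length(hap_counts)
      assign <- sample.int(sample.int(k, 1), k, replace = TRUE)
      class_counts <- as.vector(tapply(hap_counts, assign, sum))
      hd <- hap_hd(hap_counts)
      bd <- hap_bd(class_counts)
      hbd <- hap_hbd(hap_counts, class_counts)
      expect_lte(bd, hd + 1e-12)
      expect_lte(hbd, min(hd, bd) + 1e-12)
      expect_gte(hbd, 0)
      expect_lte(hd, 1)
      expect_lte(bd, 1)
    }
  })
})

test_that("Bd grows with class count and approaches its even-split asymptote", {
  n <- 840L # divisible by 2..8
  prev <- -Inf
  for (k in c(2L, 3L, 4L, 5L, 6L, 7L, 8L)) {
    bd <- hap_bd(rep(n %/% k, k))
    expect_gt(bd, prev)
    expect_equal(bd, (1 - 1 / k) * n / (n - 1), tolerance = 1e-12)
    prev <- bd
  }
  # asymptote -> 1 as classes proliferate
  expect_gt(hap_bd(rep(2L, 420)), 0.997)
})

test_that("Bd is maximized by even splits; transfers to a larger class hurt", {
  n <- 60L
  for (k in c(2L, 3L, 5L)) {
    even <- rep(n %/% k, k)
    best <- hap_bd(even)
    withr::with_seed(7 + k, {
      for (rep in 1:20) {
        other <- random_counts(n, max_groups = k)
        if (length(other) < k) next
        expect_lte(hap_bd(other), best + 1e-12)
      }
    })
    # move one individual from a smaller to a larger class
    uneven <- even
    uneven[1] <- uneven[1] + 1L
    uneven[2] <- uneven[2] - 1L
    expect_lt(hap_bd(uneven), best)
  }
})

test_that("Bd decreases in n at fixed class proportions", {
  props <- c(2, 1, 1, 1, 1) / 6
  sizes <- c(12L, 24L, 60L, 120L, 600L)
  bds <- vapply(sizes, function(n) hap_bd(as.integer(props * n)), numeric(1))
  expect_true(all(diff(bds) < 0))
  # limit value 1 - sum(props^2)
  expect_equal(bds[length(bds)], (1 - sum(props^2)) * 600 / 599,
               tolerance = 1e-12)
})

test_that("nucleotide diversity matches the pair-enumeration definition", {
  aln <- hap_alignment(paste0("s", 1:2),
                       c("AAAAAAAAAA", "AAAAAAAAAC"))
  tab <- hap_collapse(aln)
  expect_equal(hap_pi(tab, hap_distances(tab)), 0.1, tolerance = 1e-12)

  # counts {2,1}, d = 2, L = 10 -> (2*2)/(10*3)
  aln3 <- hap_alignment(paste0("s", 1:3),
                        c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAACC"))
  tab3 <- hap_collapse(aln3)
  expect_equal(hap_pi(tab3, hap_distances(tab3)), 4 / 30, tolerance = 1e-12)

  same <- hap_collapse(hap_alignment(c("a", "b"), c("ACGT", "ACGT")))
  expect_equal(hap_pi(same, hap_distances(same)), 0)
})

test_that("full pipeline reports match the model-network reference values", {
  repB <- hap_complexity(branched21_alignment(), dataset = "branched21")
  g <- glance(repB)
  expect_equal(g$n, 21L)
  expect_equal(g$n_hap, 6L)
  expect_equal(g$n_classes, 3L)
  expect_equal(round(g$Hd, 2), 0.86)
  expect_equal(round(g$Bd, 2), 0.47)
  expect_equal(g$Nd, 0.4, tolerance = 1e-12)

  rep48 <- hap_complexity(hap_realize(model_fixtures()$even48))
  expect_equal(glance(rep48)$Bd, 0.5106383, tolerance = 1e-7)
})

test_that("metric values are invariant under record permutation", {
  aln <- branched21_alignment()
  perm <- withr::with_seed(5, sample.int(nrow(aln)))
  aln2 <- hap_alignment(aln$id[perm], aln$sequence[perm])
  g1 <- glance(hap_complexity(aln))
  g2 <- glance(hap_complexity(aln2))
  expect_equal(g1[, -1], g2[, -1])
})

test_that("degenerate input errors in strict mode and zeros in lenient", {
  one_hap <- hap_alignment(paste0("s", 1:4), rep("ACGT", 4))
  expect_hapnet_error(hap_complexity(one_hap), "undefined_metric")
  rep <- hap_complexity(one_hap, lenient = TRUE)
  expect_true(rep$degenerate)
  g <- glance(rep)
  expect_equal(unlist(g[, c("Hd", "Bd", "HBd", "Nd", "HNd")]),
               c(Hd = 0, Bd = 0, HBd = 0, Nd = 0, HNd = 0))
})

test_that("precomputed networks give the same metrics as the pipeline", {
  tab <- hap_collapse(branched21_alignment())
  net <- build_msn(hap_distances(tab), counts = tab$count)
  g_net <- glance(hap_complexity_network(net, dataset = "ext"))
  g_aln <- glance(hap_complexity(branched21_alignment()))
  for (col in c("n", "n_hap", "n_classes", "Hd", "Bd", "HBd", "Nd", "HNd")) {
    expect_equal(g_net[[col]], g_aln[[col]], info = col)
  }
  expect_true(is.na(g_net$pi))
})
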