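test_that("hamming matrix is symmetric, zero-diagonal, and brute-force exact", {
  aln <- fix_aln("AAAAAA", "AATTAA", "AATTCC")
  tab <- collapse_haplotypes(aln)
  D <- hamming_matrix(tab)
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(D, t(D))
  seqs <- apply(tab$sequences, 1, paste0, collapse = "")
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(D[i, j], brute_diff(seqs[i], seqs[j]))
    }
  }
})

test_that("two haplotypes give a single edge of their hamming weight", {
  net <- median_joining(collapse_haplotypes(fix_aln("AAAA", "TTAA", "TTAA")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
  expect_equal(sum(net$nodes$is_median), 0)
})

test_that("hub-and-spokes data give a star with no median vectors", {
  m <- 8
  aln <- hub_spokes_aln(m = m, hub_freq = 5)
  net <- median_joining(collapse_haplotypes(aln))
  expect_equal(sum(net$nodes$is_median), 0)
  expect_equal(nrow(net$edges), m) # tree: hub to each spoke
  ss <- star_summary(net)
  expect_equal(ss$hub, "H1")
  expect_equal(ss$hub_degree, m)
  expect_equal(ss$fraction_1step, 1.0)
})

test_that("the 3-haplotype Steiner fixture gains one median vector and cost 3", {
  # A, B, C each one step from an unsampled consensus at distinct sites:
  # pairwise distances all 2, MST cost 4, Steiner cost 3
  cons <- "AAAAAAAAAA"
  mk <- function(pos, to) {
    s <- strsplit(cons, "")[[1]]
    s[pos] <- to
    paste(s, collapse = "")
  }
  aln <- fix_aln(mk(1, "T"), mk(2, "C"), mk(3, "G"))
  net <- median_joining(collapse_haplotypes(aln))
  expect_equal(sum(net$nodes$is_median), 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(sum(net$edges$weight), 3)
  # every edge touches the median vector
  mv <- net$nodes$id[net$nodes$is_median]
  expect_true(all(net$edges$from == mv | net$edges$to == mv))
})

test_that("every edge weight equals the hamming distance between its endpoints", {
  sim <- simulate(demography("sudden_expansion", 0.5, 500, 2.5, n = 15, k = 100),
    nsim = 1, seed = 71
  )[[1]]
  tab <- collapse_haplotypes(as_alignment(sim))
  net <- median_joining(tab)
  # rebuild sequences for all nodes (sampled + medians, variable columns)
  seqmat <- do.call(rbind, net$sequences)
  rownames(seqmat) <- net$nodes$id
  D <- as.matrix(pairwise_differences(seqmat)$diffs)
  for (e in seq_len(nrow(net$edges))) {
    expect_equal(net$edges$weight[e], D[net$edges$from[e], net$edges$to[e]])
  }
  # connectivity
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
})

test_that("epsilon = 0 network is a subgraph of the epsilon = 1 network", {
  # fixture with co-minimal alternatives: a 4-cycle of haplotypes
  aln <- fix_aln("AAAA", "TAAA", "TTAA", "ATAA", "AAAA")
  tab <- collapse_haplotypes(aln)
  e0 <- median_joining(tab, epsilon = 0)
  e1 <- median_joining(tab, epsilon = 1)
  key <- function(net) {
    paste(pmin(net$edges$from, net$edges$to), pmax(net$edges$from, net$edges$to))
  }
  expect_true(all(key(e0) %in% key(e1)))
})

test_that("relabelling haplotypes yields an isomorphic network", {
  seqs <- c("AAAAAA", "TAAAAA", "TTAAAA", "AAAATT", "AAAAAT")
  a1 <- do.call(fix_aln, as.list(seqs))
  a2 <- do.call(fix_aln, as.list(rev(seqs)))
  n1 <- median_joining(collapse_haplotypes(a1))
  n2 <- median_joining(collapse_haplotypes(a2))
  expect_equal(nrow(n1$nodes), nrow(n2$nodes))
  expect_equal(sort(n1$edges$weight), sort(n2$edges$weight))
  expect_true(igraph::isomorphic(as_igraph(n1), as_igraph(n2)))
})

test_that("star summary on a path network reports the 2/3 neighbourhood", {
  # path H1 - H2 - H3 - H4 (one substitution per step)
  aln <- fix_aln("AAAA", "TAAA", "TTAA", "TTTA")
  net <- median_joining(collapse_haplotypes(aln))
  ss <- star_summary(net)
  expect_equal(ss$hub_degree, 2)
  expect_equal(ss$fraction_1step, 2 / 3)
})

test_that("expansion samples are more star-like than constant-size samples", {
  hub_frac <- function(sim) {
    tab <- collapse_haplotypes(as_alignment(sim))
    if (tab$k_obs < 2) return(1)
    star_summary(median_joining(tab))$fraction_1step
  }
  fr_exp <- fr_con <- numeric(12)
  for (i in 1:12) {
    se <- simulate(demography("sudden_expansion", 0.3, 1000, 3, n = 40, k = 300),
      nsim = 1, seed = 200 + i
    )[[1]]
    sc <- simulate(demography("constant", 3, 3, n = 40, k = 300),
      nsim = 1, seed = 300 + i
    )[[1]]
    fr_exp[i] <- hub_frac(se)
    fr_con[i] <- hub_frac(sc)
  }
  expect_gt(mean(fr_exp), mean(fr_con))
})

test_that("network export writes GraphML and TSV tables", {
  aln <- hub_spokes_aln(m = 4, hub_freq = 3)
  net <- median_joining(collapse_haplotypes(aln))
  gml <- tempfile(fileext = ".graphml")
  ntsv <- tempfile(fileext = ".tsv")
  etsv <- tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, nodes_tsv = ntsv, edges_tsv = etsv)
  expect_true(file.exists(gml))
  nodes <- utils::read.delim(ntsv)
  edges <- utils::read.delim(etsv)
  expect_equal(nrow(nodes), nrow(net$nodes))
  expect_equal(nrow(edges), nrow(net$edges))
})
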