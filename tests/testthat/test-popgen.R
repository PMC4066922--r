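test_that("gene diversity and Fst behave at the analytic extremes", {
  # identical frequency vectors: unbiased theta must not be positive
  h <- rep(c("A", "B"), times = 8)
  pops <- rep(c("p1", "p2"), each = 8)
  res <- geneDiversityFst(h, pops, estimator = "wc_theta", resamples = 50)
  expect_lte(res@Fst, 0)
  # complete fixation: nei_gst = 1
  h2 <- c(rep("A", 8), rep("B", 8))
  res2 <- geneDiversityFst(h2, pops, estimator = "nei_gst", resamples = 50)
  expect_equal(res2@Fst, 1)
  expect_equal(res2@Hs, 0)
  # nei_gst closed form (Ht - Hs)/Ht on supplied frequencies
  set.seed(2)
  h3 <- sample(c("A", "B", "C"), 24, replace = TRUE)
  pops3 <- rep(c("p1", "p2", "p3"), each = 8)
  res3 <- geneDiversityFst(h3, pops3, estimator = "nei_gst",
                           resamples = 50)
  expect_equal(res3@Fst, (res3@Ht - res3@Hs) / res3@Ht)
  expect_true(res3@Hs >= 0 && res3@Hs <= 1)
  expect_true(res3@Ht >= 0 && res3@Ht <= 1)
  expect_error(geneDiversityFst(h, rep("p1", 16)), "2 populations")
})

test_that("wc_theta recovers island-model differentiation (frequency oracle)", {
  # two demes fixed-difference at many sites: theta near its analytic value
  set.seed(31)
  L <- 80
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mkpop <- function(nPriv) {
    v <- base
    idx <- sample(L, nPriv)
    v[idx] <- vapply(v[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    v
  }
  # strong divergence: each deme's individuals share deme-private variants
  d1 <- mkpop(20); d2 <- mkpop(20)
  noise <- function(v) {
    i <- sample(L, 2)
    v[i] <- vapply(v[i], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    v
  }
  seqs <- c(replicate(8, paste(noise(d1), collapse = "")),
            replicate(8, paste(noise(d2), collapse = "")))
  pops <- rep(c("p1", "p2"), each = 8)
  res <- geneDiversityFst(seqs, pops, estimator = "wc_theta")
  # frequency-accounting oracle at the fixed deme-private sites: within-
  # population diversity ~ 0, so theta should be high
  expect_gt(res@Fst, 0.5)
  expect_equal(res@spreadMethod, "jackknife over polymorphic sites")
  expect_true(is.finite(res@sdFst))
})

test_that("network construction matches a spanning-tree oracle on toys", {
  # single-edge example: two ITS patterns differing only at position 669
  aln <- makeItsAlignment()
  sites <- findPolymorphicSites(aln, itsRegions())
  hm <- haplotypeMatrix(aln, sites)
  net <- buildNetwork(hm)
  g2 <- net@nodes$id[grepl("G2\\b|G2,", net@nodes$members)]
  g25a <- net@nodes$id[net@nodes$members == "G25A"]
  e <- net@edges[(net@edges$from == g2 & net@edges$to == g25a) |
                   (net@edges$from == g25a & net@edges$to == g2), ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$sites, "669")
  expect_equal(e$weight, 1)

  # one haplotype -> one node, no edges
  single <- buildNetwork(matrix("A", 1, 3,
                                dimnames = list("H1", c("1", "2", "3"))))
  expect_equal(nrow(single@nodes), 1L)
  expect_equal(nrow(single@edges), 0L)

  # toy MSN equals brute-force MST over the complete distance graph with
  # all co-minimal edges retained
  set.seed(17)
  for (rep in 1:5) {
    states <- matrix(sample(c("A", "T"), 5 * 4, replace = TRUE), 5, 4,
                     dimnames = list(paste0("H", 1:5), paste0("s", 1:4)))
    states <- states[!duplicated(apply(states, 1, paste, collapse = "")), ,
                     drop = FALSE]
    if (nrow(states) < 2) next
    net <- buildNetwork(states)
    # oracle: igraph minimum spanning tree weight
    d <- as.matrix(stats::dist(
      t(apply(states, 1, function(r) as.integer(factor(r,
        levels = c("A", "T"))))), method = "manhattan"))
    gfull <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                 weighted = TRUE)
    mst <- igraph::mst(gfull)
    expect_equal(length(unique(igraph::components(
      igraph::graph_from_data_frame(net@edges, directed = FALSE,
        vertices = net@nodes$id))$membership)), 1L)  # connected
    # total weight of any spanning tree inside the MSN equals MST weight
    gnet <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                          vertices = net@nodes$id)
    igraph::E(gnet)$weight <- net@edges$weight
    expect_equal(sum(igraph::E(igraph::mst(gnet))$weight),
                 sum(igraph::E(mst)$weight))
    # every MSN edge weight equals the Hamming distance of its endpoints
    for (i in seq_len(nrow(net@edges))) {
      a <- net@edges$from[i]; b <- net@edges$to[i]
      expect_equal(net@edges$weight[i],
                   sum(states[a, ] != states[b, ]))
    }
    expect_gte(nrow(net@edges), nrow(states) - 1L)
  }
})

test_that("median-joining augmentation stays connected and labelled", {
  states <- matrix(c("A", "A", "A",
                     "T", "T", "A",
                     "A", "T", "T"), 3, 3, byrow = TRUE,
                   dimnames = list(c("H1", "H2", "H3"), c("1", "2", "3")))
  net <- buildNetwork(states, method = "median_joining")
  gnet <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                        vertices = net@nodes$id)
  expect_equal(igraph::components(gnet)$no, 1L)
  expect_true(all(net@nodes$median[net@nodes$members == ""]))
})
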