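test_that("clone collapsing reproduces support counts (counting oracle)", {
  # three distinct clone types with counts 7, 7, 2 via clone_count weights
  tp <- twoParentClones()
  seqs <- c(tp$parents["P1"], tp$parents["P2"],
            sub("^AC", "TC", tp$parents["P1"]))
  names(seqs) <- c("h1", "h2", "h3")
  sheet <- data.frame(seq_id = c("h1", "h2", "h3"),
                      basidioma_id = "G25", locality = "BauSau",
                      clone_count = c(7L, 7L, 2L),
                      stringsAsFactors = FALSE)
  g <- collapseClones(seqs, sheet, "G25")
  expect_equal(g@support, c(7L, 7L, 2L))
  expect_equal(g@totalClones, 16L)
  expect_equal(length(g@sequences), 3L)

  # all clones identical -> 1 haplotype carrying the full count
  same <- c(a = tp$parents[["P1"]], b = tp$parents[["P1"]])
  sh <- data.frame(seq_id = c("a", "b"), basidioma_id = "B",
                   locality = "x", clone_count = c(5L, 4L),
                   stringsAsFactors = FALSE)
  g1 <- collapseClones(same, sh, "B")
  expect_equal(length(g1@sequences), 1L)
  expect_equal(g1@support, 9L)
  expect_error(collapseClones(same, sh, "nope"), "unknown")

  # random multiset: supports equal an exact-match counting oracle
  set.seed(21)
  pool <- c("AAAA", "AAAT", "AATT", "ATTT")
  draw <- sample(pool, 30, replace = TRUE)
  names(draw) <- sprintf("c%02d", 1:30)
  sh2 <- data.frame(seq_id = names(draw), basidioma_id = "B",
                    locality = "x", clone_count = 1L,
                    stringsAsFactors = FALSE)
  g2 <- collapseClones(draw, sh2, "B")
  oracle <- sort(table(draw), decreasing = TRUE)
  expect_equal(sort(g2@support, decreasing = TRUE),
               unname(sort(as.integer(oracle), decreasing = TRUE)))
  expect_equal(sum(g2@support), 30L)
})

test_that("singleton exclusion and dominant labelling follow the support rule", {
  mkGroup <- function(supports) {
    seqs <- vapply(seq_along(supports), function(i) {
      paste(c(rep("A", i), rep("C", length(supports) + 1 - i)),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("h", seq_along(supports))
    o <- order(-supports, names(seqs))
    new("CloneGroup", basidioma = "B", sequences = seqs[o],
        support = as.integer(supports[o]),
        members = as.list(names(seqs)[o]),
        totalClones = sum(as.integer(supports)))
  }
  c1 <- filterSingletons(mkGroup(c(7, 7, 2)))
  expect_equal(c1$status, c("dominant", "dominant", "minor_supported"))
  c2 <- filterSingletons(mkGroup(c(2, 1)))
  expect_equal(c2$status, c("dominant", "singleton_excluded"))
  c3 <- filterSingletons(mkGroup(c(1, 1, 1)))
  expect_true(all(c3$status == "singleton_excluded"))
  # collapse -> filter conserves total clone count across statuses
  expect_equal(sum(c1$support), 16)
  expect_equal(sum(c3$support), 3)
  # configurable threshold
  c4 <- filterSingletons(mkGroup(c(7, 3, 2)), minSupport = 3L)
  expect_equal(c4$status,
               c("dominant", "dominant", "singleton_excluded"))
})

test_that("shared-error probabilities calibrate to the printed anchors", {
  for (L in 15:17) {
    m <- errorModel(16L, L)
    p2 <- sharedErrorProbability(m, 2, "transition")
    p3 <- sharedErrorProbability(m, 3, "transition")
    # within a factor of 2 of the printed ~0.148 and ~0.022
    expect_gt(p2, 0.148 / 2); expect_lt(p2, 0.148 * 2)
    expect_gt(p3, 0.022 / 2); expect_lt(p3, 0.022 * 2)
    # halving rule is exact for every k
    for (k in 2:4) {
      expect_equal(sharedErrorProbability(m, k, "transversion"),
                   sharedErrorProbability(m, k, "transition") / 2)
    }
  }
  m <- errorModel(16L, 16L)
  expect_equal(sharedErrorProbability(m, 1, "transition"), 1)
  expect_equal(sharedErrorProbability(m, 17, "transition"), 0)
  # joint probability of a transition + transversion pair at k = 2 is the
  # product, near the printed ~0.011
  joint <- sharedErrorProbability(m, 2, "transition") *
    sharedErrorProbability(m, 2, "transversion")
  expect_gt(joint, 0.011 / 2); expect_lt(joint, 0.011 * 2)
})

test_that("shared-error probability is monotone in k and L", {
  for (variant in c("tuple", "binomial")) {
    m16 <- errorModel(20L, 16L, variant)
    p <- vapply(2:6, function(k) {
      sharedErrorProbability(m16, k, "transition")
    }, numeric(1))
    expect_true(all(diff(p) <= 0))
    pL <- vapply(c(5L, 10L, 20L, 40L), function(L) {
      sharedErrorProbability(errorModel(20L, L, variant), 2, "transition")
    }, numeric(1))
    expect_true(all(diff(pL) <= 0))
  }
})

test_that("closed form agrees with the Monte-Carlo coincidence oracle", {
  set.seed(99)
  for (case in list(c(16, 16, 2), c(16, 15, 3), c(10, 8, 2))) {
    n <- case[1]; L <- case[2]; k <- case[3]
    mc <- mcSharedErrorTransition(n, L, k, reps = 1e5)
    closed <- sharedErrorProbability(errorModel(n, L), k, "transition")
    expect_lt(abs(mc["mean"] - closed), 3 * mc["se"] + 1e-12)
  }
})

test_that("parent-count calls follow the evidence rules", {
  # G25-style: supports 7/7/2, minor with 2 unique polymorphisms
  base <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  p1 <- base; p2 <- base
  diffs <- c(10, 30, 50, 70, 90)
  p2[diffs] <- "T"
  minor <- base
  minor[diffs[1:2]] <- "T"          # shares left block with p2
  minor[c(61, 81)] <- c("G", "C")   # two unique polymorphisms (ts + tv)
  seqs <- c(rep(paste(p1, collapse = ""), 7),
            rep(paste(p2, collapse = ""), 7),
            rep(paste(minor, collapse = ""), 2))
  names(seqs) <- sprintf("c%02d", seq_along(seqs))
  sheet <- data.frame(seq_id = names(seqs), basidioma_id = "G25",
                      locality = "x", clone_count = 1L,
                      stringsAsFactors = FALSE)
  g <- collapseClones(seqs, sheet, "G25")
  calls <- annotateHaplotypeCalls(g, filterSingletons(g),
                                  model = errorModel(16L, 16L))
  minorRow <- calls[calls$status == "minor_supported", ]
  expect_equal(minorRow$unique_polymorphisms, 2L)
  expect_lt(minorRow$shared_error_p, 0.05)
  dom <- calls$haplotype[calls$status == "dominant"]
  xr <- minCrossovers(g@sequences[minorRow$haplotype], g@sequences[dom])
  expect_equal(length(xr@unexplained), 2L)
  pc <- callParentCount(g, calls,
                        stats::setNames(list(xr), minorRow$haplotype))
  expect_equal(pc$nParents, 3L)

  # single haplotype -> 1 parent with caveat
  one <- collapseClones(seqs[1:7], sheet[1:7, ], "G25")
  co <- annotateHaplotypeCalls(one, filterSingletons(one))
  pc1 <- callParentCount(one, co)
  expect_equal(pc1$nParents, 1L)
  expect_match(pc1$caveat, "undetected|homozygous")

  # minor fully reconstructable with 1 crossover and 0 unique sites -> 2
  rec <- base
  rec[diffs[1:2]] <- "T"            # p2 left, p1 right, no unique sites
  seqs2 <- c(seqs[1:14], rep(paste(rec, collapse = ""), 2))
  names(seqs2) <- sprintf("c%02d", seq_along(seqs2))
  sheet2 <- data.frame(seq_id = names(seqs2), basidioma_id = "B",
                       locality = "x", clone_count = 1L,
                       stringsAsFactors = FALSE)
  g2 <- collapseClones(seqs2, sheet2, "B")
  calls2 <- annotateHaplotypeCalls(g2, filterSingletons(g2),
                                   model = errorModel(16L, 16L))
  m2 <- calls2[calls2$status == "minor_supported", ]
  dom2 <- calls2$haplotype[calls2$status == "dominant"]
  xr2 <- minCrossovers(g2@sequences[m2$haplotype], g2@sequences[dom2])
  expect_equal(xr2@kSwitches, 1L)
  expect_equal(length(xr2@unexplained), 0L)
  pc2 <- callParentCount(g2, calls2,
                         stats::setNames(list(xr2), m2$haplotype))
  expect_equal(pc2$nParents, 2L)

  # nothing retained -> uncallable, not an exception
  lone <- collapseClones(seqs[c(1, 8)], sheet[c(1, 8), ], "G25")
  cl <- annotateHaplotypeCalls(lone, filterSingletons(lone))
  pcU <- callParentCount(lone, cl)
  expect_equal(pcU$status, "uncallable")
  expect_true(is.na(pcU$nParents))
})
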