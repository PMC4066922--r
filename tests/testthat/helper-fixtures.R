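# Fixture builders and independent oracles used across the test files.

# ITS polymorphism patterns of the 13 Vietnamese collections: four variable
# positions (195 indel, 338 T/C, 538 indel, 669 G/A) on a 669-column
# alignment with an otherwise constant background.
itsPatterns <- function() {
  data.frame(
    members = c("G2,G16,G19", "G25A", "G6,G11,G13", "G25B",
                "G1,G7A,G9,G24B", "G7B", "G24A", "G3A", "G30", "G3B"),
    p195 = c("A", "A", "A", "A", "-", "-", "-", "-", "-", "-"),
    p338 = c("T", "T", "T", "T", "C", "C", "C", "T", "T", "T"),
    p538 = c("A", "A", "-", "-", "-", "-", "A", "A", "-", "-"),
    p669 = c("G", "A", "G", "A", "G", "A", "G", "G", "A", "G"),
    stringsAsFactors = FALSE)
}

makeItsAlignment <- function() {
  pat <- itsPatterns()
  L <- 669L
  background <- strsplit(paste(rep("ACGT", ceiling(L / 4)), collapse = ""),
                         "", fixed = TRUE)[[1]][seq_len(L)]
  seqs <- character(0)
  for (i in seq_len(nrow(pat))) {
    for (id in strsplit(pat$members[i], ",", fixed = TRUE)[[1]]) {
      v <- background
      v[195] <- pat$p195[i]; v[338] <- pat$p338[i]
      v[538] <- pat$p538[i]; v[669] <- pat$p669[i]
      seqs[id] <- paste(v, collapse = "")
    }
  }
  seqs
}

itsRegions <- function() RegionMap(1L, 669L, "exon", 669L)

# published tef1a mutation-spectrum counts (per class x region)
tef1aSpectrumCounts <- function() {
  cnt <- cbind(exon = c(5L, 22L, 2L, 1L, 2L, 0L, 0L),
               intron = c(7L, 44L, 9L, 12L, 6L, 7L, 12L))
  rownames(cnt) <- c("A-G", "C-T", "A-C", "A-T", "C-G", "G-T", "indel")
  cnt
}

tef1aRegionLengths <- function() c(exon = 586, intron = 207)

# exhaustive minimal-switch count over all parent-assignment paths
bruteForceMinSwitches <- function(childStates, parentStates) {
  nS <- length(childStates)
  allowed <- lapply(seq_len(nS), function(i) {
    which(vapply(parentStates, function(p) p[i] == childStates[i],
                 logical(1)))
  })
  if (any(lengths(allowed) == 0L)) stop("child unexplained at some site")
  paths <- expand.grid(allowed, KEEP.OUT.ATTRS = FALSE)
  min(apply(as.matrix(paths), 1, function(p) {
    if (length(p) < 2L) 0L else sum(p[-1] != p[-length(p)])
  }))
}

# random toy: nP parents differing at nS sites, child mosaics the parents
randomCrossoverToy <- function(nP, nS) {
  L <- 2L * nS
  pos <- sort(sample(L, nS))
  parents <- matrix("A", nP, L)
  for (i in seq_len(nS)) {
    st <- sample(c("C", "G", "T", "-"), nP, replace = TRUE)
    while (length(unique(st)) == 1L) {
      st <- sample(c("C", "G", "T", "-"), nP, replace = TRUE)
    }
    parents[, pos[i]] <- st
  }
  child <- vapply(seq_len(L), function(j) parents[sample(nP, 1L), j],
                  character(1))
  pseqs <- apply(parents, 1, paste, collapse = "")
  names(pseqs) <- paste0("P", seq_len(nP))
  list(child = stats::setNames(paste(child, collapse = ""), "child"),
       parents = pseqs, childStates = child, parentStates = parents,
       pos = pos)
}

# Monte-Carlo oracle for the shared-error closed form: each clone draws one
# mutation (site uniform over L, change with transition:transversion:
# transversion weights 2:1:1); coincidences are counted as k-tuples of
# clones reproducing the focal specific transition, so the mean matches
# choose(n,k) * (1/(2L))^k exactly in expectation.
mcSharedErrorTransition <- function(n, L, k, reps = 1e5) {
  site <- matrix(sample.int(L, n * reps, replace = TRUE), nrow = reps)
  change <- matrix(sample.int(4L, n * reps, replace = TRUE), nrow = reps)
  hits <- rowSums(site == 1L & change <= 2L)  # weight 2 of 4 = transition
  vals <- choose(hits, k)
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(reps))
}

# brute-force per-column polymorphic scan (no gap-run merging; used on
# gap-free toys)
columnScanSites <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  which(vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]; v <- v[v != "N"]
    length(unique(v)) > 1L
  }, logical(1)))
}

# a small clone data set: 2 parents differing at fixed positions
twoParentClones <- function(nClones = 8L, L = 60L, diffAt = c(10L, 30L, 50L)) {
  base <- strsplit(paste(rep("ACGT", L / 4), collapse = ""), "")[[1]]
  p1 <- base
  p2 <- base
  p2[diffAt] <- c("T", "G", "A")[seq_along(diffAt)]
  parents <- c(P1 = paste(p1, collapse = ""), P2 = paste(p2, collapse = ""))
  idx <- rep(1:2, length.out = nClones)
  seqs <- unname(parents[idx])
  names(seqs) <- sprintf("c%02d", seq_len(nClones))
  sheet <- data.frame(seq_id = names(seqs), basidioma_id = "B1",
                      locality = "locA", clone_count = 1L,
                      stringsAsFactors = FALSE)
  list(parents = parents, clones = seqs, sheet = sheet)
}
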