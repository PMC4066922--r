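test_that("mutation classification follows the purine-pyrimidine rule", {
  expect_equal(classifyMutation("T", "C"), "transition")
  expect_equal(classifyMutation("A", "G"), "transition")
  expect_equal(classifyMutation("C", "G"), "transversion")
  expect_equal(classifyMutation("A", "-"), "indel")
  expect_equal(classifyMutation("--", "AG"), "indel")
  # symmetric and total over distinct base pairs
  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in bases) {
    if (a == b) {
      expect_error(classifyMutation(a, b), "distinct")
    } else {
      expect_identical(classifyMutation(a, b), classifyMutation(b, a))
      expect_true(classifyMutation(a, b) %in%
                    c("transition", "transversion"))
    }
  }
})

test_that("ITS-style alignment yields the four published sites and classes", {
  aln <- makeItsAlignment()
  sites <- findPolymorphicSites(aln, itsRegions())
  expect_equal(sites@sites$position, c(195L, 338L, 538L, 669L))
  expect_equal(sites@events$class,
               c("indel", "C-T", "indel", "A-G"))
  hm <- haplotypeMatrix(aln, sites)
  expect_equal(nrow(hm), 10L)  # ten distinct ITS haplotypes
})

test_that("polymorphic-site finder agrees with a per-column scan oracle", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T", "N"), 8 * 30, replace = TRUE,
                       prob = c(.3, .3, .2, .15, .05)), 8, 30)
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- paste0("s", 1:8)
    rm <- RegionMap(1L, 30L, "exon", 30L)
    got <- findPolymorphicSites(seqs, rm)
    oracle <- columnScanSites(seqs)
    skipped <- which(apply(m == "N", 2, any))
    expect_setequal(got@sites$position, setdiff(oracle, skipped))
    expect_setequal(got@skippedColumns, skipped)
  }
  # all-identical alignment -> no sites
  same <- rep("ACGTACGT", 4); names(same) <- paste0("s", 1:4)
  empty <- findPolymorphicSites(same, RegionMap(1L, 8L, "exon", 8L))
  expect_equal(nrow(empty@sites), 0L)
  expect_error(findPolymorphicSites(character(0),
                                    RegionMap(1L, 8L, "exon", 8L)))
})

test_that("identical gap runs merge into one indel event", {
  seqs <- c(s1 = "ACGTACGTAC",
            s2 = "AC----GTAC",  # one 4-bp deletion
            s3 = "ACGTACGTAC")
  rm <- RegionMap(1L, 10L, "intron", 10L)
  sites <- findPolymorphicSites(seqs, rm)
  ind <- sites@sites[sites@sites$type == "indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$position, 3L)
  expect_equal(ind$length, 4L)
  expect_equal(sum(sites@events$class == "indel"), 1L)

  # two different gap patterns stay separate events
  seqs2 <- c(s1 = "ACGTACGTAC", s2 = "AC--ACGTAC", s3 = "ACGTAC--AC")
  sites2 <- findPolymorphicSites(seqs2, rm)
  expect_equal(sum(sites2@events$class == "indel"), 2L)
})

test_that("multi-allelic sites contribute nStates - 1 minor-major events", {
  seqs <- c(s1 = "AAAA", s2 = "CAAA", s3 = "GAAA", s4 = "AAAA")
  rm <- RegionMap(1L, 4L, "exon", 4L)
  sites <- findPolymorphicSites(seqs, rm)
  ev <- sites@events
  expect_equal(nrow(ev), 2L)           # A majority; C and G minors
  expect_setequal(ev$class, c("A-C", "A-G"))
  all_pairs <- findPolymorphicSites(seqs, rm, pairing = "all_pairs")
  expect_equal(nrow(all_pairs@events), 3L)  # A-C, A-G, C-G
})

test_that("spectrum table reproduces published-style totals and frequencies", {
  st <- spectrumFromCounts(tef1aSpectrumCounts(), tef1aRegionLengths())
  s <- spectrumSummary(st)
  get <- function(row, col) s[s$mutation == row, col]
  expect_equal(get("transitions", "exon"), 27)
  expect_equal(get("transversions", "exon"), 5)
  expect_equal(get("total", "exon"), 32)
  expect_equal(get("transitions", "intron"), 51)
  expect_equal(get("transversions", "intron"), 34)
  expect_equal(get("total", "intron"), 97)
  expect_equal(get("total", "total"), 129)
  # class conservation per region: classes sum to the region total
  expect_equal(sum(st@counts[, "exon"]), unname(totalMutations(st)["exon"]))
  expect_equal(sum(st@counts[, "intron"]),
               unname(totalMutations(st)["intron"]))
  # frequencies, printed at 1 dp by truncation
  expect_equal(polykaryon:::truncDigits(polymorphismFrequency(st, "intron"), 1), 46.8)
  expect_equal(polykaryon:::truncDigits(polymorphismFrequency(st, "exon"), 1), 5.4)
  expect_equal(polymorphismFrequency(
    spectrumFromCounts(tef1aSpectrumCounts() * 0L, tef1aRegionLengths()),
    "exon"), 0)
})

test_that("spectrumTable aggregates events from an alignment consistently", {
  cfg <- simConfig(seed = 12)
  pool <- simulateParentalPool(cfg)
  sites <- findPolymorphicSites(pool$alignment, pool$regions)
  st <- spectrumTable(sites, pool$regions)
  # conservation: event rows equal count cells
  for (reg in colnames(st@counts)) {
    expect_equal(sum(st@counts[, reg]),
                 sum(sites@events$region == reg))
  }
  # exon indels never occur under the simulator's model
  expect_equal(st@counts["indel", "exon"], 0L)
})

test_that("haplotype matrix groups identical patterns (hash oracle)", {
  set.seed(3)
  base <- strsplit(paste(rep("ACGT", 10), collapse = ""), "")[[1]]
  variants <- lapply(1:6, function(i) {
    v <- base
    v[sample(40, 2)] <- "T"
    paste(v, collapse = "")
  })
  seqs <- unlist(variants)[c(1, 2, 1, 3, 2, 4, 5, 6, 1)]
  names(seqs) <- paste0("s", seq_along(seqs))
  rm <- RegionMap(1L, 40L, "exon", 40L)
  sites <- findPolymorphicSites(seqs, rm)
  hm <- haplotypeMatrix(seqs, sites)
  # oracle: group by full-sequence identity
  oracle <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  expect_equal(nrow(hm), length(oracle))
  expect_setequal(hm$members,
                  vapply(oracle, paste, character(1), collapse = ","))
  # single sequence -> single row
  one <- haplotypeMatrix(seqs[1], findPolymorphicSites(
    c(seqs[1], seqs[1]), rm))
  expect_equal(nrow(one), 1L)
})
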