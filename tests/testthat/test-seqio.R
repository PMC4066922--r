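test_that("FASTA reading validates shape, ids and alphabet", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT-ACGTA", ">b", "acgttacgta", ">c", "ACGTNACGTA"),
             tmp)
  aln <- readAlignment(tmp)
  expect_s4_class(aln, "DNAStringSet")
  expect_equal(length(aln), 3L)
  expect_equal(unique(Biostrings::width(aln)), 10L)
  expect_equal(as.character(aln[["b"]]), "ACGTTACGTA")  # uppercased

  writeLines(c(">short", "ACGT", ">long", "ACGTA"), tmp)
  expect_error(readAlignment(tmp), "short|long")

  writeLines(c(">x", "ACGXACGT"), tmp)
  expect_error(readAlignment(tmp), "position 4")

  writeLines(c(">a", "ACGT", ">a", "ACGT"), tmp)
  expect_error(readAlignment(tmp), "duplicate")

  writeLines(c(">rna", "ACGU"), tmp)
  expect_warning(aln <- readAlignment(tmp), "'U'")
  expect_equal(as.character(aln[[1]]), "ACGT")
})

test_that("write-then-read round-trips ids and sequences losslessly", {
  cfg <- simConfig(seed = 5, nParentalPool = 6L)
  sim <- simulateDataset(cfg, nBasidiomata = 2L)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeAlignment(sim$alignment, f1)
  back <- readAlignment(f1)
  expect_identical(names(back), names(sim$alignment))
  expect_identical(as.character(back), as.character(sim$alignment))
  writeAlignment(back, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical re-write
})

test_that("BED regions convert to 1-based inclusive and must tile exactly", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines("locus\t0\t586\texon", tmp)
  r <- readRegions(tmp, 586L)
  expect_equal(IRanges::start(r@ranges), 1L)
  expect_equal(IRanges::end(r@ranges), 586L)
  expect_equal(regionLengths(r), c(exon = 586L))

  # tef1a-style layout: 5 exon segments interleaved with 4 introns of
  # 50-58 columns; totals must add up to the alignment length
  exonSeg <- c(118, 117, 117, 117, 117)
  intrLen <- c(50, 53, 56, 58)
  starts0 <- integer(0); ends0 <- integer(0); lab <- character(0)
  pos <- 0
  for (i in 1:5) {
    starts0 <- c(starts0, pos); pos <- pos + exonSeg[i]
    ends0 <- c(ends0, pos); lab <- c(lab, "exon")
    if (i <= 4) {
      starts0 <- c(starts0, pos); pos <- pos + intrLen[i]
      ends0 <- c(ends0, pos); lab <- c(lab, "intron")
    }
  }
  writeLines(sprintf("locus\t%d\t%d\t%s", starts0, ends0, lab), tmp)
  r <- readRegions(tmp, pos)
  expect_equal(length(r@ranges), 9L)
  expect_equal(sum(regionLengths(r)), 586L + sum(intrLen))
  expect_equal(unname(regionLengths(r)["exon"]), 586L)

  writeLines(c("locus\t0\t300\texon", "locus\t250\t586\tintron"), tmp)
  expect_error(readRegions(tmp, 586L), "overlap")
  writeLines(c("locus\t0\t300\texon", "locus\t350\t586\tintron"), tmp)
  expect_error(readRegions(tmp, 586L), "cover")
  writeLines("locus\t0\t600\tpromoter", tmp)
  expect_error(readRegions(tmp, 600L), "exon")
})

test_that("partitionAlignment keeps exactly the labelled columns", {
  # random 20-column toy, per-column labels: compare to a column-mask oracle
  set.seed(42)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 20, replace = TRUE), 5, 20)
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- paste0("s", 1:5)
  labs <- rep(c("exon", "intron"), each = 2, length.out = 20)
  runs <- rle(labs)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  rm <- RegionMap(starts, ends, runs$values, 20L)

  ex <- partitionAlignment(seqs, rm, "exon")
  oracle <- apply(m[, labs == "exon", drop = FALSE], 1, paste, collapse = "")
  expect_equal(unname(as.character(ex)), unname(oracle))
  expect_identical(names(ex), names(seqs))

  # identity on a single full-cover interval
  whole <- RegionMap(1L, 20L, "exon", 20L)
  expect_equal(as.character(partitionAlignment(seqs, whole, "exon")),
               stats::setNames(seqs, names(seqs)))
  expect_error(partitionAlignment(seqs, whole, "intron"), "absent")

  # exon + intron columns jointly conserve the input columns
  intr <- partitionAlignment(seqs, rm, "intron")
  expect_equal(Biostrings::width(ex)[1] + Biostrings::width(intr)[1], 20L)
  mask <- labs == "exon"
  rebuilt <- character(5)
  em <- do.call(rbind, strsplit(as.character(ex), ""))
  im <- do.call(rbind, strsplit(as.character(intr), ""))
  for (i in 1:5) {
    v <- character(20); v[mask] <- em[i, ]; v[!mask] <- im[i, ]
    rebuilt[i] <- paste(v, collapse = "")
  }
  expect_equal(rebuilt, unname(seqs))
})

test_that("sample sheets validate ids, counts and alignment consistency", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tbasidioma_id\tlocality\tclone_count",
               "c1\tG1\tlocA\t7", "c2\tG1\tlocA\t2"), tmp)
  sheet <- readSampleSheet(tmp)
  expect_equal(sheet$clone_count, c(7L, 2L))
  aln <- c(c1 = "ACGT", c2 = "ACGA")
  expect_silent(validateSampleSheet <- readSampleSheet(tmp, aln))
  writeLines(c("seq_id\tbasidioma_id\tlocality\tclone_count",
               "c1\tG1\tlocA\t7", "c9\tG1\tlocA\t2"), tmp)
  expect_error(readSampleSheet(tmp, aln), "c9")
  writeLines(c("seq_id\tbasidioma_id\tlocality\tclone_count",
               "c1\tG1\tlocA\t0"), tmp)
  expect_error(readSampleSheet(tmp), "clone_count")
})
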