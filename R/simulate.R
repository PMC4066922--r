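#' Simulation configuration for cloned-amplicon data sets
#'
#' Defines the study conditions the simulator emulates: a 586-nt coding
#' region split by four short introns (50-58 nt), intron polymorphism
#' density roughly nine times the exon density, a C-T-dominated transition
#' bias, short (1-4 nt) intron-only indels, basidiomata formed from 2 or 3
#' parental haplotypes, multinomial clone sampling, PCR point errors and
#' PCR-mediated chimeras.
#'
#' @param exonLength total coding columns (default 586)
#' @param nIntrons number of introns (default 4)
#' @param intronLengthRange intron lengths drawn uniformly from this range
#'   (default 50-58)
#' @param exonPolyFraction expected fraction of exon sites polymorphic
#'   across the parental pool (default 0.054)
#' @param intronPolyFraction same for introns (default 0.468, ~9x the exon
#'   density)
#' @param exonTransitionProb probability a coding substitution is a
#'   transition (default 27/32, the dominant-transition spectrum)
#' @param intronTransitionProb same for intron substitutions (default 51/85)
#' @param intronIndelProb probability an intron mutation is an indel rather
#'   than a substitution (default 12/97); exon indels never occur
#' @param indelLengthRange indel lengths, uniform over this range (default
#'   1-4)
#' @param baseFreqs ancestral base frequencies; C/T-enriched by default so
#'   C-T transitions dominate
#' @param nParentalPool parental haplotypes in the local mating pool
#'   (default 20)
#' @param pThreeParents probability a basidioma receives 3 parents instead
#'   of 2 (default 0.25)
#' @param clonesPerBasidioma clones sequenced per basidioma (default 16)
#' @param cloneProportions contribution proportions of the parents; `NULL`
#'   (default) = uniform. A skewed vector (e.g. `c(7, 7, 2)/16`) emulates
#'   unequal parental representation
#' @param pcrErrorRate per-base per-clone PCR point error rate (default
#'   1e-4)
#' @param chimeraRate per-clone probability of a PCR-mediated template
#'   switch onto another parent (default 0.02)
#' @param nPopulations demes for population-structure scenarios (default 3)
#' @param demePrivateMutations deme-private mutations added to every parent
#'   of a deme; 0 (default) = panmixia
#' @param seed mandatory RNG seed
#' @return a validated `SimConfig` (list with class attribute)
#' @export
simConfig <- function(exonLength = 586L,
                      nIntrons = 4L,
                      intronLengthRange = c(50L, 58L),
                      exonPolyFraction = 0.054,
                      intronPolyFraction = 0.468,
                      exonTransitionProb = 27 / 32,
                      intronTransitionProb = 51 / 85,
                      intronIndelProb = 12 / 97,
                      indelLengthRange = c(1L, 4L),
                      baseFreqs = c(A = 0.15, C = 0.35, G = 0.15, T = 0.35),
                      nParentalPool = 20L,
                      pThreeParents = 0.25,
                      clonesPerBasidioma = 16L,
                      cloneProportions = NULL,
                      pcrErrorRate = 1e-4,
                      chimeraRate = 0.02,
                      nPopulations = 3L,
                      demePrivateMutations = 0L,
                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(exonLength = as.integer(exonLength),
              nIntrons = as.integer(nIntrons),
              intronLengthRange = as.integer(intronLengthRange),
              exonPolyFraction = exonPolyFraction,
              intronPolyFraction = intronPolyFraction,
              exonTransitionProb = exonTransitionProb,
              intronTransitionProb = intronTransitionProb,
              intronIndelProb = intronIndelProb,
              indelLengthRange = as.integer(indelLengthRange),
              baseFreqs = baseFreqs,
              nParentalPool = as.integer(nParentalPool),
              pThreeParents = pThreeParents,
              clonesPerBasidioma = as.integer(clonesPerBasidioma),
              cloneProportions = cloneProportions,
              pcrErrorRate = pcrErrorRate,
              chimeraRate = chimeraRate,
              nPopulations = as.integer(nPopulations),
              demePrivateMutations = as.integer(demePrivateMutations),
              seed = as.integer(seed))
  rates <- c(cfg$exonPolyFraction, cfg$intronPolyFraction,
             cfg$exonTransitionProb, cfg$intronTransitionProb,
             cfg$intronIndelProb, cfg$pThreeParents, cfg$pcrErrorRate,
             cfg$chimeraRate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$nParentalPool < 1L) stop("nParentalPool must be >= 1")
  if (abs(sum(cfg$baseFreqs) - 1) > 1e-8) stop("baseFreqs must sum to 1")
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig (seed", x$seed, ")\n")
  cat("  locus:", x$exonLength, "nt exon,", x$nIntrons, "introns of",
      paste(x$intronLengthRange, collapse = "-"), "nt\n")
  cat("  poly fractions: exon", x$exonPolyFraction, "intron",
      x$intronPolyFraction, "\n")
  cat("  pool", x$nParentalPool, "parents;",
      x$clonesPerBasidioma, "clones/basidioma; P(3 parents)",
      x$pThreeParents, "\n")
  cat("  pcrErrorRate", x$pcrErrorRate, "chimeraRate", x$chimeraRate, "\n")
  invisible(x)
}

# expected distinct mutation events per site, K parents mutating at rate mu:
# one transition target and two transversion targets per site, indels
# (probability pInd of a mutation) essentially always distinct
expectedEventsPerSite <- function(mu, K, pTs, pInd) {
  w <- c(pTs, (1 - pTs) / 2, (1 - pTs) / 2) * (1 - pInd)
  sum(1 - (1 - mu * w)^K) + K * mu * pInd
}

# invert expectedEventsPerSite for the target event fraction f
calibrateMu <- function(f, K, pTs, pInd) {
  if (f <= 0) return(0)
  stats::uniroot(function(mu) expectedEventsPerSite(mu, K, pTs, pInd) - f,
                 interval = c(1e-9, 0.5), tol = 1e-10)$root
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

# substitute base b: transition w.p. pTs, else one of its two transversions
substituteBase <- function(b, pTs) {
  if (stats::runif(1) < pTs) {
    TRANSITION_OF[[b]]
  } else {
    sample(TRANSVERSIONS_OF[[b]], 1L)
  }
}

#' Simulate a pool of parental haplotypes
#'
#' Draws an ancestral sequence from the configured base frequencies, lays
#' out the exon/intron structure (the coding region split into
#' `nIntrons + 1` segments with the introns in between), then derives each
#' parental haplotype by independent mutation from the ancestor (star
#' genealogy): per-region per-site mutation probabilities are set so the
#' expected polymorphic fraction across the pool matches the configured
#' targets; intron mutations are indels (1-4 nt deletions, clipped to the
#' intron) with the configured probability, substitutions otherwise.
#' Deterministic given the config seed.
#'
#' @param config a [simConfig()] object
#' @return list with `alignment` (`DNAStringSet` of parents), `regions`
#'   ([RegionMap-class]), `ancestor` (character) and `truth` (per-parent
#'   injected mutation records)
#' @export
simulateParentalPool <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$nParentalPool < 1L) stop("degenerate config: zero parents")
  set.seed(config$seed)
  simulateParentalPoolNoSeed(config)
}

# internal: uses the current RNG stream (callers manage seeding)
simulateParentalPoolNoSeed <- function(config) {
  nI <- config$nIntrons
  intronLen <- if (nI > 0L) {
    sample(seq(config$intronLengthRange[1], config$intronLengthRange[2]),
           nI, replace = TRUE)
  } else integer(0)
  # split the coding region into nI + 1 segments of near-equal length
  exonSeg <- diff(round(seq(0, config$exonLength, length.out = nI + 2)))
  starts <- integer(0); ends <- integer(0); labels <- character(0)
  pos <- 0L
  for (i in seq_len(nI + 1L)) {
    starts <- c(starts, pos + 1L); ends <- c(ends, pos + exonSeg[i])
    labels <- c(labels, "exon"); pos <- pos + exonSeg[i]
    if (i <= nI) {
      starts <- c(starts, pos + 1L); ends <- c(ends, pos + intronLen[i])
      labels <- c(labels, "intron"); pos <- pos + intronLen[i]
    }
  }
  L <- pos
  regions <- RegionMap(starts, ends, labels, L)
  lab <- columnLabels(regions)
  anc <- sample(names(config$baseFreqs), L, replace = TRUE,
                prob = config$baseFreqs)

  K <- config$nParentalPool
  # per-parent per-site mutation probability calibrated so the expected
  # number of distinct mutation events per site across the pool matches the
  # configured polymorphic fraction (mutation events per nt, the scale on
  # which spectrum frequencies are reported)
  muExon <- calibrateMu(config$exonPolyFraction, K,
                        config$exonTransitionProb, 0)
  muIntron <- calibrateMu(config$intronPolyFraction, K,
                          config$intronTransitionProb,
                          config$intronIndelProb)
  mu <- ifelse(lab == "exon", muExon, muIntron)

  parents <- matrix(rep(anc, K), nrow = K, byrow = TRUE)
  rownames(parents) <- sprintf("P%02d", seq_len(K))
  truth <- list()
  intronIdx <- which(lab == "intron")
  for (p in seq_len(K)) {
    hit <- which(stats::runif(L) < mu)
    recs <- list()
    for (j in hit) {
      if (parents[p, j] == "-") next   # already inside a deleted run
      if (lab[j] == "intron" && stats::runif(1) < config$intronIndelProb) {
        len <- sample(seq(config$indelLengthRange[1],
                          config$indelLengthRange[2]), 1L)
        # clip the deletion to its intron
        cand <- seq.int(j, min(j + len - 1L, L))
        run <- cand[cumprod(lab[cand] == "intron") == 1]
        parents[p, run] <- "-"
        recs[[length(recs) + 1L]] <- data.frame(
          parent = rownames(parents)[p], position = j, type = "indel",
          from = paste(anc[run], collapse = ""),
          to = strrep("-", length(run)), stringsAsFactors = FALSE)
      } else {
        pTs <- if (lab[j] == "exon") config$exonTransitionProb else
          config$intronTransitionProb
        nb <- substituteBase(parents[p, j], pTs)
        recs[[length(recs) + 1L]] <- data.frame(
          parent = rownames(parents)[p], position = j,
          type = "substitution", from = parents[p, j], to = nb,
          stringsAsFactors = FALSE)
        parents[p, j] <- nb
      }
    }
    truth[[p]] <- if (length(recs)) do.call(rbind, recs) else NULL
  }
  aln <- Biostrings::DNAStringSet(
    apply(parents, 1, paste, collapse = ""))
  list(alignment = aln, regions = regions, ancestor = paste(anc, collapse = ""),
       truth = do.call(rbind, truth))
}

#' Simulate the sequenced clones of one basidioma
#'
#' Draws the parental haplotypes without replacement from the pool,
#' allocates the sequenced clones to parents by a multinomial draw over the
#' contribution proportions, then pushes each clone through the PCR error
#' model: with probability `chimeraRate` the clone is a chimera switching
#' template to another of the basidioma's parents at a uniform breakpoint
#' column, and every non-gap base mutates independently at `pcrErrorRate`
#' with transition:transversion:transversion weights 2:1:1.
#'
#' @param pool result of [simulateParentalPool()]
#' @param config a [simConfig()] object
#' @param basidiomaId id for the simulated fruit body
#' @param nParents number of contributing parents; `NULL` (default) draws
#'   2 or 3 with probability `1 - pThreeParents` / `pThreeParents`
#' @return list with `clones` (`DNAStringSet`), `sheet` (sample-sheet rows,
#'   one per clone, `clone_count = 1`), and `truth` (data.frame: clone,
#'   parent, chimera partner/breakpoint, injected error positions;
#'   plus attribute `"parents"`)
#' @export
simulateBasidioma <- function(pool, config, basidiomaId = "B1",
                              nParents = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  parents <- as.character(pool$alignment)
  if (is.null(nParents)) {
    nParents <- if (stats::runif(1) < config$pThreeParents) 3L else 2L
  }
  if (length(parents) < nParents) {
    stop("pool smaller than parents per basidioma")
  }
  pick <- sample(names(parents), nParents)
  prop <- config$cloneProportions
  if (is.null(prop)) prop <- rep(1 / nParents, nParents)
  if (length(prop) != nParents) {
    stop("cloneProportions must have one entry per parent")
  }
  nClones <- config$clonesPerBasidioma
  alloc <- as.integer(stats::rmultinom(1, nClones, prob = prop))
  cloneParent <- rep(pick, alloc)
  L <- nchar(parents[1])
  seqs <- character(nClones)
  truth <- vector("list", nClones)
  for (i in seq_len(nClones)) {
    par1 <- cloneParent[i]
    s <- strsplit(parents[[par1]], "", fixed = TRUE)[[1]]
    partner <- NA_character_; brk <- NA_integer_
    if (nParents > 1L && stats::runif(1) < config$chimeraRate) {
      partner <- sample(setdiff(pick, par1), 1L)
      brk <- sample.int(L - 1L, 1L)
      s2 <- strsplit(parents[[partner]], "", fixed = TRUE)[[1]]
      s[(brk + 1L):L] <- s2[(brk + 1L):L]
    }
    errPos <- which(stats::runif(L) < config$pcrErrorRate & s != "-")
    for (j in errPos) s[j] <- substituteBase(s[j], 0.5)
    seqs[i] <- paste(s, collapse = "")
    truth[[i]] <- data.frame(
      clone = sprintf("%s_c%02d", basidiomaId, i), basidioma = basidiomaId,
      parent = par1, chimera_partner = partner, chimera_breakpoint = brk,
      error_positions = paste(errPos, collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  names(seqs) <- truth$clone
  sheet <- data.frame(seq_id = truth$clone, basidioma_id = basidiomaId,
                      locality = "sim", clone_count = 1L,
                      stringsAsFactors = FALSE)
  attr(truth, "parents") <- pick
  list(clones = Biostrings::DNAStringSet(seqs), sheet = sheet, truth = truth)
}

#' Simulate a complete cloned-amplicon data set
#'
#' Generates a parental pool, allocates basidiomata to demes (adding
#' deme-private mutations to their parents when `demePrivateMutations > 0`),
#' and simulates the sequenced clones of every basidioma. Identical seed
#' and config give byte-identical outputs.
#'
#' @param config a [simConfig()] object
#' @param nBasidiomata number of fruit bodies (default 10)
#' @return list with `alignment` (all clones), `sheet`, `regions`, `pool`,
#'   and `truth` (list: `clones` data.frame, `parents` per basidioma,
#'   `population` per basidioma)
#' @export
simulateDataset <- function(config, nBasidiomata = 10L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  pool <- simulateParentalPoolNoSeed(config)
  demes <- sprintf("pop%d", 1 + (seq_len(nBasidiomata) - 1L) %%
                     config$nPopulations)
  demes <- sample(demes)
  poolSeq <- as.character(pool$alignment)
  L <- nchar(poolSeq[1])

  demePools <- list()
  for (d in unique(demes)) {
    ps <- poolSeq
    if (config$demePrivateMutations > 0L) {
      # deme-private marker mutations shared by all of the deme's parents
      pos <- sample.int(L, config$demePrivateMutations)
      for (j in pos) {
        m <- do.call(rbind, strsplit(ps, "", fixed = TRUE))
        b <- majorityState(m[, j][m[, j] != "-"])
        nb <- substituteBase(b, 0.5)
        for (p in seq_along(ps)) {
          v <- strsplit(ps[p], "", fixed = TRUE)[[1]]
          if (v[j] != "-") v[j] <- nb
          ps[p] <- paste(v, collapse = "")
        }
      }
    }
    demePools[[d]] <- ps
  }

  clones <- character(0)
  sheets <- list()
  cloneTruth <- list()
  parentsOf <- list()
  for (b in seq_len(nBasidiomata)) {
    id <- sprintf("G%02d", b)
    demePool <- pool
    demePool$alignment <- Biostrings::DNAStringSet(demePools[[demes[b]]])
    sim <- simulateBasidioma(demePool, config, basidiomaId = id)
    sim$sheet$locality <- demes[b]
    clones <- c(clones, as.character(sim$clones))
    sheets[[b]] <- sim$sheet
    cloneTruth[[b]] <- sim$truth
    parentsOf[[id]] <- attr(sim$truth, "parents")
  }
  list(alignment = Biostrings::DNAStringSet(clones),
       sheet = do.call(rbind, sheets),
       regions = pool$regions,
       pool = pool,
       truth = list(clones = do.call(rbind, cloneTruth),
                    parents = parentsOf,
                    population = stats::setNames(demes,
                                                 names(parentsOf))))
}

#' Write a simulated data set to disk
#'
#' Emits the aligned clone FASTA, a BED region file (0-based half-open), a
#' TSV sample sheet and a JSON truth file, with the seed recorded in the
#' FASTA header comment line of the first record and in the truth file.
#'
#' @param sim result of [simulateDataset()]
#' @param dir output directory (created if needed)
#' @param config the [simConfig()] used (seed recorded in the truth JSON)
#' @return `dir`, invisibly
#' @export
writeSimulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlignment(sim$alignment, file.path(dir, "clones.fasta"))
  r <- sim$regions
  bed <- data.frame(chrom = "locus",
                    start = IRanges::start(r@ranges) - 1L,
                    end = IRanges::end(r@ranges),
                    label = r@label)
  utils::write.table(bed, file.path(dir, "regions.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeSampleSheet(sim$sheet, file.path(dir, "samples.tsv"))
  truth <- sim$truth
  truth$seed <- if (!is.null(config)) config$seed else NA
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(dir)
}
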