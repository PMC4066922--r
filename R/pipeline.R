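#' Run the full polykaryon analysis pipeline
#'
#' Orchestrates the stages on file inputs: read and validate the alignment,
#' regions and sample sheet; call polymorphic sites and the mutation
#' spectrum; collapse clones per basidioma, apply singleton exclusion and
#' the birthday-paradox annotation; explain minor haplotypes as recombinants
#' of the dominant pair and call the parental haplotype count; run the PHI
#' recombination test; compute gene diversity/Fst across localities and the
#' haplotype network. Writes TSV/JSON reports plus a run manifest to
#' `outputDir`. Reruns with the same inputs and seed produce identical
#' reports (manifest timestamp aside).
#'
#' @param alignmentFile aligned clone FASTA
#' @param regionsFile BED-style exon/intron file
#' @param sampleSheetFile TSV sample sheet
#' @param outputDir output directory (created)
#' @param minSupport singleton-exclusion threshold (default 2)
#' @param alpha shared-error significance threshold (default 0.05)
#' @param maxCrossoversRecent crossover budget for a recent recombinant
#'   (default 2)
#' @param window,nPermutations PHI test parameters
#' @param estimator Fst estimator (default `"wc_theta"`)
#' @param networkMethod `"msn"` or `"median_joining"`
#' @param seed RNG seed for all stochastic stages
#' @return invisibly, a list with all stage results (`spectrum`, `sites`,
#'   `calls`, `parentCounts`, `phi`, `diversity`, `network`)
#' @export
runPipeline <- function(alignmentFile, regionsFile, sampleSheetFile,
                        outputDir, minSupport = 2L, alpha = 0.05,
                        maxCrossoversRecent = 2L, window = 100L,
                        nPermutations = 1000L,
                        estimator = c("wc_theta", "nei_gst"),
                        networkMethod = c("msn", "median_joining"),
                        seed = 1L) {
  estimator <- match.arg(estimator)
  networkMethod <- match.arg(networkMethod)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)

  aln <- readAlignment(alignmentFile)
  regions <- readRegions(regionsFile, Biostrings::width(aln)[1])
  sheet <- readSampleSheet(sampleSheetFile, aln)

  sites <- findPolymorphicSites(aln, regions)
  spectrum <- spectrumTable(sites, regions)
  writePolymorphicSites(sites, file.path(outputDir, "sites.tsv"))
  utils::write.table(spectrumSummary(spectrum),
                     file.path(outputDir, "spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  basidiomata <- unique(sheet$basidioma_id)
  callRows <- list()
  parentCounts <- list()
  for (b in basidiomata) {
    group <- collapseClones(aln, sheet, b)
    calls <- filterSingletons(group, minSupport = minSupport)
    calls <- annotateHaplotypeCalls(group, calls)
    dom <- calls$haplotype[calls$status == "dominant"]
    minors <- calls$haplotype[calls$status == "minor_supported"]
    xr <- list()
    if (length(dom) >= 2L) {
      for (h in minors) {
        xr[[h]] <- minCrossovers(group@sequences[h],
                                 group@sequences[dom])
      }
    }
    pc <- callParentCount(group, calls, xr, alpha = alpha,
                          maxCrossoversRecent = maxCrossoversRecent)
    callRows[[b]] <- calls
    parentCounts[[b]] <- pc
  }
  allCalls <- do.call(rbind, callRows)
  utils::write.table(allCalls, file.path(outputDir, "haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(parentCounts, function(pc) {
      list(basidioma = pc$basidioma, n_parents = pc$nParents,
           status = pc$status, caveat = pc$caveat,
           evidence = pc$evidence)
    }),
    file.path(outputDir, "parent_counts.json"),
    auto_unbox = TRUE, digits = 6, na = "null", null = "null")

  phi <- phiTest(aln, window = window, nPermutations = nPermutations,
                 seed = seed)
  jsonlite::write_json(
    list(statistic = phi@statistic, p_value = phi@pValue,
         n_informative = phi@nInformative, computable = phi@computable,
         window = phi@windowSize, permutations = phi@nPermutations,
         seed = seed),
    file.path(outputDir, "phi.json"), auto_unbox = TRUE, digits = 6,
    na = "null")

  # diversity on exon haplotypes: one entry per retained haplotype
  exAln <- partitionAlignment(aln, regions, "exon")
  indiv <- character(0); pops <- character(0)
  for (b in basidiomata) {
    keep <- allCalls$haplotype[allCalls$basidioma == b &
                                 allCalls$status != "singleton_excluded"]
    loc <- sheet$locality[match(keep, sheet$seq_id)]
    indiv <- c(indiv, as.character(exAln)[keep])
    pops <- c(pops, loc)
  }
  diversity <- if (length(unique(pops)) >= 2L) {
    geneDiversityFst(indiv, pops, estimator = estimator, seed = seed)
  } else NULL
  if (!is.null(diversity)) {
    utils::write.table(
      data.frame(estimator = diversity@estimator, Hs = diversity@Hs,
                 Ht = diversity@Ht, Fst = diversity@Fst,
                 sd_Fst = diversity@sdFst),
      file.path(outputDir, "diversity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  hm <- haplotypeMatrix(aln, sites)
  net <- buildNetwork(hm, method = networkMethod)
  utils::write.table(hm, file.path(outputDir, "haplotype_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeNetwork(net, file.path(outputDir, "network.tsv"),
               dot = file.path(outputDir, "network.dot"))

  manifest <- list(
    package = "polykaryon",
    version = as.character(utils::packageVersion("polykaryon")),
    seed = seed,
    parameters = list(min_support = minSupport, alpha = alpha,
                      max_crossovers_recent = maxCrossoversRecent,
                      window = window, permutations = nPermutations,
                      estimator = estimator,
                      network_method = networkMethod),
    inputs = list(alignment = basename(alignmentFile),
                  regions = basename(regionsFile),
                  sample_sheet = basename(sampleSheetFile)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")

  invisible(list(sites = sites, spectrum = spectrum, calls = allCalls,
                 parentCounts = parentCounts, phi = phi,
                 diversity = diversity, network = net))
}

#' Summary checks for an accession-level clone alignment
#'
#' Runs the locus-level summaries used to sanity-check a deposited clone
#' data set: exon concatenation length, pairwise polymorphism counts within
#' chosen basidiomata, the PHI p-value over the full clone set, and
#' exon-haplotype Fst across localities. The alignment must be supplied by
#' the user (e.g. downloaded accessions, pre-aligned); the package ships no
#' sequence data.
#'
#' @param alignmentFile aligned FASTA of clone/haplotype sequences
#' @param regionsFile BED-style exon/intron file for the alignment
#' @param sampleSheetFile TSV sample sheet
#' @param seed RNG seed for the PHI permutation test and bootstrap
#' @return list with `exonLength`, `pairwisePolymorphisms` (per basidioma:
#'   polymorphic sites among its retained haplotypes), `phi`
#'   ([PhiResult-class]) and `diversity` ([DiversityResult-class])
#' @export
accessionChecks <- function(alignmentFile, regionsFile, sampleSheetFile,
                            seed = 1L) {
  aln <- readAlignment(alignmentFile)
  regions <- readRegions(regionsFile, Biostrings::width(aln)[1])
  sheet <- readSampleSheet(sampleSheetFile, aln)
  exAln <- partitionAlignment(aln, regions, "exon")
  perB <- list()
  for (b in unique(sheet$basidioma_id)) {
    group <- collapseClones(aln, sheet, b)
    calls <- filterSingletons(group)
    keep <- calls$haplotype[calls$status != "singleton_excluded"]
    perB[[b]] <- countPolymorphicColumns(group@sequences[keep])
  }
  phi <- phiTest(aln, seed = seed)
  pops <- sheet$locality[match(names(asAlignment(exAln)), sheet$seq_id)]
  diversity <- if (length(unique(pops)) >= 2L) {
    geneDiversityFst(as.character(exAln), pops, seed = seed)
  } else NULL
  list(exonLength = Biostrings::width(exAln)[1],
       pairwisePolymorphisms = unlist(perB),
       phi = phi, diversity = diversity)
}
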