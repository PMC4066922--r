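#' @import methods
#' @importClassesFrom IRanges IRanges
NULL

MUTATION_CLASSES <- c("A-G", "C-T", "A-C", "A-T", "C-G", "G-T", "indel")
REGION_LABELS <- c("exon", "intron")

#' RegionMap: labelled exon/intron intervals on alignment columns
#'
#' Partition of the columns of a multiple alignment into labelled intervals.
#' Coordinates are 1-based and inclusive, on alignment columns, so that
#' positions printed in reports match positions counted on the alignment
#' directly. Every column must be covered by exactly one interval.
#'
#' @slot ranges an [IRanges::IRanges] of non-overlapping, sorted intervals
#' @slot label character vector parallel to `ranges`; typically
#'   `"exon"`/`"intron"`
#' @slot alignmentLength integer, number of alignment columns covered
#' @aliases RegionMap-class
#' @exportClass RegionMap
setClass("RegionMap",
  representation(
    ranges = "IRanges",
    label = "character",
    alignmentLength = "integer"
  )
)

setValidity("RegionMap", function(object) {
  r <- object@ranges
  if (length(r) != length(object@label)) {
    return("ranges and label must have equal length")
  }
  if (length(r) == 0L) return("RegionMap must contain at least one interval")
  if (any(is.na(object@label)) || any(!nzchar(object@label))) {
    return("labels must be non-empty")
  }
  s <- IRanges::start(r); e <- IRanges::end(r)
  if (any(s > e)) return("interval with start > end")
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (any(s[-1] <= e[-length(e)])) return("intervals overlap")
  if (s[1] != 1L || e[length(e)] != object@alignmentLength ||
      any(s[-1] != e[-length(e)] + 1L)) {
    return("intervals must cover every column exactly once")
  }
  TRUE
})

#' PolymorphismSet: polymorphic sites and mutation events of an alignment
#'
#' One record per variable alignment column (or merged gap run), with the
#' mutation events (state pairs classified as transition, transversion or
#' indel) observed there. Columns containing `N` in any sequence are excluded
#' from calling and listed in `skippedColumns`.
#'
#' @slot sites data.frame with columns `position`, `region`, `type`
#'   (`"substitution"`/`"indel"`), `states` (comma-separated observed states),
#'   `nStates`, `length` (columns spanned; >1 only for merged gap runs)
#' @slot events data.frame with columns `position`, `region`, `from`, `to`,
#'   `class` (one of A-G, C-T, A-C, A-T, C-G, G-T, indel)
#' @slot alignmentLength integer
#' @slot skippedColumns integer vector of N-containing columns
#' @aliases PolymorphismSet-class
#' @exportClass PolymorphismSet
setClass("PolymorphismSet",
  representation(
    sites = "data.frame",
    events = "data.frame",
    alignmentLength = "integer",
    skippedColumns = "integer"
  )
)

setValidity("PolymorphismSet", function(object) {
  need <- c("position", "region", "type", "states", "nStates", "length")
  if (!all(need %in% names(object@sites))) {
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  }
  neede <- c("position", "region", "from", "to", "class")
  if (!all(neede %in% names(object@events))) {
    return(paste("events must have columns:", paste(neede, collapse = ", ")))
  }
  if (nrow(object@events) &&
      !all(object@events$class %in% MUTATION_CLASSES)) {
    return("unknown mutation class in events")
  }
  if (nrow(object@sites) && is.unsorted(object@sites$position)) {
    return("sites must be sorted by position")
  }
  TRUE
})

#' SpectrumTable: mutation counts by class and region
#'
#' Counts of mutation events cross-classified by mutation class (the four
#' transversion pairs, the two transition pairs, and indels) and region
#' (exon/intron). Derived rows (total transitions, transversions, mutations)
#' and percentages are always recomputed from the counts, never stored.
#'
#' @slot counts integer matrix, rows = mutation classes, cols = regions
#' @slot regionLengths named numeric, nt per region
#' @aliases SpectrumTable-class
#' @exportClass SpectrumTable
setClass("SpectrumTable",
  representation(
    counts = "matrix",
    regionLengths = "numeric"
  )
)

setValidity("SpectrumTable", function(object) {
  if (!identical(rownames(object@counts), MUTATION_CLASSES)) {
    return("counts rows must be the seven mutation classes")
  }
  if (is.null(colnames(object@counts))) return("counts must name its regions")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(sort(names(object@regionLengths)),
                 sort(colnames(object@counts)))) {
    return("regionLengths must name the same regions as counts")
  }
  TRUE
})

#' CloneGroup: collapsed clone haplotypes of one basidioma
#'
#' Exact-match collapsed clone sequences for a single fruit body, ordered by
#' descending clone support (ties broken by haplotype id).
#'
#' @slot basidioma character scalar id
#' @slot sequences named character vector of distinct haplotype sequences;
#'   names are haplotype ids
#' @slot support integer vector of clone counts, parallel to `sequences`
#' @slot members list of character vectors of member clone sequence ids
#' @slot totalClones integer, sum of supports
#' @aliases CloneGroup-class
#' @exportClass CloneGroup
setClass("CloneGroup",
  representation(
    basidioma = "character",
    sequences = "character",
    support = "integer",
    members = "list",
    totalClones = "integer"
  )
)

setValidity("CloneGroup", function(object) {
  n <- length(object@sequences)
  if (length(object@support) != n || length(object@members) != n) {
    return("sequences, support and members must be parallel")
  }
  if (n == 0L) return("CloneGroup must contain at least one haplotype")
  if (any(object@support < 1L)) return("supports must be >= 1")
  if (sum(object@support) != object@totalClones) {
    return("supports must sum to totalClones")
  }
  if (anyDuplicated(object@sequences)) {
    return("haplotype sequences must be pairwise distinct")
  }
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids)) return("haplotype ids must be unique")
  o <- order(-object@support, ids)
  if (!identical(o, seq_len(n))) {
    return("haplotypes must be sorted by descending support, ties by id")
  }
  TRUE
})

#' ErrorModel: birthday-paradox model for recurrent cloning/PCR errors
#'
#' Parameters of the shared-error probability model: the probability that the
#' same specific mutation arises independently, by PCR/cloning error, in `k`
#' or more of the `n` clones sequenced from one basidioma, when mutations fall
#' at random over `L` polymorphic regions with transition:transversion:
#' transversion weights 2:1:1.
#'
#' @slot nClones integer, clones sequenced for the basidioma
#' @slot nRegions integer, number of polymorphic regions L
#' @slot variant `"tuple"` (default closed form, see
#'   [sharedErrorProbability()]) or `"binomial"` (binomial tail)
#' @aliases ErrorModel-class
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(
    nClones = "integer",
    nRegions = "integer",
    variant = "character"
  )
)

setValidity("ErrorModel", function(object) {
  if (object@nClones < 1L) return("nClones must be >= 1")
  if (object@nRegions < 1L) return("nRegions (L) must be >= 1")
  if (!object@variant %in% c("tuple", "binomial")) {
    return("variant must be 'tuple' or 'binomial'")
  }
  TRUE
})

#' CrossoverResult: minimal template-switch explanation of one clone
#'
#' Result of explaining a clone sequence as a recombinant of candidate
#' parental haplotypes with the fewest template switches (crossovers).
#'
#' @slot childId character id of the explained sequence
#' @slot parentIds character ids of the candidate parents
#' @slot informativeSites integer positions where the parents differ
#' @slot path character parent label per informative site (`NA` at
#'   unexplained sites)
#' @slot kSwitches integer minimal number of template switches
#' @slot breakpoints two-column integer matrix; each row is the open interval
#'   (position after, position before) between sites assigned to different
#'   parents
#' @slot unexplained integer positions where the child matches no parent
#' @aliases CrossoverResult-class
#' @exportClass CrossoverResult
setClass("CrossoverResult",
  representation(
    childId = "character",
    parentIds = "character",
    informativeSites = "integer",
    path = "character",
    kSwitches = "integer",
    breakpoints = "matrix",
    unexplained = "integer"
  )
)

setValidity("CrossoverResult", function(object) {
  if (length(object@path) != length(object@informativeSites)) {
    return("path must be parallel to informativeSites")
  }
  lab <- object@path[!is.na(object@path)]
  if (length(lab) && !all(lab %in% object@parentIds)) {
    return("path labels must be parent ids")
  }
  k <- if (length(lab) < 2L) 0L else sum(lab[-1] != lab[-length(lab)])
  if (k != object@kSwitches) {
    return("kSwitches must equal the number of adjacent label changes")
  }
  if (nrow(object@breakpoints) != object@kSwitches) {
    return("one breakpoint interval per switch")
  }
  TRUE
})

#' PhiResult: pairwise homoplasy index test result
#'
#' @slot statistic numeric, mean refined incompatibility over nearby
#'   informative-site pairs
#' @slot pValue numeric in `[0,1]`, `NA` when not computable
#' @slot windowSize integer, window in informative sites
#' @slot nInformative integer, parsimony-informative sites used
#' @slot nPermutations integer
#' @slot computable logical
#' @slot method `"permutation"` or `"normal"`
#' @aliases PhiResult-class
#' @exportClass PhiResult
setClass("PhiResult",
  representation(
    statistic = "numeric",
    pValue = "numeric",
    windowSize = "integer",
    nInformative = "integer",
    nPermutations = "integer",
    computable = "logical",
    method = "character"
  )
)

setValidity("PhiResult", function(object) {
  if (object@computable) {
    if (is.na(object@pValue) || object@pValue < 0 || object@pValue > 1) {
      return("pValue must lie in [0,1]")
    }
    if (object@statistic < 0) return("statistic must be >= 0")
  }
  TRUE
})

#' DiversityResult: haploid gene diversity and Fst across populations
#'
#' @slot counts table of haplotype x population counts
#' @slot Hs numeric, mean within-population gene diversity
#' @slot Ht numeric, total gene diversity
#' @slot Fst numeric fixation index (may be negative for unbiased estimators)
#' @slot sdFst numeric spread of Fst (jackknife/bootstrap), `NA` if
#'   unavailable
#' @slot estimator `"wc_theta"` or `"nei_gst"`
#' @slot spreadMethod character, how `sdFst` was obtained
#' @aliases DiversityResult-class
#' @exportClass DiversityResult
setClass("DiversityResult",
  representation(
    counts = "table",
    Hs = "numeric",
    Ht = "numeric",
    Fst = "numeric",
    sdFst = "numeric",
    estimator = "character",
    spreadMethod = "character"
  )
)

setValidity("DiversityResult", function(object) {
  if (!is.na(object@Hs) && (object@Hs < 0 || object@Hs > 1)) {
    return("Hs must lie in [0,1]")
  }
  if (!is.na(object@Ht) && (object@Ht < 0 || object@Ht > 1)) {
    return("Ht must lie in [0,1]")
  }
  if (!object@estimator %in% c("wc_theta", "nei_gst")) {
    return("estimator must be 'wc_theta' or 'nei_gst'")
  }
  TRUE
})

#' HaplotypeNetwork: minimum-spanning / median-joining haplotype graph
#'
#' @slot nodes data.frame with columns `id`, `members` (comma-separated
#'   haplotype ids; empty for inferred median nodes), `median` (logical)
#' @slot edges data.frame with columns `from`, `to`, `weight` (mutation
#'   distance) and `sites` (comma-separated differing site positions)
#' @slot states character matrix of node states (rows = nodes, cols = sites)
#' @slot method `"msn"` or `"median_joining"`
#' @aliases HaplotypeNetwork-class
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    states = "matrix",
    method = "character"
  )
)

setValidity("HaplotypeNetwork", function(object) {
  if (nrow(object@nodes) == 0L) return("network must have at least one node")
  if (nrow(object@edges)) {
    ok <- object@edges$from %in% object@nodes$id &
      object@edges$to %in% object@nodes$id
    if (!all(ok)) return("edge endpoints must be node ids")
  }
  TRUE
})
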