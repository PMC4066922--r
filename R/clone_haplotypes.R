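#' Collapse the clone sequences of one basidioma into haplotypes
#'
#' Groups the aligned clone sequences of a single fruit body by exact string
#' identity. Each sample-sheet record contributes its `clone_count` to the
#' support of its haplotype, so a record standing for seven identical
#' sequenced clones adds 7. Haplotypes are ordered by descending support,
#' ties broken by haplotype id (the id of the first member record).
#'
#' @param aln `DNAStringSet` alignment of clone sequences
#' @param sheet sample sheet data.frame (see [readSampleSheet()])
#' @param basidioma basidioma id to collapse
#' @return a [CloneGroup-class]
#' @export
collapseClones <- function(aln, sheet, basidioma) {
  aln <- asAlignment(aln)
  validateSampleSheet(sheet, aln)
  rows <- sheet[sheet$basidioma_id == basidioma, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown basidioma_id: ", basidioma)
  seqs <- as.character(aln)[rows$seq_id]
  groups <- split(seq_len(nrow(rows)), factor(seqs, levels = unique(seqs)))
  hapSeq <- names(groups)
  support <- vapply(groups, function(i) sum(rows$clone_count[i]), integer(1))
  hapId <- vapply(groups, function(i) rows$seq_id[i[1]], character(1))
  members <- lapply(groups, function(i) rows$seq_id[i])
  o <- order(-support, hapId)
  hapSeq <- hapSeq[o]; support <- support[o]
  hapId <- hapId[o]; members <- members[o]
  names(hapSeq) <- hapId
  names(members) <- hapId
  new("CloneGroup", basidioma = basidioma, sequences = hapSeq,
      support = as.integer(support), members = members,
      totalClones = sum(as.integer(support)))
}

#' Status of each haplotype after singleton exclusion
#'
#' Haplotypes supported by fewer than `minSupport` clones are excluded as
#' possible cloning/PCR artefacts (the singleton-exclusion rule; default
#' threshold 2). Among the retained haplotypes, the two best supported are
#' labelled `dominant` (the two expected parental alleles of a dikaryon);
#' any further retained haplotype is `minor_supported`. A support tie for
#' the second dominant slot is broken by haplotype id, with a message.
#'
#' @param group a [CloneGroup-class]
#' @param minSupport minimum clone support to retain a haplotype (default 2)
#' @return data.frame with columns `basidioma`, `haplotype`, `support`,
#'   `status` (`dominant` / `minor_supported` / `singleton_excluded`)
#' @export
filterSingletons <- function(group, minSupport = 2L) {
  stopifnot(is(group, "CloneGroup"), minSupport >= 1L)
  ids <- names(group@sequences)
  status <- rep("singleton_excluded", length(ids))
  retained <- which(group@support >= minSupport)
  if (length(retained) > 2L &&
      group@support[retained[2]] == group@support[retained[3]]) {
    message("support tie for the second dominant haplotype in ",
            group@basidioma, "; broken by id")
  }
  status[retained] <- "minor_supported"
  status[retained[seq_len(min(2L, length(retained)))]] <- "dominant"
  data.frame(basidioma = group@basidioma, haplotype = ids,
             support = group@support, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Birthday-paradox error model
#'
#' @param nClones total clones sequenced for the basidioma
#' @param nRegions number of polymorphic regions L over which random
#'   mutations scatter
#' @param variant `"tuple"` (default) or `"binomial"`; see
#'   [sharedErrorProbability()]
#' @return an [ErrorModel-class]
#' @export
errorModel <- function(nClones, nRegions, variant = c("tuple", "binomial")) {
  variant <- match.arg(variant)
  new("ErrorModel", nClones = as.integer(nClones),
      nRegions = as.integer(nRegions), variant = variant)
}

#' Probability that the same mutation recurs in k clones by chance
#'
#' Model: each of the `n` clones sequenced from a basidioma may acquire a
#' random PCR/cloning mutation, falling uniformly over the `L` polymorphic
#' regions; at a region, the single transition change carries weight 2
#' against weight 1 for each of the two transversion changes. The per-clone
#' probability of reproducing one specific transition is therefore
#' `q = 1/(2L)`.
#'
#' The default `"tuple"` closed form approximates the chance that `k` or
#' more clones share the specific mutation by the expected number of
#' coincident k-tuples, `C(n,k) q^k`, and applies the class asymmetry once:
#' a transversion is reported at exactly half the transition probability
#' (matching the conventional halving rule for these probabilities). The
#' `"binomial"` variant returns the exact binomial tail
#' `P(X >= k), X ~ Bin(n, q_class)` with `q_class` = `1/(2L)` for a
#' transition, `1/(4L)` for a transversion. Probabilities for several
#' independent mutations multiply. `k = 1` requires no coincidence and
#' returns 1; `k > n` returns 0. Results are capped at 1.
#'
#' @param model an [ErrorModel-class]
#' @param k number of clones carrying the mutation
#' @param class `"transition"`, `"transversion"` or `"indel"` (indels are
#'   treated at transversion weight)
#' @return probability in `[0, 1]`
#' @export
#' @examples
#' m <- errorModel(nClones = 16, nRegions = 16)
#' sharedErrorProbability(m, k = 2, "transition")
#' sharedErrorProbability(m, k = 3, "transition")
#' sharedErrorProbability(m, k = 2, "transversion")
sharedErrorProbability <- function(model, k,
                                   class = c("transition", "transversion",
                                             "indel")) {
  class <- match.arg(class)
  stopifnot(is(model, "ErrorModel"), k >= 1L)
  n <- model@nClones
  L <- model@nRegions
  if (k > n) return(0)
  if (k == 1L) return(1)
  qTs <- 1 / (2 * L)
  if (model@variant == "tuple") {
    p <- choose(n, k) * qTs^k
    if (class != "transition") p <- p / 2
  } else {
    q <- if (class == "transition") qTs else qTs / 2
    p <- stats::pbinom(k - 1L, n, q, lower.tail = FALSE)
  }
  min(p, 1)
}

#' Annotate retained haplotypes with unique polymorphisms and shared-error p
#'
#' For every non-dominant retained haplotype, counts the sites at which it
#' differs from *all* dominant haplotypes (its unique polymorphisms), and
#' computes the joint probability that those mutations recur `support` times
#' by chance, as the product of per-mutation [sharedErrorProbability()]
#' values. Dominant haplotypes get `NA` in these columns.
#'
#' @param group a [CloneGroup-class]
#' @param calls data.frame from [filterSingletons()]
#' @param model an [ErrorModel-class]; by default `errorModel(totalClones,
#'   L)` with `L` = number of polymorphic sites among the retained
#'   haplotypes
#' @param sites optional [PolymorphismSet-class] called on the full clone
#'   alignment; used only to classify unique-site mutations, recomputed from
#'   the group when absent
#' @return `calls` with added columns `unique_polymorphisms`,
#'   `shared_error_p`
#' @export
annotateHaplotypeCalls <- function(group, calls, model = NULL, sites = NULL) {
  stopifnot(is(group, "CloneGroup"))
  dom <- calls$haplotype[calls$status == "dominant"]
  minor <- calls$haplotype[calls$status == "minor_supported"]
  calls$unique_polymorphisms <- NA_integer_
  calls$shared_error_p <- NA_real_
  if (!length(dom)) return(calls)
  seqs <- group@sequences
  retained <- calls$haplotype[calls$status != "singleton_excluded"]
  if (is.null(model)) {
    L <- max(1L, countPolymorphicColumns(seqs[retained]))
    model <- errorModel(group@totalClones, L)
  }
  for (h in minor) {
    d <- uniqueDifferences(seqs[[h]], lapply(dom, function(i) seqs[[i]]))
    calls$unique_polymorphisms[calls$haplotype == h] <- length(d$positions)
    k <- calls$support[calls$haplotype == h]
    p <- 1
    for (cls in d$classes) p <- p * sharedErrorProbability(model, k, cls)
    calls$shared_error_p[calls$haplotype == h] <-
      if (length(d$classes)) p else NA_real_
  }
  calls
}

# polymorphic columns among a set of equal-length sequences (gap runs merged)
countPolymorphicColumns <- function(seqs) {
  if (length(seqs) < 2L) return(0L)
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  varying <- which(apply(m, 2, function(v) length(unique(v[v != "N"])) > 1L))
  if (!length(varying)) return(0L)
  # merge adjacent varying gap columns with identical pattern into one region
  nRegions <- 0L
  prev <- -10L; prevPat <- ""
  for (j in varying) {
    pat <- paste(m[, j], collapse = "")
    gappy <- any(m[, j] == "-")
    if (gappy && j == prev + 1L && pat == prevPat) {
      prev <- j
      next
    }
    nRegions <- nRegions + 1L
    prev <- j; prevPat <- pat
  }
  nRegions
}

# positions & classes where child differs from every dominant sequence
uniqueDifferences <- function(child, dominants) {
  cs <- strsplit(child, "", fixed = TRUE)[[1]]
  dm <- do.call(rbind, strsplit(unlist(dominants), "", fixed = TRUE))
  diffAll <- vapply(seq_along(cs), function(j) {
    cs[j] != "N" && all(dm[, j] != cs[j] & dm[, j] != "N")
  }, logical(1))
  pos <- which(diffAll)
  # merge adjacent gap positions into single indel events
  positions <- integer(0); classes <- character(0)
  i <- 1L
  while (i <= length(pos)) {
    j <- pos[i]
    if (cs[j] == "-" || all(dm[, j] == "-")) {
      run <- j
      while (i + 1L <= length(pos) && pos[i + 1L] == run + 1L &&
             (cs[pos[i + 1L]] == "-" || all(dm[, pos[i + 1L]] == "-"))) {
        i <- i + 1L; run <- pos[i]
      }
      positions <- c(positions, j)
      classes <- c(classes, "indel")
    } else {
      positions <- c(positions, j)
      cls <- classifyMutation(cs[j], dm[1, j])
      classes <- c(classes, cls)
    }
    i <- i + 1L
  }
  list(positions = positions, classes = classes)
}

#' Call the number of parental haplotypes of a basidioma
#'
#' The null expectation for a dikaryotic fruit body is two parental
#' haplotypes. A `minor_supported` haplotype counts as an additional parent
#' iff (a) the joint probability that its unique polymorphisms recur
#' `support` times by chance is below `alpha`, and (b) it is *not*
#' explainable as a recombinant of the dominant pair using at most
#' `maxCrossoversRecent` template switches with zero unexplained sites. With
#' a single retained haplotype the call is 1 parent with a caveat (the
#' second parent may be undetected or the basidioma homozygous); with no
#' retained haplotype the call is `uncallable`.
#'
#' @param group a [CloneGroup-class]
#' @param calls annotated calls from [annotateHaplotypeCalls()]
#' @param crossoverResults named list of [CrossoverResult-class], one per
#'   minor haplotype, child vs the dominant pair (see [minCrossovers()])
#' @param alpha significance threshold on the shared-error probability
#'   (default 0.05)
#' @param maxCrossoversRecent maximum switches attributable to recent (PCR
#'   or meiotic) recombination (default 2)
#' @return a list with elements `basidioma`, `nParents` (`NA` when
#'   uncallable), `status` (`called`/`uncallable`), and `evidence`
#'   (per-haplotype data.frame with the rationale)
#' @export
callParentCount <- function(group, calls, crossoverResults = list(),
                            alpha = 0.05, maxCrossoversRecent = 2L) {
  stopifnot(is(group, "CloneGroup"))
  retained <- calls[calls$status != "singleton_excluded", , drop = FALSE]
  if (nrow(retained) == 0L) {
    return(list(basidioma = group@basidioma, nParents = NA_integer_,
                status = "uncallable",
                evidence = data.frame(haplotype = character(0),
                                      verdict = character(0))))
  }
  dom <- retained$haplotype[retained$status == "dominant"]
  minors <- retained$haplotype[retained$status == "minor_supported"]
  ev <- data.frame(haplotype = retained$haplotype,
                   support = retained$support,
                   status = retained$status,
                   unique_polymorphisms = retained$unique_polymorphisms,
                   shared_error_p = retained$shared_error_p,
                   crossover_k = NA_integer_,
                   crossover_unexplained = NA_integer_,
                   verdict = "", stringsAsFactors = FALSE)
  ev$verdict[ev$status == "dominant"] <- "parent (dominant)"
  nParents <- length(dom)
  caveat <- NULL
  if (length(dom) == 1L) {
    caveat <- paste("single haplotype: second parent undetected or",
                    "basidioma homozygous at this locus")
  }
  for (h in minors) {
    i <- which(ev$haplotype == h)
    xr <- crossoverResults[[h]]
    if (length(dom) >= 2L && is.null(xr)) {
      stop("crossover result missing for minor haplotype ", h)
    }
    p <- ev$shared_error_p[i]
    pOK <- !is.na(p) && p < alpha
    recombinant <- FALSE
    if (!is.null(xr)) {
      stopifnot(is(xr, "CrossoverResult"))
      ev$crossover_k[i] <- xr@kSwitches
      ev$crossover_unexplained[i] <- length(xr@unexplained)
      recombinant <- xr@kSwitches <= maxCrossoversRecent &&
        length(xr@unexplained) == 0L
    }
    if (pOK && !recombinant) {
      nParents <- nParents + 1L
      ev$verdict[i] <- "parent (distinct minor haplotype)"
    } else if (recombinant) {
      ev$verdict[i] <- "explainable as recent recombinant of dominants"
    } else {
      ev$verdict[i] <- "unique polymorphisms attributable to cloning error"
    }
  }
  list(basidioma = group@basidioma, nParents = as.integer(nParents),
       status = "called", caveat = caveat, evidence = ev)
}

#' @describeIn CloneGroup-class compact display
#' @param object a `CloneGroup`
#' @export
setMethod("show", "CloneGroup", function(object) {
  cat("CloneGroup", object@basidioma, "-", length(object@sequences),
      "haplotype(s) from", object@totalClones, "clones\n")
  for (i in seq_along(object@sequences)) {
    cat(sprintf("  %s (%d)\n", names(object@sequences)[i],
                object@support[i]))
  }
})
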