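#' Classify a mutation as transition, transversion or indel
#'
#' Applies the purine-pyrimidine rule: A<->G and C<->T are transitions, the
#' remaining base pairs transversions; any state involving a gap is an indel.
#' Symmetric in its arguments. States may be single bases or gap/base runs
#' (e.g. `"-"`, `"--"`, `"AG"`), as produced by merged-indel calling.
#'
#' @param stateA,stateB distinct allele states
#' @return `"transition"`, `"transversion"` or `"indel"`
#' @export
#' @examples
#' classifyMutation("T", "C")   # transition
#' classifyMutation("A", "-")   # indel
#' classifyMutation("C", "G")   # transversion
classifyMutation <- function(stateA, stateB) {
  stopifnot(is.character(stateA), is.character(stateB),
            length(stateA) == 1L, length(stateB) == 1L)
  if (identical(stateA, stateB)) stop("states must be distinct")
  if (grepl("-", stateA, fixed = TRUE) || grepl("-", stateB, fixed = TRUE)) {
    return("indel")
  }
  if (nchar(stateA) != 1L || nchar(stateB) != 1L) {
    # multi-base states without gaps arise only from merged runs; classify by
    # per-position vote is not defined, treat as indel-free substitution block
    stop("non-gap states must be single bases")
  }
  purine <- c("A", "G")
  both <- c(stateA, stateB)
  if (!all(both %in% c("A", "C", "G", "T"))) {
    stop("states must be bases or gap runs, got: ", stateA, ", ", stateB)
  }
  if (sum(both %in% purine) %in% c(0L, 2L)) "transition" else "transversion"
}

# class label of a substitution pair, e.g. ("T","C") -> "C-T"
mutationClassName <- function(stateA, stateB) {
  cls <- classifyMutation(stateA, stateB)
  if (cls == "indel") return("indel")
  paste(sort(c(stateA, stateB)), collapse = "-")
}

#' Find polymorphic sites of an alignment
#'
#' Scans alignment columns for variation among sequences. Columns containing
#' `N` in any sequence are excluded from calling. Maximal runs of consecutive
#' gap-containing columns whose gap pattern across sequences is identical are
#' merged into a single indel event of length = run length, so a 4-bp
#' deletion counts as one indel, not four. Base variation among the non-gap
#' sequences is called per column as usual. At multi-allelic columns,
#' `nStates - 1` events are formed by pairing each minor state with the
#' majority state (ties broken alphabetically); `pairing = "all_pairs"`
#' counts every unordered state pair instead.
#'
#' @param aln `DNAStringSet` alignment (or named character vector)
#' @param regions [RegionMap-class] covering the alignment
#' @param pairing `"minor_major"` (default) or `"all_pairs"`
#' @return a [PolymorphismSet-class]
#' @export
findPolymorphicSites <- function(aln, regions,
                                 pairing = c("minor_major", "all_pairs")) {
  pairing <- match.arg(pairing)
  aln <- asAlignment(aln)
  if (length(aln) == 0L) stop("empty alignment")
  stopifnot(is(regions, "RegionMap"))
  m <- alignmentMatrix(aln)
  if (ncol(m) != regions@alignmentLength) {
    stop("alignment and regions disagree on length")
  }
  labels <- columnLabels(regions)
  hasN <- which(apply(m == "N", 2, any))
  usable <- setdiff(seq_len(ncol(m)), hasN)

  sites <- list()
  events <- list()

  addSite <- function(position, region, type, states, len) {
    sites[[length(sites) + 1L]] <<- data.frame(
      position = position, region = region, type = type,
      states = paste(states, collapse = ","),
      nStates = length(states), length = len,
      stringsAsFactors = FALSE)
  }
  addEvent <- function(position, region, from, to) {
    events[[length(events) + 1L]] <<- data.frame(
      position = position, region = region, from = from, to = to,
      class = mutationClassName(from, to), stringsAsFactors = FALSE)
  }

  # ---- merged indel runs -------------------------------------------------
  gapPat <- apply(m == "-", 2, function(g) paste(as.integer(g), collapse = ""))
  isGapCol <- apply(m == "-", 2, any)
  runStart <- NULL; runCols <- integer(0)
  flushRun <- function() {
    if (!length(runCols)) return(invisible())
    pos <- runCols[1]
    gapRows <- m[, pos] == "-"
    nonGap <- m[!gapRows, runCols, drop = FALSE]
    # majority non-gap state over the run (row-wise strings)
    rows <- apply(nonGap, 1, paste, collapse = "")
    major <- majorityState(rows)
    addSite(pos, labels[pos], "indel",
            sort(unique(c(rows, strrep("-", length(runCols))))),
            length(runCols))
    addEvent(pos, labels[pos], major, strrep("-", length(runCols)))
    runStart <<- NULL; runCols <<- integer(0)
  }
  for (j in usable) {
    if (isGapCol[j]) {
      if (length(runCols) &&
          j == runCols[length(runCols)] + 1L &&
          gapPat[j] == gapPat[runCols[1]]) {
        runCols <- c(runCols, j)
      } else {
        flushRun()
        runCols <- j
      }
    } else {
      flushRun()
    }
    # substitution calling among non-gap rows of this column
    v <- m[, j]
    v <- v[v != "-"]
    states <- sort(unique(v))
    if (length(states) >= 2L) {
      addSite(j, labels[j], "substitution", states, 1L)
      major <- majorityState(v)
      if (pairing == "minor_major") {
        for (s in setdiff(states, major)) addEvent(j, labels[j], major, s)
      } else {
        cmb <- utils::combn(states, 2)
        for (k in seq_len(ncol(cmb))) {
          addEvent(j, labels[j], cmb[1, k], cmb[2, k])
        }
      }
    }
  }
  flushRun()

  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(position = integer(0), region = character(0),
               type = character(0), states = character(0),
               nStates = integer(0), length = integer(0))
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(position = integer(0), region = character(0),
               from = character(0), to = character(0), class = character(0))
  o <- order(sites$position, sites$type)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  events <- events[order(events$position, events$class), , drop = FALSE]
  rownames(events) <- NULL
  new("PolymorphismSet", sites = sites, events = events,
      alignmentLength = ncol(m), skippedColumns = as.integer(hasN))
}

# most frequent state; ties broken alphabetically
majorityState <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  names(tab)[tab == tab[1]][order(names(tab)[tab == tab[1]])][1]
}

#' Aggregate polymorphic sites into a mutation spectrum table
#'
#' Cross-classifies the mutation events of a [PolymorphismSet-class] by
#' mutation class (A-G, C-T, A-C, A-T, C-G, G-T, indel) and region, with the
#' region lengths needed for frequency computation. Derived totals and
#' percentages are recomputed on demand (see [spectrumSummary()]).
#'
#' @param sites a `PolymorphismSet` (from [findPolymorphicSites()])
#' @param regions the same [RegionMap-class] the sites were called with
#' @return a [SpectrumTable-class]
#' @export
spectrumTable <- function(sites, regions) {
  stopifnot(is(sites, "PolymorphismSet"), is(regions, "RegionMap"))
  regs <- sort(unique(regions@label))
  ev <- sites@events
  if (nrow(ev) && !all(ev$region %in% regs)) {
    stop("event region label absent from regions: ",
         paste(setdiff(unique(ev$region), regs), collapse = ", "))
  }
  counts <- matrix(0L, nrow = length(MUTATION_CLASSES), ncol = length(regs),
                   dimnames = list(MUTATION_CLASSES, regs))
  if (nrow(ev)) {
    tab <- table(factor(ev$class, levels = MUTATION_CLASSES),
                 factor(ev$region, levels = regs))
    counts[] <- as.integer(tab)
  }
  rl <- regionLengths(regions)
  new("SpectrumTable", counts = counts, regionLengths = rl[regs])
}

#' Build a SpectrumTable directly from per-class counts
#'
#' Convenience constructor for working with published count tables rather
#' than alignments.
#'
#' @param counts matrix or data.frame with rows named by mutation class
#'   (A-G, C-T, A-C, A-T, C-G, G-T, indel) and columns named by region
#' @param regionLengths named numeric vector of region lengths (nt)
#' @return a [SpectrumTable-class]
#' @export
#' @examples
#' cnt <- cbind(exon = c(5, 22, 2, 1, 2, 0, 0),
#'              intron = c(7, 44, 9, 12, 6, 7, 12))
#' rownames(cnt) <- c("A-G", "C-T", "A-C", "A-T", "C-G", "G-T", "indel")
#' st <- spectrumFromCounts(cnt, c(exon = 586, intron = 207))
#' spectrumSummary(st)
spectrumFromCounts <- function(counts, regionLengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must name its rows by class")
  counts <- counts[MUTATION_CLASSES, , drop = FALSE]
  storage.mode(counts) <- "integer"
  new("SpectrumTable", counts = counts,
      regionLengths = regionLengths[colnames(counts)])
}

#' Derived totals and percentages of a SpectrumTable
#'
#' Recomputes, per region and overall: total transitions (A-G + C-T), total
#' transversions (A-C + A-T + C-G + G-T), indels, total mutations, and the
#' percentage each class contributes to the region's total mutations
#' (integer percent, rounded half away from zero, the convention of printed
#' mutation-spectrum tables).
#'
#' @param x a [SpectrumTable-class]
#' @return a data.frame with one row per derived quantity and one column per
#'   region plus `total`
#' @export
spectrumSummary <- function(x) {
  stopifnot(is(x, "SpectrumTable"))
  cnt <- x@counts
  cnt <- cbind(cnt, total = rowSums(cnt))
  ts <- colSums(cnt[c("A-G", "C-T"), , drop = FALSE])
  tv <- colSums(cnt[c("A-C", "A-T", "C-G", "G-T"), , drop = FALSE])
  ind <- cnt["indel", ]
  tot <- ts + tv + ind
  out <- rbind(cnt[c("A-G", "C-T"), , drop = FALSE],
               transitions = ts,
               cnt[c("A-C", "A-T", "C-G", "G-T"), , drop = FALSE],
               transversions = tv,
               indels = ind,
               total = tot)
  pct <- sweep(out, 2, tot, function(a, b) ifelse(b > 0, 100 * a / b, 0))
  data.frame(mutation = rownames(out), out,
             percent = roundHalfUp(pct[, ncol(pct)], 0),
             check.names = FALSE, row.names = NULL)
}

# round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# truncate toward zero at a number of decimals (printed-frequency convention)
truncDigits <- function(x, digits = 1) {
  p <- 10^digits
  trunc(x * p) / p
}

#' Per-region totals of a SpectrumTable
#' @param x a [SpectrumTable-class]
#' @return named numeric: total mutation events per region
#' @export
totalMutations <- function(x) {
  stopifnot(is(x, "SpectrumTable"))
  colSums(x@counts)
}

#' Polymorphism frequency of a region
#'
#' 100 x total mutation events in the region / region length (nt). The exact
#' percentage is returned; printed frequencies of this kind are conventionally
#' reported at 1 decimal place with truncation toward zero (see `digits` and
#' `style`).
#'
#' @param x a [SpectrumTable-class]
#' @param region region label
#' @param digits if non-NULL, round/truncate to this many decimals
#' @param style `"exact"` (default), `"truncate"` or `"round"` (half away
#'   from zero); ignored when `digits` is NULL
#' @return percent
#' @export
polymorphismFrequency <- function(x, region, digits = NULL,
                                  style = c("exact", "truncate", "round")) {
  style <- match.arg(style)
  stopifnot(is(x, "SpectrumTable"))
  if (!region %in% colnames(x@counts)) stop("unknown region: ", region)
  len <- x@regionLengths[[region]]
  if (is.na(len) || len <= 0) stop("region length must be > 0")
  f <- 100 * sum(x@counts[, region]) / len
  if (!is.null(digits) && style != "exact") {
    f <- switch(style,
                truncate = truncDigits(f, digits),
                round = roundHalfUp(f, digits))
  }
  f
}

#' Haplotype matrix over polymorphic sites
#'
#' Table of each sequence's state at every polymorphic site, with sequences
#' carrying identical state patterns grouped together (the shape of a
#' published per-isolate polymorphism table). States at merged indel sites
#' are the full run (`"-"` repeated run-length times for the deleted allele).
#'
#' @param aln the alignment the sites were called from
#' @param sites a [PolymorphismSet-class]
#' @return a data.frame: one row per distinct pattern, columns `haplotype`
#'   (pattern id), one column per site position, and `members`
#'   (comma-separated sequence ids); attribute `"perSequence"` carries the
#'   ungrouped per-sequence state matrix
#' @export
haplotypeMatrix <- function(aln, sites) {
  aln <- asAlignment(aln)
  stopifnot(is(sites, "PolymorphismSet"))
  m <- alignmentMatrix(aln)
  if (ncol(m) != sites@alignmentLength) {
    stop("sites were not called from this alignment (length mismatch)")
  }
  st <- sites@sites
  if (nrow(st) == 0L) {
    states <- matrix(character(0), nrow = nrow(m), ncol = 0,
                     dimnames = list(rownames(m), NULL))
  } else {
    states <- matrix("", nrow = nrow(m), ncol = nrow(st),
                     dimnames = list(rownames(m), as.character(st$position)))
    for (i in seq_len(nrow(st))) {
      cols <- seq.int(st$position[i], length.out = st$length[i])
      states[, i] <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    }
  }
  key <- apply(states, 1, paste, collapse = "|")
  groups <- split(rownames(m), factor(key, levels = unique(key)))
  pat <- states[!duplicated(key), , drop = FALSE]
  out <- data.frame(haplotype = paste0("H", seq_along(groups)),
                    pat, check.names = FALSE, row.names = NULL)
  out$members <- vapply(groups, paste, character(1), collapse = ",")
  attr(out, "perSequence") <- states
  out
}

#' Write a PolymorphismSet site/event listing as TSV
#' @param sites a [PolymorphismSet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePolymorphicSites <- function(sites, path) {
  stopifnot(is(sites, "PolymorphismSet"))
  st <- sites@sites
  evstr <- vapply(st$position, function(p) {
    rows <- sites@events[sites@events$position == p, , drop = FALSE]
    paste(paste0(rows$from, ">", rows$to, ":", rows$class), collapse = ";")
  }, character(1))
  utils::write.table(
    data.frame(position = st$position, region = st$region,
               alleles = st$states, events = evstr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn SpectrumTable-class display shaped like a published
#'   mutation-spectrum table
#' @param object a `SpectrumTable`
#' @export
setMethod("show", "SpectrumTable", function(object) {
  cat("SpectrumTable (", paste(colnames(object@counts), collapse = " / "),
      ")\n", sep = "")
  s <- spectrumSummary(object)
  print(s, row.names = FALSE)
  len <- object@regionLengths
  cat("Length (nt):", paste(sprintf("%s=%g", names(len), len),
                            collapse = "  "), "\n")
})

#' @describeIn PolymorphismSet-class compact display
#' @param object a `PolymorphismSet`
#' @export
setMethod("show", "PolymorphismSet", function(object) {
  cat("PolymorphismSet:", nrow(object@sites), "site(s),",
      nrow(object@events), "event(s) on", object@alignmentLength,
      "columns\n")
  if (length(object@skippedColumns)) {
    cat("  ", length(object@skippedColumns),
        "column(s) skipped (contain N)\n")
  }
  if (nrow(object@sites)) {
    print(utils::head(object@sites, 10), row.names = FALSE)
    if (nrow(object@sites) > 10) cat("  ...\n")
  }
})
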