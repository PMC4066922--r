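#' Haploid gene diversity and Fst across populations
#'
#' Individuals are haploid units: each retained haplotype of a basidioma
#' contributes once, unweighted by clone support. When `haplotypes` are
#' sequences (equal length > 1), every polymorphic site is treated as a
#' locus and the estimator is the multilocus ratio-of-sums, with spread by
#' jackknife over polymorphic sites. When `haplotypes` are plain labels, a
#' single multiallelic locus is assumed and spread comes from a bootstrap
#' over individuals (resampled within populations).
#'
#' Estimators: `"wc_theta"` (default) is the haploid Weir-Cockerham
#' variance-components estimator
#' \eqn{\theta = (MSP - MSW)/(MSP + (n_c - 1) MSW)}, unbiased and therefore
#' allowed to go negative under panmixia; `"nei_gst"` is Nei's
#' \eqn{G_{ST} = (H_T - H_S)/H_T} computed exactly on the supplied haplotype
#' frequencies. `Hs` and `Ht` (plain frequency-based gene diversities) are
#' reported for both.
#'
#' @param haplotypes character vector: one haplotype (sequence or label) per
#'   individual
#' @param populations character/factor vector of population labels, parallel
#'   to `haplotypes`
#' @param estimator `"wc_theta"` or `"nei_gst"`
#' @param resamples bootstrap replicates when jackknife is unavailable
#'   (default 200)
#' @param seed RNG seed for the bootstrap
#' @return a [DiversityResult-class]
#' @export
geneDiversityFst <- function(haplotypes, populations,
                             estimator = c("wc_theta", "nei_gst"),
                             resamples = 200L, seed = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(length(haplotypes) == length(populations))
  populations <- as.character(populations)
  pops <- unique(populations)
  if (length(pops) < 2L) stop("need at least 2 populations")

  counts <- table(haplotype = haplotypes, population = populations)
  hs_ht <- neiDiversities(haplotypes, populations)

  isSeq <- all(nchar(haplotypes) == nchar(haplotypes[1])) &&
    nchar(haplotypes[1]) > 1L &&
    all(grepl("^[ACGTN-]+$", haplotypes))

  if (isSeq) {
    m <- do.call(rbind, strsplit(haplotypes, "", fixed = TRUE))
    polySites <- which(apply(m, 2, function(v) {
      length(unique(v[v != "N"])) > 1L
    }))
    if (!length(polySites)) {
      fst <- if (estimator == "nei_gst") 0 else NA_real_
      return(new("DiversityResult", counts = counts, Hs = hs_ht["Hs"],
                 Ht = hs_ht["Ht"], Fst = fst, sdFst = NA_real_,
                 estimator = estimator, spreadMethod = "none"))
    }
    comps <- lapply(polySites, function(j) {
      fstComponents(m[, j], populations, estimator)
    })
    fst <- ratioOfSums(comps)
    # jackknife over polymorphic sites
    sdFst <- if (length(comps) > 1L) {
      jk <- vapply(seq_along(comps), function(i) {
        ratioOfSums(comps[-i])
      }, numeric(1))
      nL <- length(comps)
      sqrt((nL - 1) / nL * sum((jk - mean(jk))^2))
    } else NA_real_
    spread <- "jackknife over polymorphic sites"
  } else {
    comp <- fstComponents(haplotypes, populations, estimator)
    fst <- ratioOfSums(list(comp))
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(seed)
    bt <- vapply(seq_len(resamples), function(b) {
      idx <- unlist(lapply(pops, function(p) {
        i <- which(populations == p)
        sample(i, length(i), replace = TRUE)
      }))
      ratioOfSums(list(
        fstComponents(haplotypes[idx], populations[idx], estimator)))
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    sdFst <- stats::sd(bt, na.rm = TRUE)
    spread <- "bootstrap over individuals"
  }
  new("DiversityResult", counts = counts, Hs = unname(hs_ht["Hs"]),
      Ht = unname(hs_ht["Ht"]), Fst = fst, sdFst = sdFst,
      estimator = estimator, spreadMethod = spread)
}

# plain-frequency gene diversities: Hs = mean within-pop (1 - sum p^2),
# Ht on pooled frequencies
neiDiversities <- function(alleles, populations) {
  pops <- unique(populations)
  hs <- vapply(pops, function(p) {
    f <- table(alleles[populations == p])
    f <- f / sum(f)
    1 - sum(f^2)
  }, numeric(1))
  ft <- table(alleles) / length(alleles)
  c(Hs = mean(hs), Ht = 1 - sum(ft^2))
}

# numerator/denominator components of Fst at one locus
# wc_theta: haploid Weir-Cockerham variance components, summed over alleles
# nei_gst: Ht - Hs and Ht
fstComponents <- function(alleles, populations, estimator) {
  pops <- unique(populations)
  r <- length(pops)
  ni <- vapply(pops, function(p) sum(populations == p), numeric(1))
  N <- sum(ni)
  states <- unique(alleles[alleles != "N"])
  if (estimator == "nei_gst") {
    d <- neiDiversities(alleles[alleles != "N"],
                        populations[alleles != "N"])
    return(c(num = unname(d["Ht"] - d["Hs"]), den = unname(d["Ht"])))
  }
  keep <- alleles != "N"
  al <- alleles[keep]; po <- populations[keep]
  ni <- vapply(pops, function(p) sum(po == p), numeric(1))
  N <- sum(ni)
  if (any(ni == 0)) {
    pops <- pops[ni > 0]; ni <- ni[ni > 0]; r <- length(pops)
  }
  if (r < 2L || N <= r) return(c(num = 0, den = 0))
  nc <- (N - sum(ni^2) / N) / (r - 1)
  num <- 0; den <- 0
  for (s in states) {
    pi <- vapply(pops, function(p) mean(al[po == p] == s), numeric(1))
    pbar <- sum(ni * pi) / N
    msp <- sum(ni * (pi - pbar)^2) / (r - 1)
    msw <- sum(ni * pi * (1 - pi)) / (N - r)
    num <- num + (msp - msw)
    den <- den + (msp + (nc - 1) * msw)
  }
  c(num = num, den = den)
}

ratioOfSums <- function(comps) {
  num <- sum(vapply(comps, `[[`, numeric(1), "num"))
  den <- sum(vapply(comps, `[[`, numeric(1), "den"))
  if (den == 0) return(NA_real_)
  num / den
}

#' @describeIn DiversityResult-class compact display
#' @param object a `DiversityResult`
#' @export
setMethod("show", "DiversityResult", function(object) {
  cat(sprintf(
    "DiversityResult (%s): Hs = %.4f, Ht = %.4f, Fst = %.4f (sd %.4f, %s)\n",
    object@estimator, object@Hs, object@Ht, object@Fst, object@sdFst,
    object@spreadMethod))
})

#' Build a haplotype network
#'
#' Connects haplotypes by their mutation distance: the number of differing
#' sites, with a merged indel (a site spanning a gap run) counting one step.
#' The default `"msn"` is the minimum-spanning network: edges are added in
#' order of increasing distance, and an edge joins two haplotypes whenever
#' they are not yet connected by strictly shorter edges, so all co-minimal
#' edges are retained and the result is deterministic. `"median_joining"`
#' (experimental) augments the network with quasi-median haplotypes
#' (site-wise majority of mutually close triplets) until closure, which can
#' reveal unsampled intermediate haplotypes.
#'
#' @param x haplotype states: a character state matrix (rows = haplotypes,
#'   columns = sites, rownames = haplotype ids), or the data.frame returned
#'   by [haplotypeMatrix()]
#' @param method `"msn"` (default) or `"median_joining"`
#' @param epsilon tolerance added to the connection threshold (default 0)
#' @return a [HaplotypeNetwork-class]
#' @export
buildNetwork <- function(x, method = c("msn", "median_joining"),
                         epsilon = 0) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    members <- if ("members" %in% names(x)) x$members else x$haplotype
    ids <- if ("haplotype" %in% names(x)) x$haplotype else rownames(x)
    cols <- setdiff(names(x), c("haplotype", "members"))
    states <- as.matrix(x[, cols, drop = FALSE])
    rownames(states) <- ids
  } else {
    states <- as.matrix(x)
    if (is.null(rownames(states))) {
      rownames(states) <- paste0("H", seq_len(nrow(states)))
    }
    members <- rownames(states)
  }
  storage.mode(states) <- "character"
  if (nrow(states) == 0L) stop("need at least one haplotype")
  isMedian <- rep(FALSE, nrow(states))

  if (method == "median_joining" && nrow(states) >= 3L && ncol(states)) {
    res <- addQuasiMedians(states)
    if (nrow(res) > nrow(states)) {
      members <- c(members, rep("", nrow(res) - nrow(states)))
      isMedian <- c(isMedian, rep(TRUE, nrow(res) - nrow(states)))
    }
    states <- res
  }

  n <- nrow(states)
  nodes <- data.frame(id = rownames(states), members = members,
                      median = isMedian, stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), sites = character(0),
                      stringsAsFactors = FALSE)
  if (n > 1L && ncol(states)) {
    d <- hammingStates(states)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    lv <- sort(unique(d[upper.tri(d)]))
    for (w in lv) {
      comp <- igraph::components(g)$membership
      add <- which(upper.tri(d) & d == w, arr.ind = TRUE)
      keep <- add[comp[add[, 1]] != comp[add[, 2]] |
                    (epsilon > 0 & d[add] <= min(lv) + epsilon), ,
                  drop = FALSE]
      if (nrow(keep)) {
        g <- igraph::add_edges(g, t(keep))
        for (i in seq_len(nrow(keep))) {
          a <- keep[i, 1]; b <- keep[i, 2]
          diffSites <- colnames(states)[states[a, ] != states[b, ]]
          edges <- rbind(edges, data.frame(
            from = rownames(states)[a], to = rownames(states)[b],
            weight = w,
            sites = paste(diffSites, collapse = ","),
            stringsAsFactors = FALSE))
        }
      }
      if (igraph::components(g)$no == 1L && epsilon == 0) break
    }
  }
  new("HaplotypeNetwork", nodes = nodes, edges = edges, states = states,
      method = method)
}

# pairwise Hamming distance over state columns (merged indel = 1 step)
hammingStates <- function(states) {
  n <- nrow(states)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(states[i, ] != states[j, ])
    }
  }
  d
}

# iterated quasi-median augmentation (epsilon = 0); site-wise majority of
# triplets, added when new, until closure or the iteration cap
addQuasiMedians <- function(states, maxIter = 10L) {
  for (it in seq_len(maxIter)) {
    n <- nrow(states)
    if (n < 3L) break
    added <- FALSE
    trip <- utils::combn(n, 3)
    for (t in seq_len(ncol(trip))) {
      s <- states[trip[, t], , drop = FALSE]
      med <- vapply(seq_len(ncol(s)), function(j) {
        majorityState(s[, j])
      }, character(1))
      key <- paste(med, collapse = "|")
      have <- apply(states, 1, paste, collapse = "|")
      if (!key %in% have) {
        states <- rbind(states, med)
        rownames(states)[nrow(states)] <-
          paste0("median", nrow(states) - n + it * 0L)
        added <- TRUE
      }
    }
    if (!added) break
  }
  # unique row names
  rownames(states) <- make.unique(rownames(states))
  states
}

#' Write a haplotype network as an edge-list TSV (and optional DOT file)
#'
#' @param net a [HaplotypeNetwork-class]
#' @param path TSV output path
#' @param dot optional path for a Graphviz DOT rendering
#' @return `path`, invisibly
#' @export
writeNetwork <- function(net, path, dot = NULL) {
  stopifnot(is(net, "HaplotypeNetwork"))
  utils::write.table(net@edges[, c("from", "to", "sites")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("node_a", "node_b", "sites"))
  if (!is.null(dot)) {
    lines <- c("graph haplotypes {",
               sprintf("  \"%s\" [shape=%s];", net@nodes$id,
                       ifelse(net@nodes$median, "point", "ellipse")),
               sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                       net@edges$from, net@edges$to, net@edges$sites),
               "}")
    writeLines(lines, dot)
  }
  invisible(path)
}

#' @describeIn HaplotypeNetwork-class compact display
#' @param object a `HaplotypeNetwork`
#' @export
setMethod("show", "HaplotypeNetwork", function(object) {
  cat("HaplotypeNetwork (", object@method, "): ", nrow(object@nodes),
      " node(s), ", nrow(object@edges), " edge(s)\n", sep = "")
  if (any(object@nodes$median)) {
    cat("  including", sum(object@nodes$median), "inferred median node(s)\n")
  }
})
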