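#' Minimal template-switch explanation of a clone from candidate parents
#'
#' Explains a clone sequence as a mosaic of the candidate parental
#' haplotypes with the fewest template switches (crossovers). Informative
#' sites are the positions where the parents differ from one another
#' (restricted to the positions of `sites` when supplied); the child is
#' compared to the parents only there. Gap characters are matched as a fifth
#' state, since indels are genuine haplotype markers at a cloned locus.
#' Positions where the child matches no parent are reported as
#' `unexplained` and never force a switch (they are the child's unique
#' polymorphisms, accounted separately). Positions where the child carries
#' `N` are skipped with a message.
#'
#' The assignment path minimising the number of switches is found by
#' dynamic programming over the ordered informative sites with one state
#' per parent and unit cost per template change; among minimal paths, the
#' one whose breakpoints come earliest (ties then broken by parent order)
#' is reported. Breakpoints are open intervals between consecutive
#' informative sites assigned to different parents.
#'
#' @param child named character scalar (or length-1 `DNAStringSet`); the
#'   clone to explain
#' @param parents named character vector (>= 2) of candidate parental
#'   sequences, same alignment length as `child`
#' @param sites optional [PolymorphismSet-class]; restrict informative sites
#'   to these positions
#' @return a [CrossoverResult-class]
#' @export
#' @examples
#' p <- c(P1 = "AAAAAAAAAA", P2 = "TTTTTTTTTT")
#' minCrossovers(c(ch = "AAAAATTTTT"), p)@kSwitches  # 1
minCrossovers <- function(child, parents, sites = NULL) {
  child <- as.character(asAlignment(child))
  parents <- as.character(asAlignment(parents))
  if (length(child) != 1L) stop("child must be a single sequence")
  if (length(parents) < 2L) stop("need at least 2 candidate parents")
  if (nchar(child) != nchar(parents[1])) {
    stop("child and parents must share the alignment length")
  }
  childId <- names(child)
  parentIds <- names(parents)
  cs <- strsplit(child, "", fixed = TRUE)[[1]]
  pm <- do.call(rbind, strsplit(unname(parents), "", fixed = TRUE))

  informative <- which(apply(pm, 2, function(v) length(unique(v)) > 1L))
  scope <- seq_along(cs)
  if (!is.null(sites)) {
    stopifnot(is(sites, "PolymorphismSet"))
    scope <- sites@sites$position
    informative <- intersect(informative, scope)
  }
  skipN <- informative[cs[informative] == "N"]
  if (length(skipN)) {
    message("child has N at ", length(skipN),
            " informative site(s); skipped")
    informative <- setdiff(informative, skipN)
  }
  if (!length(informative)) stop("no informative sites between the parents")

  # unique polymorphisms: any in-scope position where the child matches no
  # parent (whether or not the parents differ there); they never force a
  # switch
  unexplained <- scope[vapply(scope, function(j) {
    cs[j] != "N" && all(pm[, j] != cs[j])
  }, logical(1))]

  match_ <- t(vapply(informative,
                     function(j) pm[, j] == cs[j], logical(nrow(pm))))
  explained <- rowSums(match_) > 0L
  useSites <- informative[explained]
  useMatch <- match_[explained, , drop = FALSE]

  nP <- length(parentIds)
  nS <- length(useSites)
  path <- rep(NA_character_, length(informative))
  names(path) <- informative
  k <- 0L
  breakpoints <- matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("after", "before")))
  if (nS > 0L) {
    INF <- nS + 1L
    # suffix[i, p]: minimal switches explaining sites i..nS starting on p
    suffix <- matrix(0L, nrow = nS + 1L, ncol = nP)
    for (i in nS:1) {
      stay <- suffix[i + 1L, ]
      best <- min(stay)
      for (p in seq_len(nP)) {
        if (!useMatch[i, p]) {
          suffix[i, p] <- INF
        } else {
          suffix[i, p] <- min(stay[p], best + 1L)
        }
      }
      if (all(suffix[i, ] >= INF)) stop("internal: unexplained site in DP")
    }
    # greedy left-to-right reconstruction: place switches as early as
    # possible among optimal paths, parent-order tie-break
    lab <- integer(nS)
    cur <- which(suffix[1, ] == min(suffix[1, ]))[1]
    lab[1] <- cur
    if (nS > 1L) {
      for (i in 2:nS) {
        costs <- vapply(seq_len(nP), function(p) {
          if (!useMatch[i, p]) return(INF)
          suffix[i, p] + as.integer(p != cur)
        }, integer(1))
        best <- min(costs)
        cand <- which(costs == best)
        # prefer an early switch when switching is co-optimal
        pick <- if (any(cand != cur)) cand[cand != cur][1] else cur
        if (pick != cur) {
          breakpoints <- rbind(breakpoints,
                               c(useSites[i - 1L], useSites[i]))
          k <- k + 1L
        }
        cur <- pick
        lab[i] <- cur
      }
    }
    path[match(useSites, informative)] <- parentIds[lab]
  }
  new("CrossoverResult", childId = if (is.null(childId)) "child" else childId,
      parentIds = parentIds,
      informativeSites = as.integer(informative),
      path = unname(path), kSwitches = k,
      breakpoints = breakpoints,
      unexplained = as.integer(unexplained))
}

#' @describeIn CrossoverResult-class compact display
#' @param object a `CrossoverResult`
#' @export
setMethod("show", "CrossoverResult", function(object) {
  cat("CrossoverResult:", object@childId, "vs",
      paste(object@parentIds, collapse = "/"), "\n")
  cat("  informative sites:", length(object@informativeSites),
      " switches:", object@kSwitches,
      " unexplained:", length(object@unexplained), "\n")
  if (object@kSwitches > 0L) {
    for (i in seq_len(nrow(object@breakpoints))) {
      cat(sprintf("  crossover between positions %d-%d\n",
                  object@breakpoints[i, 1], object@breakpoints[i, 2]))
    }
  }
  if (length(object@unexplained)) {
    cat("  unique polymorphisms at:",
        paste(object@unexplained, collapse = ", "), "\n")
  }
})

# refined incompatibility of two site columns:
# cycles of the partition intersection graph = edges - vertices + components
refinedIncompatibility <- function(a, b) {
  keep <- a != "N" & b != "N"
  riCoded(match(a[keep], unique(a[keep])), match(b[keep], unique(b[keep])))
}

# integer-coded version: a, b in 1..nStates, no missing values
riCoded <- function(a, b) {
  combo <- unique(a * 16L + b)
  e <- length(combo)
  na <- max(a); nb <- max(b)
  v <- na + nb
  parent <- seq_len(v)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (cmb in combo) {
    i <- cmb %/% 16L
    j <- na + cmb %% 16L
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  comp <- sum(vapply(seq_len(v), find, integer(1)) == seq_len(v))
  e - v + comp
}

#' Pairwise homoplasy index (PHI) test for recombination
#'
#' Computes the refined incompatibility score (the minimum number of extra
#' mutations, i.e. homoplasies, any genealogy must invoke to accommodate a
#' pair of sites) for every pair of parsimony-informative sites lying within
#' `window` alignment columns (nt) of each other, and takes the mean as the
#' statistic.
#' Recombination lets nearby sites stay compatible while distant ones
#' conflict, so under recombination the observed nearby-pair mean is low
#' relative to its permutation distribution; clonal evolution with
#' exchangeable site order gives a uniform p-value. The p-value is the
#' fraction of site-order permutations (site contents shuffled across the
#' informative positions) with a statistic less than or equal to the
#' observed one (`method = "normal"` uses a normal approximation to the
#' permutation distribution instead). Gaps count as a fifth character
#' state; columns containing `N` are excluded.
#'
#' @param aln `DNAStringSet` alignment (>= 4 sequences)
#' @param window pair window in alignment columns, nt (default 100)
#' @param nPermutations permutations for the p-value (default 1000)
#' @param seed RNG seed for the permutation test (required for
#'   reproducibility)
#' @param method `"permutation"` (default) or `"normal"`
#' @return a [PhiResult-class]; flagged not computable with < 4 sequences
#'   or < 2 informative sites
#' @export
phiTest <- function(aln, window = 100L, nPermutations = 1000L, seed = 1L,
                    method = c("permutation", "normal")) {
  method <- match.arg(method)
  aln <- asAlignment(aln)
  m <- alignmentMatrix(aln)
  notComputable <- function(n) {
    new("PhiResult", statistic = NA_real_, pValue = NA_real_,
        windowSize = as.integer(window), nInformative = as.integer(n),
        nPermutations = as.integer(nPermutations), computable = FALSE,
        method = method)
  }
  if (nrow(m) < 4L) return(notComputable(0L))
  keep <- !apply(m == "N", 2, any)
  m <- m[, keep, drop = FALSE]
  # parsimony-informative: >= 2 states each seen >= 2 times
  informative <- which(apply(m, 2, function(v) {
    tab <- table(v)
    sum(tab >= 2L) >= 2L
  }))
  origPos <- which(keep)[informative]
  if (length(informative) < 2L) return(notComputable(length(informative)))
  mi <- m[, informative, drop = FALSE]
  # duplicate sequences never change any pair's incompatibility
  mi <- mi[!duplicated(apply(mi, 1, paste, collapse = "")), , drop = FALSE]
  s <- ncol(mi)
  # integer-code each column's states as 1..k
  mic <- apply(mi, 2, function(v) match(v, unique(v)))
  ri <- matrix(0, s, s)
  for (i in seq_len(s - 1L)) {
    ai <- mic[, i]
    for (j in (i + 1L):s) {
      ri[i, j] <- ri[j, i] <- riCoded(ai, mic[, j])
    }
  }
  pd <- abs(outer(origPos, origPos, "-"))
  nearby <- pd >= 1L & pd <= window
  if (!any(nearby)) return(notComputable(s))
  obs <- mean(ri[nearby])
  withr_seed <- function(expr) {
    # local RNG scope so the test never disturbs the caller's RNG stream
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  perm <- withr_seed({
    vapply(seq_len(nPermutations), function(b) {
      o <- sample.int(s)
      mean(ri[o, o][nearby])
    }, numeric(1))
  })
  p <- if (method == "permutation") {
    (1 + sum(perm <= obs)) / (nPermutations + 1)
  } else {
    mu <- mean(perm); sdv <- stats::sd(perm)
    if (sdv == 0) 1 else stats::pnorm(obs, mean = mu, sd = sdv)
  }
  new("PhiResult", statistic = obs, pValue = p,
      windowSize = as.integer(window), nInformative = as.integer(s),
      nPermutations = as.integer(nPermutations), computable = TRUE,
      method = method)
}

#' @describeIn PhiResult-class compact display
#' @param object a `PhiResult`
#' @export
setMethod("show", "PhiResult", function(object) {
  if (!object@computable) {
    cat("PHI test: not computable (", object@nInformative,
        "informative sites )\n")
    return(invisible())
  }
  cat(sprintf(
    "PHI test: statistic = %.4g, p = %.4g (%s, %d informative sites, %d permutations)\n",
    object@statistic, object@pValue, object@method, object@nInformative,
    object@nPermutations))
})
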