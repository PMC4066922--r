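#' @importFrom Biostrings readBStringSet writeXStringSet DNAStringSet width
#' @importFrom IRanges IRanges
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read a multiple alignment from FASTA
#'
#' Reads an aligned FASTA file into a [Biostrings::DNAStringSet] after
#' validation: all sequences must have identical length, ids must be unique
#' and non-empty, and the alphabet is restricted to `A,C,G,T,N,-` after
#' uppercasing. `U` is mapped to `T` with a warning (RNA-style FASTA
#' dialects). Record order is preserved.
#'
#' @param path path to a FASTA file
#' @return a named `DNAStringSet` of equal-width sequences
#' @seealso [writeAlignment()], [partitionAlignment()]
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT-ACGTA", ">b", "ACGTTACGTA"), tmp)
#' aln <- readAlignment(tmp)
#' Biostrings::width(aln)
readAlignment <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  x <- toupper(as.character(raw))
  ids <- names(raw)
  # FASTA headers may carry descriptions after whitespace; id = first token
  ids <- sub("\\s.*$", "", ids)
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("alignment contains a record with an empty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(x) <- ids
  validateAlignmentStrings(x)
  x <- vapply(x, function(s) gsub("U", "T", s, fixed = TRUE), character(1))
  if (any(grepl("U", toupper(as.character(raw)), fixed = TRUE))) {
    warning("'U' characters mapped to 'T'")
  }
  Biostrings::DNAStringSet(x)
}

# shared validation for character-vector alignments
validateAlignmentStrings <- function(x) {
  if (length(x) == 0L) stop("empty alignment")
  ids <- names(x)
  w <- nchar(x)
  if (length(unique(w)) > 1L) {
    modal <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
    bad <- ids[w != modal]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " differ in length from the majority (", modal, " columns)")
  }
  if (w[1] < 1L) stop("alignment length must be >= 1")
  bad <- regexpr("[^ACGTNU-]", x)  # '-' last: not a range
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop("illegal character '", substr(x[i], bad[i], bad[i]),
         "' in sequence ", ids[i], " at position ", bad[i])
  }
  invisible(TRUE)
}

#' Write a multiple alignment to FASTA
#'
#' Inverse of [readAlignment()]; writing then re-reading is lossless for ids
#' and sequences, and repeated write calls on the same alignment produce
#' byte-identical files.
#'
#' @param aln a `DNAStringSet` (or named character vector) of equal-width
#'   sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAlignment <- function(aln, path) {
  aln <- asAlignment(aln)
  Biostrings::writeXStringSet(aln, filepath = path, width = 70L)
  invisible(path)
}

# coerce character vectors to DNAStringSet, pass DNAStringSet through
asAlignment <- function(aln) {
  if (is(aln, "DNAStringSet")) {
    if (length(unique(Biostrings::width(aln))) > 1L) {
      stop("ragged alignment")
    }
    return(aln)
  }
  if (is.character(aln)) {
    if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
    x <- toupper(aln)
    validateAlignmentStrings(x)
    return(Biostrings::DNAStringSet(x))
  }
  stop("expected a DNAStringSet or a named character vector")
}

# alignment as a character matrix (rows = sequences, cols = columns)
alignmentMatrix <- function(aln) {
  aln <- asAlignment(aln)
  m <- do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Construct a RegionMap
#'
#' @param start,end integer vectors of 1-based inclusive column intervals
#' @param label character labels (typically `"exon"`/`"intron"`)
#' @param alignmentLength total number of alignment columns
#' @return a [RegionMap-class] object
#' @export
#' @examples
#' RegionMap(start = c(1, 101), end = c(100, 150),
#'           label = c("exon", "intron"), alignmentLength = 150)
RegionMap <- function(start, end, label, alignmentLength) {
  o <- order(start)
  new("RegionMap",
      ranges = IRanges::IRanges(start = as.integer(start[o]),
                                end = as.integer(end[o])),
      label = as.character(label[o]),
      alignmentLength = as.integer(alignmentLength))
}

#' Read exon/intron regions from a BED-style file
#'
#' The file must have at least four whitespace-separated columns:
#' chrom (ignored), start, end, label. Input coordinates follow the BED
#' convention (0-based, half-open) and are converted to the internal 1-based
#' inclusive convention, so that reported positions match positions counted
#' directly on the alignment. Intervals must tile the alignment exactly:
#' overlaps, gaps in coverage and out-of-range intervals are hard errors.
#'
#' @param path path to the BED-style file
#' @param alignmentLength number of columns of the companion alignment
#' @return a [RegionMap-class]
#' @export
readRegions <- function(path, alignmentLength) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "label"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  if (nrow(tab) == 0L) stop("empty region file: ", path)
  if (!all(tab$label %in% REGION_LABELS)) {
    bad <- setdiff(unique(tab$label), REGION_LABELS)
    stop("region labels must be 'exon' or 'intron'; found: ",
         paste(bad, collapse = ", "))
  }
  start1 <- tab$start + 1L   # BED 0-based half-open -> 1-based inclusive
  end1 <- tab$end
  if (any(start1 > end1)) {
    i <- which(start1 > end1)[1]
    stop("empty or inverted interval: [", tab$start[i], ",", tab$end[i], ")")
  }
  alignmentLength <- as.integer(alignmentLength)
  if (any(end1 > alignmentLength) || any(start1 < 1L)) {
    i <- which(end1 > alignmentLength | start1 < 1L)[1]
    stop("interval out of range for alignment of length ", alignmentLength,
         ": [", tab$start[i], ",", tab$end[i], ")")
  }
  o <- order(start1)
  start1 <- start1[o]; end1 <- end1[o]; lab <- tab$label[o]
  if (any(start1[-1] <= end1[-length(end1)])) {
    i <- which(start1[-1] <= end1[-length(end1)])[1]
    stop("overlapping intervals near [", start1[i + 1] - 1L, ",",
         end1[i + 1], ")")
  }
  if (start1[1] != 1L || end1[length(end1)] != alignmentLength ||
      any(start1[-1] != end1[-length(end1)] + 1L)) {
    stop("intervals must cover every alignment column exactly once")
  }
  RegionMap(start1, end1, lab, alignmentLength)
}

#' Extract the columns of an alignment carrying one region label
#'
#' Concatenates, column-wise and in order, every interval with the requested
#' label; original row order is preserved. Used to remove introns before
#' exon-only analyses.
#'
#' @param aln a `DNAStringSet` alignment
#' @param regions a [RegionMap-class] covering `aln`
#' @param keep label to retain (`"exon"` or `"intron"`)
#' @return a `DNAStringSet` of the kept columns
#' @export
partitionAlignment <- function(aln, regions, keep) {
  aln <- asAlignment(aln)
  stopifnot(is(regions, "RegionMap"))
  if (Biostrings::width(aln)[1] != regions@alignmentLength) {
    stop("regions cover ", regions@alignmentLength,
         " columns but alignment has ", Biostrings::width(aln)[1])
  }
  if (!keep %in% regions@label) {
    stop("label '", keep, "' absent from regions")
  }
  cols <- regionColumns(regions, keep)
  m <- alignmentMatrix(aln)
  out <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(aln)
  Biostrings::DNAStringSet(out)
}

# integer columns carrying a label
regionColumns <- function(regions, lab) {
  idx <- which(regions@label == lab)
  unlist(lapply(idx, function(i) {
    seq.int(IRanges::start(regions@ranges)[i], IRanges::end(regions@ranges)[i])
  }), use.names = FALSE)
}

# label of each alignment column
columnLabels <- function(regions) {
  lab <- character(regions@alignmentLength)
  for (i in seq_along(regions@label)) {
    lab[seq.int(IRanges::start(regions@ranges)[i],
                IRanges::end(regions@ranges)[i])] <- regions@label[i]
  }
  lab
}

#' Total columns per region label
#'
#' @param regions a [RegionMap-class]
#' @return named integer vector of summed interval lengths per label
#' @export
regionLengths <- function(regions) {
  stopifnot(is(regions, "RegionMap"))
  w <- IRanges::end(regions@ranges) - IRanges::start(regions@ranges) + 1L
  vapply(split(w, regions@label), sum, integer(1))
}

#' Read a clone sample sheet
#'
#' Tab-separated file with header
#' `seq_id  basidioma_id  locality  clone_count` mapping every aligned clone
#' sequence to its fruit body and collection locality. `clone_count` carries
#' the number of identical sequenced clones the record stands for (the
#' bracketed counts of a collection table), and must be >= 1.
#'
#' @param path path to the TSV file
#' @param aln optional companion alignment; if given, every `seq_id` must be
#'   present in it
#' @return a data.frame with the four columns, `clone_count` integer
#' @export
readSampleSheet <- function(path, aln = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "basidioma_id", "locality", "clone_count")
  if (!all(need %in% names(tab))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  tab$clone_count <- as.integer(tab$clone_count)
  validateSampleSheet(tab, aln)
  tab
}

validateSampleSheet <- function(tab, aln = NULL) {
  if (any(is.na(tab$clone_count)) || any(tab$clone_count < 1L)) {
    stop("clone_count must be an integer >= 1")
  }
  if (any(!nzchar(tab$basidioma_id)) || any(!nzchar(tab$locality))) {
    stop("basidioma_id and locality must be non-empty")
  }
  if (anyDuplicated(tab$seq_id)) {
    stop("duplicate seq_id in sample sheet: ",
         paste(unique(tab$seq_id[duplicated(tab$seq_id)]), collapse = ", "))
  }
  if (!is.null(aln)) {
    missing <- setdiff(tab$seq_id, names(asAlignment(aln)))
    if (length(missing)) {
      stop("seq_id(s) absent from alignment: ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write a sample sheet
#' @param sheet data.frame as returned by [readSampleSheet()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn RegionMap-class compact display
#' @param object a `RegionMap`
#' @export
setMethod("show", "RegionMap", function(object) {
  cat("RegionMap on", object@alignmentLength, "alignment columns\n")
  w <- regionLengths(object)
  for (lab in names(w)) {
    cat(sprintf("  %s: %d interval(s), %d nt\n", lab,
                sum(object@label == lab), w[[lab]]))
  }
})
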