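#' Construct a genomic interval table
#'
#' Intervals are BED-convention throughout: 0-based, half-open `[start, end)`,
#' so `length = end - start` and two intervals touching at a coordinate do not
#' overlap. Chromosome names are compared by exact string match.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start positions (inclusive).
#' @param end Integer vector of end positions (exclusive); must exceed `start`.
#' @param name Optional character vector of region names.
#' @param score Optional numeric vector of scores.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, one row per interval, in input order.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  if (length(chrom) == 1L && n != 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer coordinates")
  if (any(start < 0)) stop("negative start coordinate")
  bad <- which(end <= start)
  if (length(bad))
    stop("end <= start at interval ", bad[1L], " (", chrom[bad[1L]], ":",
         start[bad[1L]], "-", end[bad[1L]], ")")
  data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = if (is.null(name)) rep(NA_character_, n) else as.character(name),
    score = if (is.null(score)) rep(NA_real_, n) else as.numeric(score),
    stringsAsFactors = FALSE
  )
}

.check_intervals <- function(x, arg = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(arg, " must be a data.frame with chrom/start/end columns")
  invisible(x)
}

## Internal bridge to Bioconductor range machinery. GRanges is 1-based closed:
## [start, end) maps to [start + 1, end], which preserves overlap and gap
## semantics exactly.
.as_gr <- function(x, levels = unique(x$chrom)) {
  .check_intervals(x)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = levels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

.from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = NA_character_,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read a BED3/BED5 file
#'
#' Tab-separated, no header; columns 4 and 5 (name, score) are kept when
#' present. Input order is preserved. A malformed line (fewer than three
#' columns, non-integer coordinates, or `end <= start`) raises an error naming
#' the offending line.
#'
#' @param path Path to a BED file.
#' @return Interval `data.frame` as from [genomic_intervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": end <= start")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- rep(NA_real_, length(lines))
  has5 <- nf >= 5L
  if (any(has5))
    score[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  genomic_intervals(chrom, start, end, name = name, score = score)
}

#' Write intervals to a BED file
#'
#' Writes BED3 when neither name nor score is present, BED5 otherwise (missing
#' names become ".", missing scores 0). Round-trips coordinates exactly.
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  .check_intervals(x)
  if (all(is.na(x$name)) && all(is.na(x$score))) {
    out <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  } else {
    nm <- ifelse(is.na(x$name), ".", x$name)
    sc <- ifelse(is.na(x$score), 0, x$score)
    out <- sprintf("%s\t%d\t%d\t%s\t%s", x$chrom, x$start, x$end, nm,
                   format(sc, trim = TRUE, scientific = FALSE))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `position`, `strand`.
#' A gene may own several TSS records.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with those four columns.
#' @export
read_tss <- function(path) {
  tss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "position", "strand")
  if (!all(need %in% names(tss)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  tss$position <- as.integer(tss$position)
  if (any(is.na(tss$position)) || any(tss$position < 0))
    stop("TSS positions must be non-negative integers")
  if (!all(tss$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  tss[, need]
}

#' Merge intervals, bridging gaps up to a maximum
#'
#' Two intervals on the same chromosome are merged iff the gap between them is
#' at most `max_gap` bases (a gap of 0 means overlapping or book-ended).
#' Output is sorted and non-overlapping.
#'
#' @param ivs Interval `data.frame`.
#' @param max_gap Non-negative integer gap (bp) to bridge.
#' @return Merged interval `data.frame` (name/score columns are dropped to NA).
#' @export
merge_intervals <- function(ivs, max_gap = 0L) {
  .check_intervals(ivs)
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (nrow(ivs) == 0L) return(genomic_intervals(character(), integer(), integer()))
  gr <- GenomicRanges::reduce(.as_gr(ivs), min.gapwidth = max_gap + 1L)
  out <- .from_gr(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag intervals overlapping another set
#'
#' @param a,b Interval `data.frame`s in the same genome namespace.
#' @return Logical vector over rows of `a`: `TRUE` where `a[i]` shares at
#'   least one base with some interval of `b` on the same chromosome.
#' @export
overlap_any <- function(a, b) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  lev <- unique(c(a$chrom, b$chrom))
  IRanges::overlapsAny(.as_gr(a, lev), .as_gr(b, lev))
}

#' Assign genes to regions by TSS overlap
#'
#' A TSS at position `p` hits region `[start, end)` iff `start <= p < end`
#' (half-open point membership); strand is ignored. All matching regions are
#' reported for every TSS of a gene.
#'
#' @param tss TSS `data.frame` (`gene_id`, `chrom`, `position`, `strand`).
#' @param regions Interval `data.frame`.
#' @return Named list mapping `gene_id` to the sorted unique integer indices
#'   of overlapped rows of `regions`; genes with no hit are absent.
#' @export
assign_tss <- function(tss, regions) {
  .check_intervals(regions, "regions")
  if (nrow(regions) == 0L || nrow(tss) == 0L) return(list())
  lev <- unique(c(tss$chrom, regions$chrom))
  pt <- GenomicRanges::GRanges(
    seqnames = factor(tss$chrom, levels = lev),
    ranges = IRanges::IRanges(start = tss$position + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(pt, .as_gr(regions, lev))
  if (!length(hits)) return(list())
  g <- tss$gene_id[S4Vectors::queryHits(hits)]
  idx <- S4Vectors::subjectHits(hits)
  lapply(split(idx, g), function(i) sort(unique(i)))
}
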