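#' Configuration for differential-acetylation region calling
#'
#' @param fdr_threshold Per-bin FDR cutoff for calling a bin UP or DOWN
#'   (default 0.05).
#' @param ratio_up Region is UP when the UP:DOWN bin ratio is at least this
#'   (default 2).
#' @param ratio_down Region is DOWN when the ratio is at most this
#'   (default 0.5).
#' @param min_bin_peak_overlap Minimum bin/peak overlap in bp for a bin to be
#'   attributed to a peak (default 75).
#' @return A list with class `diffac_config`.
#' @export
diffac_config <- function(fdr_threshold = 0.05, ratio_up = 2,
                          ratio_down = 0.5, min_bin_peak_overlap = 75L) {
  if (!(ratio_down <= 1 && 1 <= ratio_up))
    stop("need ratio_down <= 1 <= ratio_up")
  if (min_bin_peak_overlap < 1) stop("min_bin_peak_overlap must be >= 1")
  structure(list(fdr_threshold = fdr_threshold, ratio_up = ratio_up,
                 ratio_down = ratio_down,
                 min_bin_peak_overlap = as.integer(min_bin_peak_overlap)),
            class = "diffac_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values (monotone, clipped at 1), applied
#' genome-wide over all tested bins.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Label bins as UP / DOWN / NS
#'
#' UP requires `fdr <= fdr_threshold` and a positive log2 fold change; DOWN a
#' negative one; everything else (including a significant bin with log2fc
#' exactly 0, whose sign is undefined) is NS.
#'
#' @param bins `data.frame` with columns `log2fc` and `fdr` (compute `fdr`
#'   with [bh_adjust()] first).
#' @param cfg A [diffac_config()].
#' @return Character vector of per-bin labels.
#' @export
label_bins <- function(bins, cfg = diffac_config()) {
  if (!all(c("log2fc", "fdr") %in% names(bins)))
    stop("bins must have log2fc and fdr columns")
  sig <- bins$fdr <= cfg$fdr_threshold
  ifelse(sig & bins$log2fc > 0, "UP",
         ifelse(sig & bins$log2fc < 0, "DOWN", "NS"))
}

#' Group bins under the peaks they overlap
#'
#' A bin is attributed to a peak when their overlap is at least
#' `min_bin_peak_overlap` bases. A bin clearing that threshold for several
#' peaks goes to the peak with the largest overlap (ties to the leftmost
#' peak); bins overlapping no peak are dropped. Peaks must be non-overlapping
#' (pre-merge them with [merge_intervals()]).
#'
#' @param bins Interval `data.frame` of bins (non-overlapping).
#' @param peaks Interval `data.frame` of peaks; row `i` gets id
#'   `peaks$name[i]` when present, else `peak_<i>`.
#' @param cfg A [diffac_config()].
#' @return Named list mapping peak id to integer indices of member bins
#'   (peaks with no bins are absent).
#' @export
group_bins_by_peak <- function(bins, peaks, cfg = diffac_config()) {
  .check_intervals(bins, "bins"); .check_intervals(peaks, "peaks")
  if (nrow(peaks) > 1L) {
    ov <- GenomicRanges::findOverlaps(.as_gr(peaks), .as_gr(peaks))
    if (length(ov) > nrow(peaks))
      stop("peaks overlap each other; pre-merge them with merge_intervals()")
  }
  ids <- if (!is.null(peaks$name) && !anyNA(peaks$name)) peaks$name else
    sprintf("peak_%d", seq_len(nrow(peaks)))
  lev <- unique(c(bins$chrom, peaks$chrom))
  gr_b <- .as_gr(bins, lev); gr_p <- .as_gr(peaks, lev)
  hits <- GenomicRanges::findOverlaps(gr_b, gr_p,
                                      minoverlap = cfg$min_bin_peak_overlap)
  if (!length(hits)) return(stats::setNames(list(), character(0)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ovw <- GenomicRanges::width(IRanges::pintersect(gr_b[q], gr_p[s]))
  ## best peak per bin: largest overlap, ties to leftmost (smallest start,
  ## then smallest index)
  ord <- order(q, -ovw, peaks$start[s], s)
  q <- q[ord]; s <- s[ord]
  keep <- !duplicated(q)
  q <- q[keep]; s <- s[keep]
  grp <- split(q, ids[s])
  lapply(grp, function(i) sort(i))
}

#' Classify merged regions from member-bin labels
#'
#' With `u` UP and `d` DOWN bins in a group: both zero gives UNCHANGED; only
#' UP bins gives UP; only DOWN bins gives DOWN; otherwise the ratio `u / d`
#' decides: UP when `>= ratio_up`, DOWN when `<= ratio_down`, MIXED in
#' between. The region interval spans min start to max end of member bins.
#'
#' @param groups Mapping from [group_bins_by_peak()].
#' @param bins Interval `data.frame` of bins (same one used for grouping).
#' @param bin_labels Per-bin labels from [label_bins()].
#' @param cfg A [diffac_config()].
#' @return `data.frame` with columns `peak_id`, `chrom`, `start`, `end`,
#'   `n_up`, `n_down`, `n_bins`, `direction`.
#' @export
classify_regions <- function(groups, bins, bin_labels, cfg = diffac_config()) {
  if (length(bin_labels) != nrow(bins))
    stop("bin_labels must match rows of bins")
  if (!length(groups))
    return(data.frame(peak_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_up = integer(),
                      n_down = integer(), n_bins = integer(),
                      direction = character(), stringsAsFactors = FALSE))
  rows <- lapply(names(groups), function(pid) {
    i <- groups[[pid]]
    if (!length(i)) stop("empty bin group for ", pid)
    u <- sum(bin_labels[i] == "UP"); d <- sum(bin_labels[i] == "DOWN")
    dir <- if (u == 0L && d == 0L) "UNCHANGED"
      else if (d == 0L) "UP"
      else if (u == 0L) "DOWN"
      else {
        r <- u / d
        if (r >= cfg$ratio_up) "UP"
        else if (r <= cfg$ratio_down) "DOWN"
        else "MIXED"
      }
    data.frame(peak_id = pid, chrom = bins$chrom[i[1L]],
               start = min(bins$start[i]), end = max(bins$end[i]),
               n_up = u, n_down = d, n_bins = length(i), direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Link classified regions to genes
#'
#' A gene is linked to a region by direct TSS overlap, or through an optional
#' precomputed distal link table (`region_id`, `gene_id`). Each gene reports
#' the multiset of directions of its linked regions.
#'
#' @param regions `data.frame` from [classify_regions()].
#' @param tss TSS `data.frame`.
#' @param distal_links Optional `data.frame` with columns `region_id`,
#'   `gene_id`; referencing an unknown region id is an error.
#' @return Long-form `data.frame` (`gene_id`, `peak_id`, `direction`), one
#'   row per gene-region link; genes with no link are absent.
#' @export
regions_to_genes <- function(regions, tss, distal_links = NULL) {
  hits <- assign_tss(tss, regions)
  out <- if (length(hits)) {
    do.call(rbind, lapply(names(hits), function(g)
      data.frame(gene_id = g, peak_id = regions$peak_id[hits[[g]]],
                 direction = regions$direction[hits[[g]]],
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_id = character(), peak_id = character(),
               direction = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(distal_links)) {
    if (!all(c("region_id", "gene_id") %in% names(distal_links)))
      stop("distal_links needs region_id and gene_id columns")
    unknown <- setdiff(distal_links$region_id, regions$peak_id)
    if (length(unknown))
      stop("distal_links references unknown region ids: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    m <- match(distal_links$region_id, regions$peak_id)
    out <- rbind(out, data.frame(gene_id = distal_links$gene_id,
                                 peak_id = distal_links$region_id,
                                 direction = regions$direction[m],
                                 stringsAsFactors = FALSE))
  }
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Association between region direction and gene identity class
#'
#' For each region direction category, counts genes of each identity class
#' and reports the count relative to the reference class (OTHER), with a
#' Fisher exact test of class membership vs the category (BH-corrected across
#' categories).
#'
#' @param gene_regions Long-form link table from [regions_to_genes()].
#' @param calls Identity calls from [classify_genes()].
#' @param classes Gene classes to contrast against the reference
#'   (default `c("ID", "UBQ")`).
#' @param reference Reference gene class (default `"OTHER"`).
#' @return `data.frame` with one row per (category, class): counts, ratio to
#'   reference (NA when the reference count is zero), odds ratio, `p` and
#'   BH-adjusted `q`.
#' @export
direction_class_association <- function(gene_regions, calls,
                                        classes = c("ID", "UBQ"),
                                        reference = "OTHER") {
  common <- intersect(gene_regions$gene_id, calls$gene_id)
  if (!length(common)) stop("no genes shared between links and identity calls")
  klass <- stats::setNames(calls$klass, calls$gene_id)
  cats <- unique(gene_regions$direction)
  rows <- list()
  for (cat in cats) {
    in_cat <- unique(gene_regions$gene_id[gene_regions$direction == cat])
    in_cat <- intersect(in_cat, calls$gene_id)
    for (cl in classes) {
      n_cl_cat <- sum(klass[in_cat] == cl)
      n_ref_cat <- sum(klass[in_cat] == reference)
      n_cl_all <- sum(calls$klass == cl)
      n_ref_all <- sum(calls$klass == reference)
      tab <- matrix(c(n_cl_cat, n_ref_cat,
                      n_cl_all - n_cl_cat, n_ref_all - n_ref_cat), 2L)
      p <- stats::fisher.test(tab)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, klass = cl, n_class = n_cl_cat,
        n_reference = n_ref_cat,
        ratio = if (n_ref_cat > 0L) n_cl_cat / n_ref_cat else NA_real_,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cl in classes)
    out$q[out$klass == cl] <- bh_adjust(out$p[out$klass == cl])
  rownames(out) <- NULL
  out
}

#' Run the full bin-to-region differential pipeline
#'
#' Adjusts bin p-values genome-wide, labels bins, groups them under peaks and
#' classifies the merged regions.
#'
#' @param bins `data.frame` with `chrom`, `start`, `end`, `log2fc`, `pvalue`.
#' @param peaks Interval `data.frame` of pre-merged peaks.
#' @param cfg A [diffac_config()].
#' @return List with `bins` (with `fdr` and `label` columns) and `regions`
#'   (from [classify_regions()]).
#' @export
call_diff_regions <- function(bins, peaks, cfg = diffac_config()) {
  if (!"pvalue" %in% names(bins)) stop("bins must have a pvalue column")
  bins$fdr <- bh_adjust(bins$pvalue)
  bins$label <- label_bins(bins, cfg)
  groups <- group_bins_by_peak(bins, peaks, cfg)
  list(bins = bins, regions = classify_regions(groups, bins, bins$label, cfg))
}
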