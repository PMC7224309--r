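#' Configuration for enhancer stitching
#'
#' @param stitch_distance Maximum gap (bp) bridged when stitching constituent
#'   peaks into enhancers; default 12500.
#' @param tss_exclusion Distance (bp) around TSS to mask before stitching;
#'   default 0, i.e. no masking (the only mode implemented).
#' @return A list with class `stitch_config`.
#' @export
stitch_config <- function(stitch_distance = 12500L, tss_exclusion = 0L) {
  if (stitch_distance < 0 || tss_exclusion < 0)
    stop("distances must be >= 0")
  if (tss_exclusion != 0)
    stop("tss_exclusion != 0 is not implemented")
  structure(list(stitch_distance = as.integer(stitch_distance),
                 tss_exclusion = as.integer(tss_exclusion)),
            class = "stitch_config")
}

#' Stitch peaks into candidate enhancers
#'
#' Constituent peaks separated by at most `stitch_distance` bases are merged
#' into one stitched enhancer. Each stitched region's `score` is the sum of
#' its member peaks' scores (used as the signal when ranking); peaks without
#' scores contribute 0.
#'
#' @param peaks Interval `data.frame`, optionally with a `score` column.
#' @param cfg A [stitch_config()].
#' @return Interval `data.frame` of stitched enhancers, sorted, with summed
#'   `score`.
#' @export
stitch_peaks <- function(peaks, cfg = stitch_config()) {
  stitched <- merge_intervals(peaks, cfg$stitch_distance)
  if (nrow(stitched) == 0L) return(stitched)
  sc <- peaks$score
  if (is.null(sc)) sc <- rep(0, nrow(peaks))
  sc[is.na(sc)] <- 0
  hits <- GenomicRanges::findOverlaps(.as_gr(peaks), .as_gr(stitched))
  tot <- rep(0, nrow(stitched))
  agg <- tapply(sc[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  stitched$score <- tot
  stitched$name <- sprintf("enh_%d", seq_len(nrow(stitched)))
  stitched
}

#' Rank-ordering super-enhancer cutoff
#'
#' Enhancers are sorted by ascending signal; rank and signal are both min-max
#' scaled to `[0, 1]` and the cutoff is the signal at the first point (from
#' the low end) where the forward finite-difference slope of the scaled curve
#' reaches 1 — the discrete form of the geometric tangent rule. An enhancer
#' is a super-enhancer iff its signal strictly exceeds the cutoff signal, so
#' flags are invariant under positive affine rescaling of all signals; all
#' signals equal yields zero super-enhancers.
#'
#' @param signal Numeric vector of non-negative per-enhancer signals
#'   (length >= 2).
#' @return List with `cutoff_signal` (original units), `is_super` (logical,
#'   input order) and `rank` (ascending-signal ranks, ties by input order).
#' @export
rose_cutoff <- function(signal) {
  n <- length(signal)
  if (n < 2L) stop("need at least 2 enhancers")
  if (any(signal < 0)) stop("signals must be >= 0")
  ord <- order(signal)
  s <- signal[ord]
  rng <- s[n] - s[1L]
  if (rng == 0) {
    return(list(cutoff_signal = s[1L], is_super = rep(FALSE, n),
                rank = order(ord)))
  }
  y <- (s - s[1L]) / rng
  x <- (seq_len(n) - 1) / (n - 1)
  slope <- diff(y) / diff(x)            # = diff(y) * (n - 1)
  i <- which(slope >= 1 - 1e-9)[1L]   # tolerance for slopes sitting on 1
  cutoff_scaled <- if (is.na(i)) y[n] else y[i]
  cutoff_signal <- cutoff_scaled * rng + s[1L]
  list(cutoff_signal = cutoff_signal,
       is_super = signal > cutoff_signal,
       rank = order(ord))
}

#' Identify super-enhancers from constituent peaks
#'
#' Stitches peaks, ranks stitched enhancers by signal and flags
#' super-enhancers with the tangent cutoff.
#'
#' @param peaks Interval `data.frame` with per-peak `score` (signal).
#' @param cfg A [stitch_config()].
#' @return `data.frame` of stitched enhancers with columns `signal`, `rank`
#'   and `is_super` added, plus attribute `cutoff_signal`.
#' @export
rank_enhancers <- function(peaks, cfg = stitch_config()) {
  enh <- stitch_peaks(peaks, cfg)
  rc <- rose_cutoff(enh$score)
  enh$signal <- enh$score
  enh$rank <- rc$rank
  enh$is_super <- rc$is_super
  attr(enh, "cutoff_signal") <- rc$cutoff_signal
  enh
}

#' Split identity domains by super-enhancer overlap
#'
#' A domain is `ID+SE` when it shares at least one base with any
#' super-enhancer, else `ID-SE`. Genes inherit the label of their domains via
#' TSS overlap (a gene with both domain types is `ID+SE`).
#'
#' @param id_domains Interval `data.frame` of identity domains.
#' @param enhancers `data.frame` from [rank_enhancers()] (or any interval
#'   table with an `is_super` column).
#' @param tss Optional TSS `data.frame`; when supplied, per-gene labels are
#'   also returned.
#' @return List with `domains` (`id_domains` plus `se_class` column) and,
#'   when `tss` is given, `genes` (`gene_id`, `se_class`).
#' @export
id_domains_by_se <- function(id_domains, enhancers, tss = NULL) {
  if (!"is_super" %in% names(enhancers))
    stop("enhancers must carry an is_super column")
  se <- enhancers[enhancers$is_super, , drop = FALSE]
  hit <- if (nrow(se)) overlap_any(id_domains, se) else
    rep(FALSE, nrow(id_domains))
  domains <- id_domains
  domains$se_class <- ifelse(hit, "ID+SE", "ID-SE")
  out <- list(domains = domains)
  if (!is.null(tss)) {
    hits <- assign_tss(tss, domains)
    genes <- data.frame(gene_id = names(hits),
                        se_class = vapply(hits, function(i)
                          if (any(domains$se_class[i] == "ID+SE")) "ID+SE"
                          else "ID-SE", ""),
                        stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    out$genes <- genes
  }
  out
}
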