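#' Configuration for identity-gene calling
#'
#' @param broad_multiplier Broadness cutoff: a peak is a broad domain when its
#'   length strictly exceeds `broad_multiplier` times the median peak length of
#'   its tissue. Default 3.
#' @param specificity_threshold A broad domain is tissue-specific (ID) when the
#'   fraction of other tissues sharing it is strictly below this value.
#'   Default 0.25.
#' @return A list with class `identity_config`.
#' @export
identity_config <- function(broad_multiplier = 3, specificity_threshold = 0.25) {
  if (broad_multiplier <= 0) stop("broad_multiplier must be > 0")
  if (specificity_threshold <= 0 || specificity_threshold > 1)
    stop("specificity_threshold must be in (0, 1]")
  structure(list(broad_multiplier = broad_multiplier,
                 specificity_threshold = specificity_threshold),
            class = "identity_config")
}

#' Select broad domains within one tissue
#'
#' A peak is broad when its length is strictly greater than
#' `broad_multiplier` times the median length of all peaks of that tissue
#' (the median of an even count is the mean of the two central values).
#'
#' @param peaks Interval `data.frame` of one tissue's enriched regions.
#' @param cfg An [identity_config()].
#' @return The subset of `peaks` that are broad, input order preserved.
#' @export
select_broad_domains <- function(peaks, cfg = identity_config()) {
  .check_intervals(peaks, "peaks")
  if (nrow(peaks) == 0L) stop("empty peak list")
  len <- peaks$end - peaks$start
  peaks[len > cfg$broad_multiplier * stats::median(len), , drop = FALSE]
}

#' Classify broad domains by cross-tissue sharing
#'
#' For each focal broad domain, the shared fraction is the number of other
#' tissues whose own broad-domain set overlaps it by at least one base,
#' divided by the number of other tissues. Domains with shared fraction
#' strictly below the specificity threshold are labeled `ID`
#' (tissue-specific), the rest `UBQ`.
#'
#' @param focal Interval `data.frame` of the focal tissue's broad domains.
#' @param others Named list of interval `data.frame`s: each other tissue's
#'   broad domains (already reduced to broad domains, not raw peaks).
#' @param cfg An [identity_config()].
#' @return `focal` with added columns `shared_fraction` and `label`.
#' @export
domain_specificity <- function(focal, others, cfg = identity_config()) {
  .check_intervals(focal, "focal")
  if (length(others) == 0L) stop("at least one other tissue is required")
  shared <- rep(0L, nrow(focal))
  for (ot in others) {
    shared <- shared + as.integer(overlap_any(focal, ot))
  }
  out <- focal
  out$shared_fraction <- shared / length(others)
  out$label <- ifelse(out$shared_fraction < cfg$specificity_threshold,
                      "ID", "UBQ")
  out
}

#' Call per-gene identity classes from labeled domains
#'
#' A gene is `ID` when any of its TSS overlaps an ID domain, else `UBQ` when
#' any TSS overlaps a UBQ domain, else `OTHER`. Every gene in the annotation
#' receives exactly one class; ID takes precedence over UBQ.
#'
#' @param domains Labeled domains from [domain_specificity()] (column `label`).
#' @param tss TSS `data.frame` spanning the gene annotation.
#' @return `data.frame` with columns `gene_id`, `klass`, `n_id_domains`,
#'   `n_ubq_domains`, one row per annotated gene.
#' @export
classify_genes <- function(domains, tss) {
  if (!"label" %in% names(domains))
    stop("domains must carry a 'label' column (see domain_specificity)")
  genes <- unique(tss$gene_id)
  hits <- assign_tss(tss, domains)
  n_id <- n_ubq <- stats::setNames(integer(length(genes)), genes)
  for (g in names(hits)) {
    lab <- domains$label[hits[[g]]]
    n_id[g] <- sum(lab == "ID")
    n_ubq[g] <- sum(lab == "UBQ")
  }
  klass <- ifelse(n_id > 0L, "ID", ifelse(n_ubq > 0L, "UBQ", "OTHER"))
  data.frame(gene_id = genes, klass = unname(klass),
             n_id_domains = unname(n_id), n_ubq_domains = unname(n_ubq),
             stringsAsFactors = FALSE)
}

#' Full identity-calling pipeline over a multi-tissue peak collection
#'
#' Reduces every tissue to its broad domains, labels the focal tissue's
#' domains by cross-tissue sharing, and classifies genes by TSS overlap.
#'
#' @param peaks_by_tissue Named list of interval `data.frame`s, one per tissue.
#' @param focal Name of the focal tissue (must be in `names(peaks_by_tissue)`).
#' @param tss TSS `data.frame`.
#' @param cfg An [identity_config()].
#' @return List with `domains` (labeled focal broad domains) and `calls`
#'   (per-gene classes from [classify_genes()]).
#' @export
call_identity <- function(peaks_by_tissue, focal, tss, cfg = identity_config()) {
  if (!focal %in% names(peaks_by_tissue))
    stop("focal tissue '", focal, "' not found")
  broad <- lapply(peaks_by_tissue, select_broad_domains, cfg = cfg)
  domains <- domain_specificity(broad[[focal]],
                                broad[names(broad) != focal], cfg)
  list(domains = domains, calls = classify_genes(domains, tss))
}

#' Tissue-specificity expression index
#'
#' The index of a gene is the mean of its focal-tissue replicates minus the
#' mean over control tissues of the per-tissue replicate means (log2 units on
#' log2-normalized input).
#'
#' @param expr Numeric matrix, genes x samples, log2-normalized.
#' @param tissue Character vector of per-column tissue labels.
#' @param focal Focal tissue label.
#' @return Named numeric vector of per-gene indices.
#' @export
specificity_index <- function(expr, tissue, focal) {
  if (length(tissue) != ncol(expr))
    stop("tissue labels must match columns of expr")
  if (!focal %in% tissue) stop("no replicates labeled '", focal, "'")
  ctrl <- setdiff(unique(tissue), focal)
  if (!length(ctrl)) stop("at least one control tissue is required")
  focal_mean <- rowMeans(expr[, tissue == focal, drop = FALSE])
  ctrl_means <- vapply(ctrl, function(tt)
    rowMeans(expr[, tissue == tt, drop = FALSE]), numeric(nrow(expr)))
  ctrl_means <- matrix(ctrl_means, nrow = nrow(expr))
  focal_mean - rowMeans(ctrl_means)
}
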