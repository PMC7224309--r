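#' Build an enhancer x TF binary occupancy matrix
#'
#' @param enhancers Interval `data.frame`; row `i` gets id `enhancers$name[i]`
#'   when present, else `enh_<i>`.
#' @param cistromes Named list of interval `data.frame`s, one per TF (names
#'   must be unique). `occupancy[e, t]` is 1 iff enhancer `e` overlaps at
#'   least one binding site of TF `t` by one or more bases.
#' @return List of class `binding_matrix` with `enhancers` (the input table),
#'   `tf_names` and the binary `occupancy` matrix.
#' @export
build_binding_matrix <- function(enhancers, cistromes) {
  .check_intervals(enhancers, "enhancers")
  if (!length(cistromes)) stop("at least one TF cistrome is required")
  tf <- names(cistromes)
  if (is.null(tf) || anyDuplicated(tf) || any(!nzchar(tf)))
    stop("cistromes must be uniquely named by TF")
  ids <- if (!is.null(enhancers$name) && !anyNA(enhancers$name))
    enhancers$name else sprintf("enh_%d", seq_len(nrow(enhancers)))
  occ <- vapply(cistromes, function(cs)
    as.integer(overlap_any(enhancers, cs)), integer(nrow(enhancers)))
  occ <- matrix(occ, nrow = nrow(enhancers),
                dimnames = list(ids, tf))
  structure(list(enhancers = enhancers, tf_names = tf, occupancy = occ),
            class = "binding_matrix")
}

#' Enhancer inactivation stratified by co-binding degree
#'
#' Enhancers are first split by whether the focal TF binds them, then by the
#' number of additional TFs bound (degree, excluding the focal TF) into the
#' given strata. Each cell reports the percentage of its enhancers
#' overlapping any DOWN region; an empty stratum yields `NA`, not 0.
#'
#' @param bm A [build_binding_matrix()] result.
#' @param focal_tf Name of the focal TF (must be a column of the matrix).
#' @param down_regions Interval `data.frame` of inactivated (DOWN) regions.
#' @param strata List of inclusive integer ranges `c(lo, hi)` covering
#'   `0..(nTF - 1)` without gaps or overlap; default
#'   `list(c(0,2), c(3,5), c(6,8))`.
#' @return `data.frame` with columns `bound` (focal TF), `stratum`, `n`,
#'   `pct_down`.
#' @export
cobinding_strata_fraction <- function(bm, focal_tf, down_regions,
                                      strata = list(c(0L, 2L), c(3L, 5L),
                                                    c(6L, 8L))) {
  if (!inherits(bm, "binding_matrix")) stop("bm must be a binding_matrix")
  if (!focal_tf %in% bm$tf_names) stop("unknown focal TF: ", focal_tf)
  lo <- vapply(strata, `[[`, 0L, 1L); hi <- vapply(strata, `[[`, 0L, 2L)
  covered <- sort(unlist(Map(seq, lo, hi)))
  need <- 0L:(length(bm$tf_names) - 1L)
  if (anyDuplicated(covered) || !identical(as.integer(covered), need))
    stop("strata must cover 0..", length(bm$tf_names) - 1L,
         " exactly once")
  occ <- bm$occupancy
  bound <- occ[, focal_tf] == 1L
  degree <- rowSums(occ[, setdiff(bm$tf_names, focal_tf), drop = FALSE])
  hit_down <- overlap_any(bm$enhancers, down_regions)
  rows <- list()
  for (b in c(TRUE, FALSE)) for (k in seq_along(strata)) {
    sel <- bound == b & degree >= lo[k] & degree <= hi[k]
    rows[[length(rows) + 1L]] <- data.frame(
      bound = b, stratum = sprintf("%d-%d", lo[k], hi[k]), n = sum(sel),
      pct_down = if (any(sel)) 100 * mean(hit_down[sel]) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cistrome overlap enrichment over a region universe
#'
#' For each target set, builds the 2x2 table (query regions overlapping the
#' set, query not overlapping, rest of the universe overlapping, rest not),
#' tests it with Fisher's exact test, and reports the natural-log odds ratio.
#' When any cell is zero, 0.5 is added to every cell for the log-odds
#' (Haldane correction) — the p-value always comes from the uncorrected
#' table. A query equal to the whole universe (or empty) offers no contrast
#' and reports log-odds 0.
#'
#' @param query Either integer/logical indices into `universe`, or an
#'   interval `data.frame` whose rows match universe rows by exact
#'   chrom/start/end.
#' @param target_sets Named list of interval `data.frame`s (e.g. cistromes).
#' @param universe Interval `data.frame` of all tested regions; `query` must
#'   be a subset of it.
#' @return `data.frame` with one row per target set: `set`, `log_odds`, `p`,
#'   `q` (BH over sets) and the four table cells.
#' @export
overlap_enrichment <- function(query, target_sets, universe) {
  .check_intervals(universe, "universe")
  if (nrow(universe) == 0L) stop("empty universe")
  if (is.data.frame(query)) {
    key_u <- paste(universe$chrom, universe$start, universe$end)
    key_q <- paste(query$chrom, query$start, query$end)
    idx <- match(key_q, key_u)
    if (anyNA(idx)) stop("query regions must be rows of the universe")
    in_query <- seq_len(nrow(universe)) %in% idx
  } else if (is.logical(query)) {
    if (length(query) != nrow(universe))
      stop("logical query must match universe length")
    in_query <- query
  } else {
    in_query <- seq_len(nrow(universe)) %in% as.integer(query)
  }
  if (!length(target_sets) || is.null(names(target_sets)))
    stop("target_sets must be a named list")
  rows <- lapply(names(target_sets), function(nm) {
    hit <- overlap_any(universe, target_sets[[nm]])
    a <- sum(in_query & hit);  b <- sum(in_query & !hit)
    c_ <- sum(!in_query & hit); d <- sum(!in_query & !hit)
    tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    if (all(in_query) || !any(in_query)) {
      lo <- 0  # degenerate split: no contrast between query and rest
    } else {
      cells <- c(a, b, c_, d)
      if (any(cells == 0)) cells <- cells + 0.5
      lo <- log(cells[1L] * cells[4L] / (cells[2L] * cells[3L]))
    }
    data.frame(set = nm, log_odds = lo, p = p, n_query_hit = a,
               n_query_miss = b, n_rest_hit = c_, n_rest_miss = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of an enrichment matrix
#'
#' Clusters rows with Euclidean distance and Ward linkage on squared
#' distances (`ward.D2`), the standard choice for log-odds enrichment
#' heatmaps. Missing values are imputed to 0 with a warning. Deterministic
#' given input order.
#'
#' @param m Numeric matrix of log-odds (rows = sets, columns = classes).
#' @param k Number of flat clusters to cut (default 2).
#' @return List with `hclust` (the merge tree), `order` (dendrogram order)
#'   and `clusters` (named integer labels at the `k` cut).
#' @export
cluster_enrichment <- function(m, k = 2L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (anyNA(m)) {
    warning("missing log-odds imputed to 0")
    m[is.na(m)] <- 0
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  list(hclust = hc, order = hc$order,
       clusters = stats::cutree(hc, k = min(k, nrow(m))))
}
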