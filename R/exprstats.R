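#' Median-of-ratios size factors
#'
#' The size factor of sample `j` is the median, over genes with a positive
#' geometric mean across samples, of `counts[g, j] / geomean(counts[g, ])`.
#'
#' @param counts Non-negative numeric matrix, genes x samples.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene has positive counts in all samples")
  apply(counts[use, , drop = FALSE], 2L, function(cnts)
    stats::median(exp(log(cnts) - log_geo[use])))
}

#' Baseline filter, global z-scaling and scaled fold changes
#'
#' Reproduces the comparable-fold-change construction: (1) drop the
#' `drop_fraction` of genes with lowest mean expression in the baseline
#' condition (ties broken by gene id order; the number dropped is
#' `floor(drop_fraction * n)`); (2) z-scale the whole retained matrix with
#' its global mean and global standard deviation over all values of all
#' conditions; (3) per gene, the scaled fold change is the mean of scaled
#' perturbed values minus the mean of scaled baseline values.
#'
#' @param expr Numeric matrix, genes x samples (log2-normalized), with
#'   rownames as gene ids.
#' @param condition Character vector of per-column condition labels.
#' @param baseline_cond Baseline (control) condition label.
#' @param perturbed_cond Perturbed condition label; defaults to the single
#'   non-baseline condition (error if ambiguous).
#' @param drop_fraction Fraction of genes to discard by low baseline
#'   expression, in `[0, 1)`; default 0.2.
#' @return `data.frame` (the FC table) with columns `gene_id`, `baseline`
#'   (baseline mean on the input scale), `raw_fc`, `scaled_fc`, plus
#'   attributes `global_mean` and `global_sd`.
#' @export
scale_and_fc <- function(expr, condition, baseline_cond,
                         perturbed_cond = NULL, drop_fraction = 0.2) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene ids as rownames")
  if (length(condition) != ncol(expr))
    stop("condition labels must match columns")
  if (!baseline_cond %in% condition) stop("baseline condition absent")
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  if (is.null(perturbed_cond)) {
    others <- setdiff(unique(condition), baseline_cond)
    if (length(others) != 1L)
      stop("perturbed_cond must be given when more than two conditions exist")
    perturbed_cond <- others
  }
  base_mean <- rowMeans(expr[, condition == baseline_cond, drop = FALSE])
  ord <- order(base_mean, rownames(expr))
  n_drop <- floor(drop_fraction * nrow(expr))
  keep <- sort(ord[seq.int(n_drop + 1L, nrow(expr))])
  m <- expr[keep, , drop = FALSE]
  mu <- mean(m)
  sdv <- stats::sd(as.vector(m))
  if (sdv == 0) stop("zero global standard deviation")
  z <- (m - mu) / sdv
  pert <- rowMeans(z[, condition == perturbed_cond, drop = FALSE])
  base <- rowMeans(z[, condition == baseline_cond, drop = FALSE])
  raw <- rowMeans(expr[keep, condition == perturbed_cond, drop = FALSE]) -
    rowMeans(expr[keep, condition == baseline_cond, drop = FALSE])
  out <- data.frame(gene_id = rownames(m), baseline = base_mean[keep],
                    raw_fc = unname(raw), scaled_fc = unname(pert - base),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "global_mean") <- mu
  attr(out, "global_sd") <- sdv
  out
}

#' Identity-gene enrichment across repression quartiles
#'
#' Repressed genes are ranked by increasing repression (most negative fold
#' change last) and split into four near-equal quartiles — remainder genes go
#' to the earlier quartiles — so Q4 holds the most repressed genes. Reports
#' the fraction of `ID` genes per quartile relative to Q1 (set to 1), with a
#' per-quartile chi-square test against Q1 and BH correction.
#'
#' @param fc FC table (from [scale_and_fc()]) restricted to repressed genes;
#'   the ranking uses `scaled_fc`.
#' @param calls Identity calls from [classify_genes()].
#' @param id_class Class counted as identity genes; default `"ID"`.
#' @return `data.frame` with one row per quartile: `quartile`, `n`, `n_id`,
#'   `id_fraction`, `rel_fraction` (NA with attribute `q1_zero = TRUE` when
#'   Q1 has no ID genes), `p`, `q` (Q1 rows get NA p/q).
#' @export
quartile_enrichment <- function(fc, calls, id_class = "ID") {
  if (nrow(fc) < 4L) stop("need at least 4 repressed genes")
  klass <- stats::setNames(calls$klass, calls$gene_id)
  is_id <- unname(klass[fc$gene_id]) == id_class
  is_id[is.na(is_id)] <- FALSE
  ord <- order(fc$scaled_fc, decreasing = TRUE)   # Q1 mildest, Q4 deepest
  n <- nrow(fc)
  base <- n %/% 4L; rem <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, rem), rep(0L, 4L - rem))
  qlab <- rep.int(paste0("Q", 1:4), sizes)
  quart <- character(n); quart[ord] <- qlab
  rows <- lapply(1:4, function(k) {
    sel <- quart == paste0("Q", k)
    data.frame(quartile = paste0("Q", k), n = sum(sel),
               n_id = sum(is_id[sel]), id_fraction = mean(is_id[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  q1 <- out$id_fraction[1L]
  q1_zero <- q1 == 0
  out$rel_fraction <- if (q1_zero) NA_real_ else out$id_fraction / q1
  out$p <- NA_real_
  for (k in 2:4) {
    tab <- matrix(c(out$n_id[k], out$n[k] - out$n_id[k],
                    out$n_id[1L], out$n[1L] - out$n_id[1L]), 2L)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    out$p[k] <- if (is.finite(p)) p else NA_real_
  }
  out$q <- c(NA_real_, stats::p.adjust(out$p[2:4], method = "BH"))
  attr(out, "q1_zero") <- q1_zero
  rownames(out) <- NULL
  out
}

#' Weighted gene-set enrichment score
#'
#' The running sum walks down the ranked gene list, incrementing by
#' `|score|^weight / sum(|score|^weight over hits)` at gene-set members and
#' decrementing by `1 / (N - m)` at non-members; the enrichment score is the
#' signed extremum. With `weight = 0` this is the classic Kolmogorov-Smirnov
#' statistic. The normalized score and FDR come from gene-set permutations:
#' `NES = ES / mean(|permuted ES of the same sign|)` and the FDR is the
#' fraction of same-sign permuted normalized scores at least as extreme.
#'
#' @param genes Character vector of gene ids, ordered by the ranking metric
#'   (best first).
#' @param scores Numeric ranking-metric values aligned with `genes`.
#' @param gene_set Character vector of member gene ids; must intersect
#'   `genes` and must not cover the whole list.
#' @param weight Exponent on `|score|`; default 1 ("weighted").
#' @param n_perm Number of gene-set permutations for NES/FDR (default 1000;
#'   0 skips them).
#' @param seed Optional integer seed for the permutations.
#' @return List of class `gsea_result`: `es`, `nes`, `fdr`, `running_sum`,
#'   `hit_indices`.
#' @export
gsea_es <- function(genes, scores, gene_set, weight = 1, n_perm = 1000L,
                    seed = NULL) {
  if (length(genes) != length(scores)) stop("genes and scores must align")
  hit <- genes %in% gene_set
  m <- sum(hit); N <- length(genes)
  if (m == 0L) stop("gene_set does not intersect the ranked list")
  if (m == N) stop("gene_set covers the whole ranked list")
  running_of <- function(hit) {
    w <- abs(scores[hit])^weight
    inc <- numeric(N)
    inc[hit] <- if (sum(w) == 0) 1 / sum(hit) else w / sum(w)
    inc[!hit] <- -1 / (N - sum(hit))
    cumsum(inc)
  }
  es_of <- function(hit) {
    rs <- running_of(hit)
    rs[which.max(abs(rs))]
  }
  running <- running_of(hit)
  es <- running[which.max(abs(running))]
  nes <- fdr <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    perm <- vapply(seq_len(n_perm), function(i) {
      h <- logical(N); h[sample.int(N, m)] <- TRUE
      es_of(h)
    }, 0)
    same <- perm[sign(perm) == sign(es)]
    if (length(same)) {
      denom <- mean(abs(same))
      nes <- es / denom
      nperm_norm <- same / denom
      fdr <- mean(abs(nperm_norm) >= abs(nes))
    }
  }
  structure(list(es = es, nes = nes, fdr = fdr, running_sum = running,
                 hit_indices = which(hit)), class = "gsea_result")
}

#' Rank genes by difference of condition means
#'
#' Helper producing the "difference of classes" ranking metric: per gene,
#' mean expression in the perturbed condition minus mean in the baseline.
#'
#' @param expr Numeric matrix, genes x samples, rownames as gene ids.
#' @param condition Per-column condition labels.
#' @param baseline_cond,perturbed_cond Condition labels.
#' @return List with `genes` (ids ordered by decreasing metric) and `scores`
#'   (matching metric values), ready for [gsea_es()].
#' @export
rank_by_class_difference <- function(expr, condition, baseline_cond,
                                     perturbed_cond) {
  d <- rowMeans(expr[, condition == perturbed_cond, drop = FALSE]) -
    rowMeans(expr[, condition == baseline_cond, drop = FALSE])
  ord <- order(d, decreasing = TRUE)
  list(genes = rownames(expr)[ord], scores = unname(d[ord]))
}

#' Per-cell gene-set score
#'
#' Mean normalized expression of the set genes in each cell.
#'
#' @param norm_expr Numeric matrix, genes x cells, rownames as gene ids.
#' @param gene_set Character vector of gene ids present in the matrix.
#' @return Numeric vector of per-cell scores.
#' @export
gene_set_score <- function(norm_expr, gene_set) {
  if (!length(gene_set)) stop("empty gene set")
  missing <- setdiff(gene_set, rownames(norm_expr))
  if (length(missing))
    stop("gene set members absent from matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  colMeans(norm_expr[gene_set, , drop = FALSE])
}
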