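#' Bundle expression studies with batch and condition labels
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene ids,
#'   colnames = sample ids).
#' @param batch Per-sample batch (study) labels.
#' @param condition Per-sample condition labels.
#' @param reference_batch Batch used as the developmental reference.
#' @param anchor Named character vector mapping every batch to the condition
#'   treated as equivalent to the reference's mature (adult) stage — e.g. the
#'   non-injured controls of each injury study and the adult stage of the
#'   reference itself.
#' @return List of class `batched_expression`.
#' @export
batched_expression <- function(expr, batch, condition, reference_batch,
                               anchor) {
  expr <- as.matrix(expr)
  if (length(batch) != ncol(expr) || length(condition) != ncol(expr))
    stop("batch and condition must label every column")
  if (!reference_batch %in% batch) stop("reference batch absent")
  for (b in unique(batch)) {
    if (!b %in% names(anchor)) stop("no anchor condition for batch ", b)
    if (!any(batch == b & condition == anchor[[b]]))
      stop("batch ", b, " has no sample in its anchor condition")
  }
  structure(list(expr = expr, batch = batch, condition = condition,
                 reference_batch = reference_batch, anchor = anchor),
            class = "batched_expression")
}

#' Location-only, anchor-referenced batch alignment
#'
#' Per gene, every non-reference batch is shifted by a constant so that the
#' mean of its anchor-condition samples matches the mean of the reference
#' batch's anchor-stage samples; the reference batch is returned unchanged.
#' Optional empirical-Bayes shrinkage pulls each gene's shift toward the
#' batch-wide mean shift with a normal prior whose weight comes from
#' method-of-moments hyperparameters (off by default).
#'
#' @param be A [batched_expression()].
#' @param eb_shrink Shrink per-gene shifts toward the batch mean shift?
#'   Default `FALSE`.
#' @return Corrected matrix, same shape as `be$expr`.
#' @export
align_batches <- function(be, eb_shrink = FALSE) {
  if (!inherits(be, "batched_expression"))
    stop("be must be a batched_expression")
  expr <- be$expr
  ref <- be$reference_batch
  ref_anchor <- be$batch == ref & be$condition == be$anchor[[ref]]
  ref_mean <- rowMeans(expr[, ref_anchor, drop = FALSE])
  out <- expr
  for (b in setdiff(unique(be$batch), ref)) {
    anchor_cols <- be$batch == b & be$condition == be$anchor[[b]]
    shift <- rowMeans(expr[, anchor_cols, drop = FALSE]) - ref_mean
    if (eb_shrink) {
      mu <- mean(shift)
      s2_tot <- stats::var(shift)
      ## within-gene sampling variance of the anchor-mean difference,
      ## pooled across genes; prior variance by method of moments
      n_a <- sum(anchor_cols); n_r <- sum(ref_anchor)
      resid_var <- mean(apply(expr[, anchor_cols, drop = FALSE], 1L,
                              stats::var))
      if (is.na(resid_var)) resid_var <- 0
      samp_var <- resid_var / n_a + resid_var / n_r
      tau2 <- max(s2_tot - samp_var, 0)
      w <- if (tau2 + samp_var > 0) tau2 / (tau2 + samp_var) else 1
      shift <- mu + w * (shift - mu)
    }
    out[, be$batch == b] <- expr[, be$batch == b, drop = FALSE] - shift
  }
  out
}

#' Fit a developmental axis and project supplementary samples
#'
#' A principal-component analysis is fitted on the reference-batch samples
#' only, in covariance form (genes centered by reference means, no
#' unit-variance scaling). Non-reference samples are supplementary
#' individuals: centered by the reference gene means and projected onto the
#' first component. The axis is oriented so that the reference batch's
#' anchor-stage (adult) samples have a positive mean coordinate.
#'
#' @param corrected Corrected matrix from [align_batches()].
#' @param be The [batched_expression()] the matrix came from.
#' @return List of class `dev_projection`: `pc1_loadings` (unit-norm,
#'   per gene), `pc1_var_fraction`, and `coords` — a `data.frame` with
#'   `sample`, `batch`, `condition`, `pc1_coord`.
#' @export
fit_project <- function(corrected, be) {
  if (!inherits(be, "batched_expression"))
    stop("be must be a batched_expression")
  ref_cols <- be$batch == be$reference_batch
  if (sum(ref_cols) < 3L) stop("reference batch needs at least 3 samples")
  X <- t(corrected[, ref_cols, drop = FALSE])      # samples x genes
  if (nrow(unique(X)) < 2L) stop("reference samples are all identical")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  ## eigen on the small samples x samples cross-product, then lift loadings
  ## back to gene space (genes typically outnumber samples)
  K <- tcrossprod(Xc)
  ei <- eigen(K, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  if (ev[1L] <= 0) stop("reference batch has zero variance")
  v <- crossprod(Xc, ei$vectors[, 1L])
  v <- v / sqrt(sum(v^2))
  var_frac <- ev[1L] / sum(ev)
  all_c <- sweep(t(corrected), 2L, ctr)
  coord <- as.numeric(all_c %*% v)
  adult <- ref_cols & be$condition == be$anchor[[be$reference_batch]]
  if (mean(coord[adult]) < 0) { v <- -v; coord <- -coord }
  coords <- data.frame(
    sample = colnames(corrected), batch = be$batch,
    condition = be$condition, pc1_coord = coord, stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  structure(list(pc1_loadings = stats::setNames(as.vector(v),
                                                rownames(corrected)),
                 pc1_var_fraction = var_frac, coords = coords),
            class = "dev_projection")
}
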