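#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions every generator emulates: a multi-tissue
#' peak landscape with planted identity and ubiquitous broad domains, bin
#' tables with planted UP/DOWN regions, cistromes whose co-binding degree
#' drives inactivation through a logistic link, and expression matrices with
#' a maturation trajectory, planted identity-gene repression, batch offsets
#' and Poisson single-cell counts. All generators are pure functions of this
#' configuration: the same seed yields byte-identical output.
#'
#' @param seed Integer seed.
#' @param n_tissues Number of tissues (1 focal + others); default 10.
#' @param n_genes Number of annotated genes; default 2000.
#' @param n_id_genes Planted identity genes (broad domain in the focal tissue
#'   only); default 200.
#' @param n_ubq_genes Planted ubiquitous genes (broad domain in every
#'   tissue); default 200.
#' @param n_peaks_per_tissue Background peaks per tissue (also the number of
#'   peaks in generated bin tables); default 1000.
#' @param broad_length_factor Planted domain length as a multiple of the
#'   background median peak length (500 bp); default 5.
#' @param n_bins_per_peak Bins tiling each peak; default 10.
#' @param effect_size Planted |log2 fold change| for UP/DOWN bins and for
#'   identity-gene repression; default 1.
#' @param noise_sd Standard deviation of bin-level log2 fold changes;
#'   default 0.4.
#' @param frac_up_peaks,frac_down_peaks Fractions of peaks planted UP / DOWN
#'   in bin tables; default 0.1 each.
#' @param n_tfs Number of TFs in generated cistromes; default 9.
#' @param n_enhancers Enhancers receiving TF sites; default 600.
#' @param cobind_logistic_slope Slope of the logistic link from the number of
#'   bound TFs to the inactivation probability; default 0.8.
#' @param n_stages Developmental reference stages (newborn to adult);
#'   default 6.
#' @param n_reps Replicates per stage / condition in expression studies;
#'   default 3.
#' @param dediff_weight Default convex-mixing weight of the newborn profile
#'   in dedifferentiated samples; default 0.5.
#' @param expr_noise_sd Residual SD of expression values (log2 units);
#'   default 0.3.
#' @param n_cells Single cells in the Poisson count matrix; default 300.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_tissues = 10L, n_genes = 2000L,
                         n_id_genes = 200L, n_ubq_genes = 200L,
                         n_peaks_per_tissue = 1000L,
                         broad_length_factor = 5, n_bins_per_peak = 10L,
                         effect_size = 1, noise_sd = 0.4,
                         frac_up_peaks = 0.1, frac_down_peaks = 0.1,
                         n_tfs = 9L, n_enhancers = 600L,
                         cobind_logistic_slope = 0.8, n_stages = 6L,
                         n_reps = 3L, dediff_weight = 0.5,
                         expr_noise_sd = 0.3, n_cells = 300L) {
  cfg <- list(seed = as.integer(seed), n_tissues = as.integer(n_tissues),
              n_genes = as.integer(n_genes),
              n_id_genes = as.integer(n_id_genes),
              n_ubq_genes = as.integer(n_ubq_genes),
              n_peaks_per_tissue = as.integer(n_peaks_per_tissue),
              broad_length_factor = broad_length_factor,
              n_bins_per_peak = as.integer(n_bins_per_peak),
              effect_size = effect_size, noise_sd = noise_sd,
              frac_up_peaks = frac_up_peaks,
              frac_down_peaks = frac_down_peaks,
              n_tfs = as.integer(n_tfs),
              n_enhancers = as.integer(n_enhancers),
              cobind_logistic_slope = cobind_logistic_slope,
              n_stages = as.integer(n_stages), n_reps = as.integer(n_reps),
              dediff_weight = dediff_weight,
              expr_noise_sd = expr_noise_sd, n_cells = as.integer(n_cells))
  counts <- c("n_tissues", "n_genes", "n_id_genes", "n_ubq_genes",
              "n_peaks_per_tissue", "n_bins_per_peak", "n_tfs",
              "n_enhancers", "n_stages", "n_reps", "n_cells")
  if (any(unlist(cfg[counts]) <= 0)) stop("all counts must be positive")
  if (cfg$n_id_genes + cfg$n_ubq_genes > cfg$n_genes)
    stop("n_id_genes + n_ubq_genes exceeds n_genes")
  if (cfg$dediff_weight < 0 || cfg$dediff_weight > 1)
    stop("dediff_weight must be in [0, 1]")
  structure(cfg, class = "synth_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

.synth_genes <- function(cfg) {
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  list(genes = genes,
       id_genes = genes[seq_len(cfg$n_id_genes)],
       ubq_genes = genes[cfg$n_id_genes + seq_len(cfg$n_ubq_genes)])
}

#' Generate multi-tissue peak sets with planted broad domains
#'
#' Background peaks have lognormal lengths (median 500 bp) at uniform
#' positions. Identity genes carry a planted broad domain (length
#' `broad_length_factor` x 500) over their TSS in the focal tissue only;
#' ubiquitous genes carry one in every tissue. Gene TSS sit 20 kb apart on a
#' single chromosome so planted domains never collide.
#'
#' @param cfg A [synth_config()].
#' @return List with `peaks` (named list of interval tables, focal tissue
#'   `"liver"` first), `tss` (annotation table), `truth` (`gene_id`,
#'   `klass`).
#' @export
gen_tissue_peaks <- function(cfg = synth_config()) {
  g <- .synth_genes(cfg)
  tss_pos <- 10000L + (seq_len(cfg$n_genes) - 1L) * 20000L
  span <- max(tss_pos) + 20000L
  tss <- data.frame(gene_id = g$genes, chrom = "chr1", position = tss_pos,
                    strand = rep_len(c("+", "-"), cfg$n_genes),
                    stringsAsFactors = FALSE)
  tissues <- c("liver", sprintf("tissue_%02d", seq_len(cfg$n_tissues - 1L)))
  broad_len <- as.integer(round(cfg$broad_length_factor * 500))
  .with_seed(cfg$seed * 13L + 1L, {
    plant <- function(gene_ids) {
      pos <- tss_pos[match(gene_ids, g$genes)]
      off <- sample.int(broad_len - 200L, length(pos), replace = TRUE)
      start <- pmax(pos - off, 0L)
      genomic_intervals("chr1", start, start + broad_len, name = gene_ids)
    }
    peaks <- lapply(tissues, function(tt) {
      n_bg <- cfg$n_peaks_per_tissue
      len <- pmax(as.integer(round(stats::rlnorm(n_bg, log(500), 0.3))), 50L)
      start <- as.integer(floor(stats::runif(n_bg, 0, span - max(len))))
      bg <- genomic_intervals("chr1", start, start + len)
      planted <- if (tt == "liver") plant(c(g$id_genes, g$ubq_genes))
        else plant(g$ubq_genes)
      rbind(bg, planted)
    })
    names(peaks) <- tissues
    truth <- data.frame(
      gene_id = g$genes,
      klass = c(rep("ID", cfg$n_id_genes), rep("UBQ", cfg$n_ubq_genes),
                rep("OTHER", cfg$n_genes - cfg$n_id_genes - cfg$n_ubq_genes)),
      stringsAsFactors = FALSE)
    list(peaks = peaks, tss = tss, truth = truth)
  })
}

#' Generate a bin-level differential table with planted regions
#'
#' Peaks (non-overlapping, tiled by `n_bins_per_peak` 150-bp bins) are
#' assigned a truth direction: a `frac_up_peaks` fraction UP, a
#' `frac_down_peaks` fraction DOWN, the rest null. Bin log2 fold changes are
#' `Normal(+-effect_size, noise_sd)` for planted peaks and
#' `Normal(0, noise_sd)` for null peaks, with two-sided z-test p-values
#' (known SD). `all_null = TRUE` forces every peak null (calibration runs).
#'
#' @param cfg A [synth_config()].
#' @param all_null Plant nothing; default `FALSE`.
#' @return List with `bins` (`chrom`, `start`, `end`, `log2fc`, `pvalue`),
#'   `peaks` (with `name` ids) and `truth` (`peak_id`, `direction`).
#' @export
gen_bins <- function(cfg = synth_config(), all_null = FALSE) {
  n_peaks <- cfg$n_peaks_per_tissue
  bin_w <- 150L
  peak_w <- bin_w * cfg$n_bins_per_peak
  start <- (seq_len(n_peaks) - 1L) * (peak_w + 5000L)
  peaks <- genomic_intervals("chr1", start, start + peak_w,
                             name = sprintf("peak_%04d", seq_len(n_peaks)))
  .with_seed(cfg$seed * 13L + 2L, {
    dir <- rep("NULL", n_peaks)
    if (!all_null) {
      n_up <- floor(cfg$frac_up_peaks * n_peaks)
      n_down <- floor(cfg$frac_down_peaks * n_peaks)
      planted <- sample.int(n_peaks, n_up + n_down)
      dir[planted[seq_len(n_up)]] <- "UP"
      dir[planted[n_up + seq_len(n_down)]] <- "DOWN"
    }
    mu <- rep(ifelse(dir == "UP", cfg$effect_size,
                     ifelse(dir == "DOWN", -cfg$effect_size, 0)),
              each = cfg$n_bins_per_peak)
    n_bins <- n_peaks * cfg$n_bins_per_peak
    off <- (seq_len(cfg$n_bins_per_peak) - 1L) * bin_w
    bstart <- rep(start, each = cfg$n_bins_per_peak) +
      rep(off, times = n_peaks)
    log2fc <- stats::rnorm(n_bins, mu, cfg$noise_sd)
    pval <- 2 * stats::pnorm(-abs(log2fc) / cfg$noise_sd)
    bins <- data.frame(chrom = "chr1", start = bstart, end = bstart + bin_w,
                       log2fc = log2fc, pvalue = pval,
                       stringsAsFactors = FALSE)
    list(bins = bins, peaks = peaks,
         truth = data.frame(peak_id = peaks$name, direction = dir,
                            stringsAsFactors = FALSE))
  })
}

#' Generate TF cistromes with degree-linked inactivation
#'
#' Each enhancer is bound by the focal TF (`TF1`) with probability 0.5 and by
#' a uniformly drawn number of additional TFs. The probability that an
#' enhancer belongs to the inactivated (DOWN) set is logistic in the total
#' number of bound TFs: `plogis(-3 + cobind_logistic_slope * n_bound)`.
#'
#' @param cfg A [synth_config()].
#' @param enhancers Optional interval table; by default `n_enhancers`
#'   1-kb enhancers spaced 5 kb apart are created.
#' @return List with `cistromes` (named list of per-TF site tables),
#'   `enhancers`, `down_regions` and `truth` (`enhancer`, `bound_focal`,
#'   `degree`, `down`).
#' @export
gen_cistromes <- function(cfg = synth_config(), enhancers = NULL) {
  if (is.null(enhancers)) {
    start <- (seq_len(cfg$n_enhancers) - 1L) * 6000L
    enhancers <- genomic_intervals("chr1", start, start + 1000L,
                                   name = sprintf("enh_%04d",
                                                  seq_len(cfg$n_enhancers)))
  }
  n <- nrow(enhancers)
  tfs <- sprintf("TF%d", seq_len(cfg$n_tfs))
  .with_seed(cfg$seed * 13L + 3L, {
    bound_focal <- stats::runif(n) < 0.5
    degree <- sample.int(cfg$n_tfs, n, replace = TRUE) - 1L  # 0..n_tfs-1
    degree <- pmin(degree, cfg$n_tfs - 1L)
    occ <- matrix(FALSE, n, cfg$n_tfs, dimnames = list(enhancers$name, tfs))
    occ[, 1L] <- bound_focal
    for (i in seq_len(n)) {
      if (degree[i] > 0L)
        occ[i, 1L + sample.int(cfg$n_tfs - 1L, degree[i])] <- TRUE
    }
    n_bound <- rowSums(occ)
    p_down <- stats::plogis(-3 + cfg$cobind_logistic_slope * n_bound)
    down <- stats::runif(n) < p_down
    mid <- (enhancers$start + enhancers$end) %/% 2L
    cistromes <- lapply(tfs, function(tf) {
      sel <- which(occ[, tf])
      genomic_intervals(enhancers$chrom[sel], mid[sel] - 100L,
                        mid[sel] + 100L)
    })
    names(cistromes) <- tfs
    list(cistromes = cistromes, enhancers = enhancers,
         down_regions = enhancers[down, , drop = FALSE],
         truth = data.frame(enhancer = enhancers$name,
                            bound_focal = bound_focal, degree = degree,
                            n_bound = n_bound, down = down,
                            stringsAsFactors = FALSE))
  })
}

#' Generate developmental, perturbation and single-cell expression data
#'
#' Adult baselines are `Normal(8, 2)` (log2 units). Identity genes carry a
#' positive maturation loading (uniform on 2..4) so their expression rises
#' from newborn to adult; stage profiles interpolate linearly along that
#' loading. The perturbation study is adult plus a per-gene batch offset,
#' with identity genes repressed by `effect_size` in the treated condition.
#' Injury samples are convex mixes of newborn and adult profiles (weight =
#' newborn share) plus their own batch offset. Single-cell counts are
#' Poisson with per-cell maturation times and lognormal size factors.
#'
#' @param cfg A [synth_config()].
#' @param dediff_weights Newborn-mixture weights of the injury samples;
#'   default `cfg$dediff_weight`.
#' @return List with `genes`, `id_genes`, `ubq_genes`, `reference`
#'   (`expr`, `stage`, `time`), `perturbation` (`expr`, `condition`),
#'   `injury` (`expr`, `weight`, `condition`), and `sc` (`counts`, `time`).
#' @export
gen_expression <- function(cfg = synth_config(),
                           dediff_weights = cfg$dediff_weight) {
  g <- .synth_genes(cfg)
  is_id <- g$genes %in% g$id_genes
  .with_seed(cfg$seed * 13L + 4L, {
    mu <- stats::rnorm(cfg$n_genes, 8, 2)
    load <- ifelse(is_id, stats::runif(cfg$n_genes, 2, 4),
                   stats::rnorm(cfg$n_genes, 0, 0.3))
    profile <- function(t) mu - (1 - t) * load
    noise <- function(k) matrix(stats::rnorm(cfg$n_genes * k, 0,
                                             cfg$expr_noise_sd),
                                cfg$n_genes, k)
    ## developmental reference
    t_s <- seq(0, 1, length.out = cfg$n_stages)
    ref <- do.call(cbind, lapply(t_s, function(t)
      profile(t) + noise(cfg$n_reps)))
    stage <- rep(sprintf("stage_%d", seq_len(cfg$n_stages)),
                 each = cfg$n_reps)
    stage[stage == sprintf("stage_%d", cfg$n_stages)] <- "adult"
    stage[stage == "stage_1"] <- "newborn"
    colnames(ref) <- sprintf("dev_%02d", seq_len(ncol(ref)))
    rownames(ref) <- g$genes
    ## perturbation study (identity-gene repression + batch offset)
    off_p <- stats::rnorm(cfg$n_genes, 0, 1)
    ctrl <- profile(1) + off_p + noise(cfg$n_reps)
    trt <- profile(1) - cfg$effect_size * is_id + off_p + noise(cfg$n_reps)
    pert <- cbind(ctrl, trt)
    colnames(pert) <- c(sprintf("ctrl_%d", seq_len(cfg$n_reps)),
                        sprintf("ers_%d", seq_len(cfg$n_reps)))
    rownames(pert) <- g$genes
    ## injury study: partially dedifferentiated samples
    off_i <- stats::rnorm(cfg$n_genes, 0, 1)
    inj <- do.call(cbind, lapply(dediff_weights, function(w)
      (w * profile(0) + (1 - w) * profile(1)) + off_i + noise(cfg$n_reps)))
    w_lab <- rep(dediff_weights, each = cfg$n_reps)
    colnames(inj) <- sprintf("inj_w%03d_%d", round(100 * w_lab),
                             rep(seq_len(cfg$n_reps),
                                 times = length(dediff_weights)))
    rownames(inj) <- g$genes
    inj_cond <- ifelse(w_lab == 0, "control", sprintf("w%.2f", w_lab))
    ## single cells along the maturation trajectory
    t_c <- stats::runif(cfg$n_cells)
    sf <- stats::rlnorm(cfg$n_cells, 0, 0.3)
    P <- vapply(t_c, profile, numeric(cfg$n_genes))
    lam <- sweep(exp(P * log(2) / 2), 2L, sf, "*")
    counts <- matrix(stats::rpois(length(lam), lam), cfg$n_genes,
                     cfg$n_cells,
                     dimnames = list(g$genes,
                                     sprintf("cell_%03d",
                                             seq_len(cfg$n_cells))))
    list(genes = g$genes, id_genes = g$id_genes, ubq_genes = g$ubq_genes,
         reference = list(expr = ref, stage = stage,
                          time = rep(t_s, each = cfg$n_reps)),
         perturbation = list(expr = pert,
                             condition = rep(c("control", "ers"),
                                             each = cfg$n_reps)),
         injury = list(expr = inj, weight = w_lab, condition = inj_cond),
         sc = list(counts = counts, time = t_c))
  })
}
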