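toy_batches <- function(delta = 2, n_genes = 30, seed = 4) {
  set.seed(seed)
  ref <- matrix(rnorm(n_genes * 6, 8), n_genes, 6,
                dimnames = list(sprintf("g%02d", 1:n_genes),
                                sprintf("r%d", 1:6)))
  inj <- ref[, 1:4] + delta
  colnames(inj) <- sprintf("i%d", 1:4)
  expr <- cbind(ref, inj)
  batched_expression(
    expr,
    batch = c(rep("dev", 6), rep("inj", 4)),
    condition = c(rep(c("newborn", "mid", "adult"), each = 2),
                  rep(c("control", "hurt"), each = 2)),
    reference_batch = "dev",
    anchor = c(dev = "adult", inj = "control"))
}

test_that("anchored mean alignment removes a constant batch offset and
           leaves the reference untouched", {
  be <- toy_batches(delta = 3.2)
  corr <- align_batches(be)
  expect_identical(corr[, be$batch == "dev"],
                   be$expr[, be$batch == "dev"])
  ref_anchor <- rowMeans(corr[, be$condition == "adult"])
  inj_anchor <- rowMeans(corr[, be$condition == "control"])
  expect_equal(unname(inj_anchor - ref_anchor), rep(0, 30),
               tolerance = 1e-12)
})

test_that("EB shrinkage pulls per-gene shifts between the raw shift and the
           batch mean shift", {
  set.seed(9)
  be <- toy_batches()
  # make shifts heterogeneous
  be$expr[, be$batch == "inj"] <- be$expr[, be$batch == "inj"] +
    rnorm(30, 0, 1.5)
  plain <- align_batches(be)
  shrunk <- align_batches(be, eb_shrink = TRUE)
  inj <- be$batch == "inj"
  d_plain <- be$expr[, inj] - plain[, inj]    # per-gene applied shift
  d_shrunk <- be$expr[, inj] - shrunk[, inj]
  s_plain <- d_plain[, 1]; s_shrunk <- d_shrunk[, 1]
  mu <- mean(s_plain)
  between <- (s_shrunk - pmin(s_plain, mu) >= -1e-9) &
    (pmax(s_plain, mu) - s_shrunk >= -1e-9)
  expect_true(all(between))
})

test_that("a batch without anchor samples is rejected", {
  be <- toy_batches()
  expect_error(batched_expression(be$expr, be$batch, be$condition, "dev",
                                  anchor = c(dev = "adult", inj = "nope")),
               "anchor condition")
})

test_that("PCA on the reference captures a rank-1 trajectory and projects a
           duplicated sample to the same coordinate", {
  g <- 20
  v <- seq_len(g) / g
  ref <- sapply(c(0, 0.5, 1, 1.5), function(t) 5 + t * v)
  expr <- cbind(ref, ref[, 2])
  rownames(expr) <- sprintf("g%02d", 1:g)
  colnames(expr) <- c(sprintf("r%d", 1:4), "sup")
  be <- batched_expression(expr,
                           batch = c(rep("dev", 4), "inj"),
                           condition = c("n", "m", "a", "a", "control"),
                           reference_batch = "dev",
                           anchor = c(dev = "a", inj = "control"))
  pr <- fit_project(expr, be)   # no alignment: the duplicate must project
                                # exactly onto its reference twin
  expect_equal(pr$pc1_var_fraction, 1.0, tolerance = 1e-12)
  co <- pr$coords$pc1_coord
  expect_equal(co[5], co[2], tolerance = 1e-9)
  # adult reference samples average positive
  expect_gt(mean(co[3:4]), 0)
  expect_equal(sum(pr$pc1_loadings^2), 1, tolerance = 1e-12)
})

test_that("projection is invariant to a gene-wise constant and the variance
           fraction matches a dense eigendecomposition", {
  be <- toy_batches(delta = 0)
  corr <- align_batches(be)
  pr <- fit_project(corr, be)
  shifted <- corr + matrix(rnorm(30), 30, 10)[, rep(1, 10)]
  pr2 <- fit_project(shifted, be)
  expect_equal(pr$coords$pc1_coord, pr2$coords$pc1_coord, tolerance = 1e-8)
  ev <- eigen(stats::cov(t(corr[, be$batch == "dev"])))$values
  expect_equal(pr$pc1_var_fraction, ev[1] / sum(ev), tolerance = 1e-9)
})

test_that("planted dedifferentiation weights produce monotone projection
           coordinates", {
  w_grid <- c(0, 0.25, 0.5, 0.75, 1)
  ge <- gen_expression(synth_config(seed = 41, n_genes = 400,
                                    n_id_genes = 40, n_ubq_genes = 40,
                                    n_cells = 10),
                       dediff_weights = w_grid)
  expr <- cbind(ge$reference$expr, ge$injury$expr)
  be <- batched_expression(
    expr,
    batch = c(rep("dev", ncol(ge$reference$expr)),
              rep("inj", ncol(ge$injury$expr))),
    condition = c(ge$reference$stage, ge$injury$condition),
    reference_batch = "dev", anchor = c(dev = "adult", inj = "control"))
  pr <- fit_project(align_batches(be), be)
  inj_co <- pr$coords$pc1_coord[pr$coords$batch == "inj"]
  means <- tapply(inj_co, ge$injury$weight, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
  # intermediate weights land between newborn and adult reference means
  dev_co <- pr$coords$pc1_coord[pr$coords$batch == "dev"]
  nb <- mean(dev_co[ge$reference$stage == "newborn"])
  ad <- mean(dev_co[ge$reference$stage == "adult"])
  mid <- means[names(means) == "0.5"]
  expect_true(mid > nb && mid < ad)
})

test_that("fit_project refuses underdetermined references", {
  be <- toy_batches()
  small <- be
  keep <- c(1:2, 7:10)
  small$expr <- be$expr[, keep]
  small$batch <- be$batch[keep]
  small$condition <- be$condition[keep]
  expect_error(fit_project(small$expr, small), "at least 3")
})
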