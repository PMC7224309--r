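toy_cistrome_world <- function() {
  enh <- genomic_intervals("chr1", (0:5) * 2000, (0:5) * 2000 + 1000,
                           name = sprintf("e%d", 1:6))
  mid <- (enh$start + enh$end) %/% 2L
  site <- function(i) genomic_intervals("chr1", mid[i] - 50L, mid[i] + 50L)
  list(enh = enh,
       cistromes = list(TFa = site(c(1, 2, 3)), TFb = site(c(1, 4)),
                        TFc = site(1), TFd = genomic_intervals(
                          character(), integer(), integer())))
}

test_that("occupancy matrix is binary overlap against each cistrome and
           matches a brute-force scan", {
  w <- toy_cistrome_world()
  bm <- build_binding_matrix(w$enh, w$cistromes)
  expect_equal(unname(rowSums(bm$occupancy)), c(3L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(bm$occupancy[, "TFd"]), rep(0L, 6))  # empty cistrome
  brute <- sapply(w$cistromes, function(cs) as.integer(oracle_overlap(w$enh, cs)))
  expect_equal(unname(bm$occupancy), unname(brute))
  dup <- w$cistromes; names(dup) <- c("TFa", "TFa", "TFc", "TFd")
  expect_error(build_binding_matrix(w$enh, dup), "uniquely named")
})

test_that("co-binding strata report percentages, leave empty strata missing
           and stay consistent with occupancy row sums", {
  w <- toy_cistrome_world()
  bm <- build_binding_matrix(w$enh, w$cistromes)
  strata <- list(c(0L, 1L), c(2L, 3L))
  down <- genomic_intervals("chr1", c(0, 2000), c(1000, 3000))  # e1, e2
  st <- cobinding_strata_fraction(bm, "TFa", down, strata)
  # bound by TFa: e1 (2 additional), e2, e3 (0 additional)
  expect_equal(st$pct_down[st$bound & st$stratum == "2-3"], 100)  # e1
  expect_equal(st$pct_down[st$bound & st$stratum == "0-1"], 50)   # e2, e3
  expect_true(is.na(st$pct_down[!st$bound & st$stratum == "2-3"]))
  expect_equal(st$n[!st$bound & st$stratum == "2-3"], 0L)
  # stratum counts add up to the number of enhancers
  expect_equal(sum(st$n), nrow(w$enh))
  expect_error(cobinding_strata_fraction(bm, "TFa", down,
                                         list(c(0L, 1L))), "cover")
  expect_error(cobinding_strata_fraction(bm, "TFzz", down, strata),
               "unknown focal TF")
})

test_that("inactivation fraction rises with planted co-binding degree and
           peaks in the bound high-degree stratum", {
  hits <- 0L
  for (seed in 1:10) {
    g <- gen_cistromes(synth_config(seed = seed, n_enhancers = 400))
    bm <- build_binding_matrix(g$enhancers, g$cistromes)
    st <- cobinding_strata_fraction(bm, "TF1", g$down_regions)
    top <- st$pct_down[st$bound & st$stratum == "6-8"]
    if (!is.na(top) && top == max(st$pct_down, na.rm = TRUE)) hits <- hits + 1L
    bound_cells <- st$pct_down[st$bound]
    expect_true(all(diff(bound_cells[!is.na(bound_cells)]) >= -15))
  }
  expect_gte(hits, 9L)
})

test_that("overlap enrichment reproduces hand-computed 2x2 log-odds and
           degenerate contracts", {
  # universe of 100 tiled regions; query = first 20; target hits 5 of the
  # query and 15 of the rest: table [[5,15],[15,65]] -> OR = 5*65/(15*15)
  uni <- genomic_intervals("chr1", (0:99) * 1000, (0:99) * 1000 + 500)
  target <- uni[c(1:5, 21:35), ]
  res <- overlap_enrichment(1:20, list(tgt = target), uni)
  expect_equal(res$log_odds, log(5 * 65 / (15 * 15)), tolerance = 1e-9)
  expect_equal(res$p, stats::fisher.test(
    matrix(c(5, 15, 15, 65), 2, byrow = TRUE))$p.value)
  # exact [[5,5],[15,75]] table: query 10 regions, 5 hit; rest 90, 15 hit
  target2 <- uni[c(1:5, 11:25), ]
  res2 <- overlap_enrichment(1:10, list(tgt = target2), uni)
  expect_equal(res2$log_odds, log(5), tolerance = 1e-9)
  # no contrast when query is the whole universe
  resU <- overlap_enrichment(seq_len(100), list(tgt = target), uni)
  expect_equal(resU$log_odds, 0)
  # target hitting the rest but none of the query: finite negative
  # log-odds through the Haldane correction
  resF <- overlap_enrichment(1:20, list(tgt = uni[31:60, ]), uni)
  expect_true(is.finite(resF$log_odds) && resF$log_odds < 0)
})

test_that("log-odds flips sign when query and complement swap, p-values are
           label-invariant", {
  uni <- genomic_intervals("chr1", (0:59) * 1000, (0:59) * 1000 + 500)
  set.seed(3)
  target <- uni[sample(60, 25), ]
  a <- overlap_enrichment(1:20, list(x = target), uni)
  b <- overlap_enrichment(21:60, list(renamed = target), uni)
  expect_equal(a$log_odds, -b$log_odds, tolerance = 1e-9)
  expect_equal(a$p, b$p)
})

test_that("enrichment clustering uses Ward linkage on Euclidean distances
           and matches a naive agglomeration oracle", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  cl <- cluster_enrichment(m, k = 2)
  expect_equal(cl$hclust$height[1L], 0)           # identical rows first
  expect_equal(unname(cl$clusters["c"]) == unname(cl$clusters["a"]), FALSE)
  set.seed(21)
  m2 <- matrix(rnorm(40), 10, 4)
  got <- cluster_enrichment(m2)$hclust$height
  expect_equal(got, oracle_ward_heights(m2), tolerance = 1e-9)
  expect_error(cluster_enrichment(m2[1, , drop = FALSE]), "at least 2")
  m3 <- m2; m3[1, 1] <- NA
  expect_warning(cluster_enrichment(m3), "imputed")
})
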