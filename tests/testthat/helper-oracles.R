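# Independent brute-force oracles used to check the package's algorithms.
# Each deliberately takes a different computational route from the
# implementation it validates.

# Transitive-closure interval merge: repeatedly union any two intervals whose
# gap is at most max_gap until a fixed point. O(n^2) per pass.
oracle_merge <- function(ivs, max_gap) {
  rows <- split(ivs[, c("chrom", "start", "end")], seq_len(nrow(ivs)))
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      if (merged) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap <= max_gap) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quadratic overlap scan under half-open semantics.
oracle_overlap <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# Exhaustive direction-scan halfspace depth: for every point, scan the
# perpendiculars to all other points (nudged both ways) and take the minimum
# closed-halfplane count.
oracle_depth <- function(pts, eps = 1e-7) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    d <- sweep(pts, 2L, pts[i, ])
    nz <- rowSums(abs(d)) > 0
    if (!any(nz)) return(n)
    ang <- atan2(d[nz, 2L], d[nz, 1L])
    cand <- as.vector(outer(c(ang + pi / 2, ang - pi / 2),
                            c(-eps, 0, eps), "+"))
    proj <- d %*% rbind(cos(cand), sin(cand))
    min(colSums(proj >= -1e-9))
  }, numeric(1))
}

# Naive Ward agglomeration from cluster centroids: greedily merge the pair
# with smallest cost sqrt(2 nA nB / (nA + nB)) * ||muA - muB||.
oracle_ward_heights <- function(m) {
  cl <- lapply(seq_len(nrow(m)), function(i) i)
  heights <- numeric(0)
  while (length(cl) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i >= j) next
      na <- length(cl[[i]]); nb <- length(cl[[j]])
      mu_a <- colMeans(m[cl[[i]], , drop = FALSE])
      mu_b <- colMeans(m[cl[[j]], , drop = FALSE])
      d <- sqrt(2 * na * nb / (na + nb)) * sqrt(sum((mu_a - mu_b)^2))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    cl[[best[1L]]] <- c(cl[[best[1L]]], cl[[best[2L]]])
    cl[[best[2L]]] <- NULL
  }
  heights
}

# Naive element-by-element tangent scan for the rank-ordering cutoff.
oracle_rose_flags <- function(signal) {
  n <- length(signal)
  s <- sort(signal)
  cutoff <- s[n]
  for (i in seq_len(n - 1L)) {
    y1 <- (s[i] - s[1L]) / (s[n] - s[1L])
    y2 <- (s[i + 1L] - s[1L]) / (s[n] - s[1L])
    slope <- (y2 - y1) * (n - 1)
    if (slope >= 1 - 1e-9) { cutoff <- s[i]; break }
  }
  signal > cutoff
}

# Random interval set on a couple of chromosomes.
random_intervals <- function(n, span = 10000L, max_len = 300L,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}
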