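#' Tukey (halfspace) depth
#'
#' The depth of a point is the minimum, over all closed halfplanes whose
#' boundary passes through it, of the number of data points (itself included)
#' in the halfplane. For `n <= exact_limit` the depth is computed exactly by
#' the angular-sweep method (per point, sort the angles to all other points
#' and slide an open semicircle); beyond that it is approximated by scanning
#' `n_directions` random projection directions under a fixed internal seed.
#'
#' @param points Numeric n x 2 matrix.
#' @param exact_limit Largest n for the exact sweep; default 5000.
#' @param n_directions Number of random directions in approximate mode;
#'   default 1000.
#' @return Integer vector of depths (1 = a hull vertex in generic position).
#' @export
tukey_depth <- function(points, exact_limit = 5000L, n_directions = 1000L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  n <- nrow(points)
  if (n > exact_limit) return(.tukey_depth_approx(points, n_directions))
  depths <- integer(n)
  for (i in seq_len(n)) {
    dx <- points[, 1L] - points[i, 1L]
    dy <- points[, 2L] - points[i, 2L]
    coincident <- dx == 0 & dy == 0          # includes the point itself
    a <- atan2(dy[!coincident], dx[!coincident])
    a <- a %% (2 * pi)
    m <- length(a)
    if (m == 0L) { depths[i] <- n; next }
    a <- sort(a)
    b <- c(a, a + 2 * pi)
    ## the fullest open semicircle ends exactly at some point's angle:
    ## count angles in (a_j - pi, a_j], evaluated as (a_j + pi, a_j + 2pi]
    ## over the unrolled vector so the right boundary is hit exactly
    cnt <- findInterval(a + 2 * pi, b) - findInterval(a + pi, b)
    depths[i] <- m - max(cnt) + sum(coincident)
  }
  depths
}

.tukey_depth_approx <- function(points, n_directions) {
  n <- nrow(points)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(20260101L)
  theta <- stats::runif(n_directions, 0, 2 * pi)
  proj <- points %*% rbind(cos(theta), sin(theta))
  depths <- rep.int(n, n)
  for (k in seq_len(n_directions)) {
    r <- rank(proj[, k], ties.method = "min")
    depths <- pmin(depths, n - r + 1L)
  }
  as.integer(depths)
}

.convex_contains <- function(poly, pts, tol = 1e-9) {
  ## poly: convex polygon vertices (ordered); pts: m x 2. Boundary counts as
  ## inside.
  nv <- nrow(poly)
  e2 <- poly[c(2:nv, 1L), , drop = FALSE]
  inside <- rep(TRUE, nrow(pts))
  ## orientation of the polygon
  orient <- sum((e2[, 1L] - poly[, 1L]) * (e2[, 2L] + poly[, 2L]))
  s <- if (orient < 0) 1 else -1
  for (j in seq_len(nv)) {
    cr <- (e2[j, 1L] - poly[j, 1L]) * (pts[, 2L] - poly[j, 2L]) -
      (e2[j, 2L] - poly[j, 2L]) * (pts[, 1L] - poly[j, 1L])
    inside <- inside & (s * cr >= -tol)
  }
  inside
}

#' Bivariate bagplot
#'
#' A bivariate boxplot: the depth median is the deepest point (centroid of
#' the deepest set on ties); the bag is the convex hull of the `ceiling(n/2)`
#' deepest points (ties at the depth cut broken by distance to the depth
#' median, then by index); the loop is the bag inflated by `inflation`
#' (default 3) about the depth median; outliers are the points outside the
#' loop.
#'
#' @param points Numeric n x 2 matrix, `n >= 5`, not all collinear.
#' @param inflation Loop inflation factor about the depth median; default 3.
#' @return List of class `bagplot`: `depth_median` (2-vector), `depths`,
#'   `bag_indices` (the `ceiling(n/2)` deepest points), `bag` and `loop`
#'   (polygon vertex matrices), `outliers` (point indices outside the loop).
#' @export
bagplot <- function(points, inflation = 3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5L) stop("need at least 5 points")
  v1 <- points[2L, ] - points[1L, ]
  cr <- abs((points[, 1L] - points[1L, 1L]) * v1[2L] -
            (points[, 2L] - points[1L, 2L]) * v1[1L])
  if (all(cr < 1e-12 * max(1, max(abs(points)))))
    stop("points are collinear; use a univariate summary instead")
  depths <- tukey_depth(points)
  deepest <- which(depths == max(depths))
  med <- colMeans(points[deepest, , drop = FALSE])
  d2 <- (points[, 1L] - med[1L])^2 + (points[, 2L] - med[2L])^2
  ord <- order(-depths, d2, seq_len(n))
  bag_idx <- sort(ord[seq_len(ceiling(n / 2))])
  hull <- grDevices::chull(points[bag_idx, , drop = FALSE])
  bag <- points[bag_idx[hull], , drop = FALSE]
  loop <- sweep(sweep(bag, 2L, med, "-") * inflation, 2L, med, "+")
  out_idx <- if (nrow(loop) >= 3L)
    which(!.convex_contains(loop, points)) else integer(0)
  structure(list(depth_median = med, depths = depths,
                 bag_indices = bag_idx, bag = bag, loop = loop,
                 outliers = out_idx),
            class = "bagplot")
}
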