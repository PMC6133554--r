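# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: areas by the shoelace formula, containment
# by ray casting, band areas by a raster distance transform, survival
# quantities by direct enumeration over risk sets, and cluster criteria by
# naive per-definition loops.

disk_ring <- function(radius, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = radius * cos(th), y = radius * sin(th))
}

# shoelace area of a ring given as a 2-column matrix
oracle_polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j]) / 2)
}

# even-odd ray casting, vectorized over points
oracle_point_in_polygon <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (y[i] > py) != (y[j] > py)
    if (any(cross)) {
      xin <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
      flip <- cross & (px < xin)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

# Raster distance-transform oracle for compartment band areas (mm^2).
# Rasterizes the polygon mask at `res` um/pixel by ray casting, then takes
# Euclidean distance maps (EBImage) inside and outside the mask.
oracle_raster_band_areas <- function(ring, margin, res = 1) {
  pad <- margin + 2 * res
  xr <- range(ring[, 1]) + c(-pad, pad)
  yr <- range(ring[, 2]) + c(-pad, pad)
  xs <- seq(xr[1], xr[2], by = res)
  ys <- seq(yr[1], yr[2], by = res)
  nx <- length(xs); ny <- length(ys)
  mask <- matrix(FALSE, nx, ny)
  for (jy in seq_len(ny)) {
    mask[, jy] <- oracle_point_in_polygon(xs, rep(ys[jy], nx), ring)
  }
  # distance (in pixels) to the nearest background/foreground pixel
  d_in <- EBImage::distmap(EBImage::Image(mask * 1, dim = c(nx, ny)))@.Data
  d_out <- EBImage::distmap(EBImage::Image((!mask) * 1, dim = c(nx, ny)))@.Data
  m_px <- margin / res
  core <- mask & d_in > m_px
  inner <- mask & d_in <= m_px
  outer <- (!mask) & d_out <= m_px
  px_mm2 <- res^2 / 1e6
  c(TU_CORE = sum(core) * px_mm2,
    MARG_500_IN = sum(inner) * px_mm2,
    MARG_500_OUT = sum(outer) * px_mm2)
}

# ---- survival oracles -------------------------------------------------------

# Efron log partial likelihood for a single binary/continuous covariate or a
# full design matrix X (n x p), with event indicator and times.
oracle_efron_loglik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event])) {
    D <- which(event & time == t)      # deaths at t
    R <- which(time >= t)              # at risk
    d <- length(D)
    sumR <- sum(w[R]); sumD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

oracle_efron_gradient <- function(beta, X, time, event, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- rep(0, length(beta)); e[j] <- h
    (oracle_efron_loglik(beta + e, X, time, event) -
       oracle_efron_loglik(beta - e, X, time, event)) / (2 * h)
  }, numeric(1))
}

# product-limit estimator by direct iteration over risk sets
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(event & time == ts[i])
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank by per-event-time 2x2 tabulation
oracle_logrank_2group <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  ts <- sort(unique(time[event]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# ---- clustering oracles -----------------------------------------------------

oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(unique(labels[!own]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

oracle_davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  cent <- lapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]))
  s <- vapply(seq_along(ks), function(gi) {
    Xg <- X[labels == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xg, 2, cent[[gi]])^2)))
  }, numeric(1))
  total <- 0
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      val <- (s[i] + s[j]) / sqrt(sum((cent[[i]] - cent[[j]])^2))
      if (val > best) best <- val
    }
    total <- total + best
  }
  total / length(ks)
}

oracle_calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X); ks <- sort(unique(labels)); k <- length(ks)
  gm <- colMeans(X)
  B <- 0; W <- 0
  for (g in ks) {
    Xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - gm)^2)
    W <- W + sum(sweep(Xg, 2, cg)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# naive O(n^3) average-linkage agglomeration returning sorted merge heights
oracle_average_linkage_heights <- function(M) {
  clusters <- lapply(seq_len(nrow(M)), identity)
  D <- as.matrix(dist(M))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# ---- shared fixtures --------------------------------------------------------

make_disk_compartments <- function(radius = 1500, margin = 500, n = 256) {
  build_compartments(region_annotation(disk_ring(radius, n)), margin)
}
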