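# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written as direct, naive implementations that do
# not share code with the package internals they check.

# --- fixtures -------------------------------------------------------------

# light acquisition for tests that do not probe angular resolution
light_scheme <- function(n_dir = 20, n_b0 = 3, seed = 2) {
  make_gradient_scheme(n_dir, 1500, n_b0, seed = seed)
}

# small straight-tube phantom along x
tube_phantom <- function(grid = c(16, 10, 10), sigma = 0, lesion = NULL,
                         scheme = light_scheme(), seed = 1, radius = 3) {
  vs <- 2
  ymid <- (grid[2] - 1) * vs / 2
  zmid <- (grid[3] - 1) * vs / 2
  spec <- phantom_spec(
    grid_dim = grid, voxel_size = vs,
    tracts = list(straight_tube(c(0, ymid, zmid),
                                c((grid[1] - 1) * vs, ymid, zmid), radius)),
    scheme = scheme, lesion = lesion, sigma = sigma)
  build_phantom(spec, seed = seed)
}

# single-voxel-signal DWI volume: replicate one signal across n voxels
signal_volume <- function(signal, n = 1, scheme) {
  image_volume(array(rep(signal, each = n), c(n, 1, 1, length(signal))),
               diag(c(2, 2, 2, 1)), scheme = scheme)
}

# --- closed-form oracles --------------------------------------------------

# FA/MD/RD/AD evaluated directly from the textbook formulas
oracle_scalars <- function(l1, l2, l3) {
  l <- sort(c(l1, l2, l3), decreasing = TRUE)
  md <- (l[1] + l[2] + l[3]) / 3
  fa <- sqrt(3 / 2) * sqrt((l[1] - md)^2 + (l[2] - md)^2 + (l[3] - md)^2) /
    sqrt(l[1]^2 + l[2]^2 + l[3]^2)
  list(FA = fa, MD = md, RD = (l[2] + l[3]) / 2, AD = l[1])
}

# pooled-variance two-sample t from sums (classical formula)
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# one-way ANOVA F from sums of squares
oracle_anova_f <- function(values, groups) {
  gm <- mean(values)
  k <- length(unique(groups))
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Pearson r from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# --- brute-force TFCE oracle ---------------------------------------------

# per-threshold flood fill + discrete integration, independent of the
# package's connected-component code
oracle_tfce <- function(arr, E = 0.5, H = 2, dh = NULL, conn = 26) {
  mx <- max(arr, 0)
  if (mx <= 0) return(array(0, dim(arr)))
  if (is.null(dh)) dh <- mx / 100
  d <- dim(arr)
  out <- array(0, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (conn == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  tol <- 1e-12 * mx
  for (s in seq_len(floor(mx / dh + 1e-9))) {
    h <- s * dh
    supra <- arr + tol >= h & arr > 0
    lab <- array(FALSE, d)
    for (v in which(supra)) {
      if (lab[v]) next
      q <- v; lab[v] <- TRUE; mem <- integer()
      while (length(q)) {
        cur <- q[1]; q <- q[-1]; mem <- c(mem, cur)
        ijk <- arrayInd(cur, d)
        for (o in seq_len(nrow(offs))) {
          nb <- ijk + offs[o, ]
          if (any(nb < 1) || any(nb > d)) next
          lv <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
          if (supra[lv] && !lab[lv]) { lab[lv] <- TRUE; q <- c(q, lv) }
        }
      }
      out[mem] <- out[mem] + length(mem)^E * h^H * dh
    }
  }
  out
}

# --- deterministic tracking oracle ---------------------------------------

# Euler tracking along a fixed per-voxel axis field (the kappa -> Inf limit),
# written independently of the compiled tracker
oracle_deterministic_track <- function(axis_fun, mask, seed_point, step,
                                       max_steps) {
  Ainv <- solve(mask$affine)
  # nearest-voxel convention: round halves away from zero (as the tracker)
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)
  vox_of <- function(p) {
    v <- rnd((Ainv %*% c(p, 1))[1:3])
    if (any(v < 0) || any(v >= dim(mask$data))) return(NULL)
    if (mask$data[v[1] + 1, v[2] + 1, v[3] + 1] != 1) return(NULL)
    v
  }
  half <- function(d0) {
    pts <- NULL
    x <- seed_point; d <- d0
    for (s in seq_len(max_steps)) {
      xn <- x + step * d
      v <- vox_of(xn)
      if (is.null(v)) break
      pts <- rbind(pts, xn)
      dn <- axis_fun(v)
      if (sum(dn * d) < 0) dn <- -dn
      x <- xn; d <- dn
    }
    pts
  }
  v0 <- vox_of(seed_point)
  d0 <- axis_fun(v0)
  back <- half(-d0)
  fwd <- half(d0)
  rbind(if (!is.null(back)) back[rev(seq_len(nrow(back))), , drop = FALSE],
        matrix(seed_point, 1, 3), fwd)
}

# smallest cosine between successive unit steps of a streamline polyline
min_step_cosine <- function(pts) {
  if (nrow(pts) < 3) return(1)
  d <- diff(pts)
  d <- d / sqrt(rowSums(d^2))
  min(rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE]))
}
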