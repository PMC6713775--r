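# Brute-force texture-matrix oracles and small geometric phantoms.
# Deliberately naive R loops, independent of the compiled implementations.

# the 13 unique lattice directions used for GLCM/GLRLM
oracle_dirs <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dx > 0 | (d$dx == 0 & d$dy > 0) | (d$dx == 0 & d$dy == 0 & d$dz > 0)
  as.matrix(d[keep, ])
}

# exhaustive pair enumeration; returns averaged normalised symmetric GLCM
oracle_glcm <- function(lev, ng, dirs = oracle_dirs()) {
  dm <- dim(lev)
  acc <- matrix(0, ng, ng)
  used <- 0
  for (q in seq_len(nrow(dirs))) {
    M <- matrix(0, ng, ng)
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      a <- lev[i, j, k]
      if (a == 0) next
      ii <- i + dirs[q, 1]; jj <- j + dirs[q, 2]; kk <- k + dirs[q, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > dm[1] || jj > dm[2] || kk > dm[3]) next
      b <- lev[ii, jj, kk]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
    if (sum(M) > 0) { acc <- acc + M / sum(M); used <- used + 1 }
  }
  if (used > 0) acc / used else acc
}

# exhaustive run lister; returns run-count matrix averaged over directions
oracle_glrlm <- function(lev, ng, dirs = oracle_dirs()) {
  dm <- dim(lev)
  maxlen <- max(dm)
  acc <- matrix(0, ng, maxlen)
  inb <- function(i, j, k) i >= 1 && j >= 1 && k >= 1 &&
    i <= dm[1] && j <= dm[2] && k <= dm[3]
  for (q in seq_len(nrow(dirs))) {
    dx <- dirs[q, 1]; dy <- dirs[q, 2]; dz <- dirs[q, 3]
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      a <- lev[i, j, k]
      if (a == 0) next
      if (inb(i - dx, j - dy, k - dz) && lev[i - dx, j - dy, k - dz] == a) next
      len <- 1
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      while (inb(ii, jj, kk) && lev[ii, jj, kk] == a) {
        len <- len + 1; ii <- ii + dx; jj <- jj + dy; kk <- kk + dz
      }
      acc[a, len] <- acc[a, len] + 1
    }
  }
  acc / nrow(dirs)
}

# zone list via naive 26-connected flood fill; returns (level, size) pairs
oracle_zones <- function(lev) {
  dm <- dim(lev)
  seen <- array(FALSE, dm)
  zones <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (lev[i, j, k] == 0 || seen[i, j, k]) next
    lv <- lev[i, j, k]
    stack <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (!dx && !dy && !dz) next
        ii <- v[1] + dx; jj <- v[2] + dy; kk <- v[3] + dz
        if (ii < 1 || jj < 1 || kk < 1 || ii > dm[1] || jj > dm[2] || kk > dm[3]) next
        if (!seen[ii, jj, kk] && lev[ii, jj, kk] == lv) {
          seen[ii, jj, kk] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj, kk)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lv, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(lev, ng) {
  z <- oracle_zones(lev)
  M <- matrix(0, ng, max(z[, "size"]))
  for (r in seq_len(nrow(z))) M[z[r, "level"], z[r, "size"]] <-
      M[z[r, "level"], z[r, "size"]] + 1
  M
}

# NGTDM oracle: per level, summed |level - mean of in-ROI 26-neighbours|
oracle_ngtdm <- function(lev, ng) {
  dm <- dim(lev)
  s <- numeric(ng); n <- numeric(ng)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- lev[i, j, k]
    if (a == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (!dx && !dy && !dz) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || jj < 1 || kk < 1 || ii > dm[1] || jj > dm[2] || kk > dm[3]) next
      if (lev[ii, jj, kk] > 0) nb <- c(nb, lev[ii, jj, kk])
    }
    if (!length(nb)) next
    s[a] <- s[a] + abs(a - mean(nb))
    n[a] <- n[a] + 1
  }
  cbind(s, n)
}

# wrap a bare level array as the object the texture functions expect
make_droi <- function(lev) {
  structure(list(levels = lev, n_levels = max(lev), bin_width_hu = 1,
                 min_hu = 0, n_voxels = sum(lev > 0)),
            class = "discretized_roi")
}

# voxelized ball of radius r (voxel units), isotropic spacing
sphere_mask <- function(r, spacing = c(1, 1, 1)) {
  n <- 2 * r + 3
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2, dim = c(n, n, n))
}

# small fast cohort configuration for image-level tests
small_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(34L, 30L, 22L), spacing_mm = c(1, 1, 2),
         semiaxes_mm = c(10, 8, 12), size_jitter = 0.05,
         perturb_amplitude = 0.08),
    list(...))
  do.call(cohort_config, args)
}

random_levels <- function(dims, ng, seed) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  # carve an irregular ROI: zero out a random corner region
  lev[1, 1, ] <- 0L
  lev
}
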