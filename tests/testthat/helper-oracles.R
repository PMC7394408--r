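# Independent brute-force oracles used to check the package's geometry and
# statistics primitives. These deliberately avoid the package's own code
# paths (double loops, normal equations) so agreement is meaningful.

oracle_disk_mask <- function(center, radius, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) m[i, j] <- TRUE
    }
  }
  m
}

oracle_boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      nb <- c(
        if (i > 1) mask[i - 1, j] else FALSE,
        if (i < nr) mask[i + 1, j] else FALSE,
        if (j > 1) mask[i, j - 1] else FALSE,
        if (j < nc) mask[i, j + 1] else FALSE
      )
      if (any(!nb)) out[i, j] <- TRUE
    }
  }
  out
}

# mean centroid-to-boundary distance of a rasterized disk, computed from
# scratch (used as the penetration-depth oracle)
oracle_boundary_distance <- function(radius, shape = c(128, 128),
                                     center = (shape + 1) / 2) {
  m <- oracle_disk_mask(center, radius, shape)
  b <- oracle_boundary_mask(m)
  ctr <- c(mean(row(m)[m]), mean(col(m)[m]))
  idx <- which(b, arr.ind = TRUE)
  mean(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
}

oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

random_scatter_roi <- function(shape = c(32L, 32L), n_px = 40L) {
  idx <- sample(prod(shape), n_px)
  m <- matrix(FALSE, shape[1], shape[2])
  m[idx] <- TRUE
  mask_roi(m)
}

random_blob_roi <- function(shape = c(48L, 48L)) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_len(sample(1:3, 1))) {
    ctr <- c(sample(10:(shape[1] - 10), 1), sample(10:(shape[2] - 10), 1))
    r <- sample(3:8, 1)
    m <- m | oracle_disk_mask(ctr, r, shape)
  }
  mask_roi(m)
}

jaccard <- function(a, b) {
  roi_size(roi_intersect(a, b)) / roi_size(roi_union(a, b))
}

# one noisy two-channel scene with a shell-enriched tmr channel
shell_scene <- function(seed, shell_levels = c(10, 100), noise = 5) {
  render_scene(scene_spec(
    channel_profiles = list(
      cerulean = profile_uniform(100, 0),
      tmr = profile_shell(shell_levels[1], shell_levels[2], 0.9)
    ),
    noise_sigma = noise, seed = seed
  ))
}
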