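# Independent oracles and small geometry builders used across the suite.
# These deliberately avoid the package's own C++ kernels: flood fill is a
# plain-R BFS, statistics are computed by direct enumeration.

# Brute-force connected-component labelling by BFS over an explicit
# neighbour list.
flood_fill_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  lab <- array(0L, d)
  nid <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nid <- nid + 1L
    queue <- start
    lab[start] <- nid
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ci <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- ci + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(p < 1L) || any(p > d)) next
        li <- p[1L] + d[1L] * ((p[2L] - 1L) + d[2L] * (p[3L] - 1L))
        if (mask[li] && lab[li] == 0L) {
          lab[li] <- nid
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# Population standard deviation over the 3x3x3 neighbourhood by direct
# enumeration.
direct_neighborhood_sd <- function(arr, i, j, k) {
  d <- dim(arr)
  vals <- c()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    p <- c(i + dx, j + dy, k + dz)
    if (any(p < 1L) || any(p > d)) next
    vals <- c(vals, arr[p[1L], p[2L], p[3L]])
  }
  sqrt(mean((vals - mean(vals))^2))
}

# Cohen's kappa from a 2x2 table by the definition.
direct_kappa <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  (po - pe) / (1 - pe)
}

# Geometry builders (all on isotropic grids unless stated).
make_cylinder <- function(n = 33L, spacing = 0.5, radius = 3, axis = 3L,
                          value = 500, background = -900) {
  arr <- array(background, rep(n, 3L))
  co <- (seq_len(n) - (n + 1) / 2) * spacing
  disk <- outer(co^2, co^2, "+") <= radius^2
  slice <- array(background, c(n, n))
  slice[disk] <- value
  for (s in seq_len(n)) {
    if (axis == 3L) arr[, , s] <- slice
    if (axis == 2L) arr[, s, ] <- slice
    if (axis == 1L) arr[s, , ] <- slice
  }
  ct_volume(arr, rep(spacing, 3L))
}

make_sphere_mask <- function(n = 33L, spacing = 0.5, radius = 3) {
  ctr <- (n + 1) / 2
  co <- (seq_len(n) - ctr) * spacing
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  r2 <= radius^2
}

make_gaussian_blob <- function(n = 41L, spacing = 0.5, width = 2,
                               amplitude = 500, background = -900) {
  ctr <- (n + 1) / 2
  co <- (seq_len(n) - ctr) * spacing
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  ct_volume(background + amplitude * exp(-r2 / (2 * width^2)),
            rep(spacing, 3L))
}

# A deterministic random label map over a compact mask.
random_label_volume <- function(n = 12L, p = 0.4, seed = 1L,
                                spacing = c(1, 1, 1)) {
  set.seed(seed)
  arr <- array(0L, rep(n, 3L))
  on <- runif(n^3) < p
  arr[on] <- sample(1:3, sum(on), replace = TRUE)
  label_volume(arr, spacing)
}

expect_same_partition <- function(lab_a, lab_b) {
  # same partition up to label renaming
  expect_equal(max(lab_a), max(lab_b))
  key <- paste(lab_a[lab_a > 0], lab_b[lab_b > 0])
  expect_equal(length(unique(key)), max(lab_a))
}
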