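test_that("the continuity weight follows the piecewise-linear law exactly", {
  # flat at 1 up to the entering diameter
  expect_equal(continuity_weight(2, 2, a = 3), 1)
  expect_equal(continuity_weight(1.2, 2, a = 3), 1)
  # zero at and beyond a times the entering diameter
  expect_equal(continuity_weight(6, 2, a = 3), 0)
  expect_equal(continuity_weight(9, 2, a = 3), 0)
  # linear midpoint of the transition
  expect_equal(continuity_weight(4, 2, a = 3), 0.5)
  # vectorized
  expect_equal(continuity_weight(c(1, 2, 4, 6, 8), 2, a = 3),
               c(1, 1, 0.5, 0, 0))
})

test_that("the continuity weight is continuous at both breakpoints", {
  eps <- 1e-9
  a <- 3
  d_out <- 1.7
  expect_lt(abs(continuity_weight(d_out + eps, d_out, a) - 1), 1e-8)
  expect_lt(abs(continuity_weight(a * d_out - eps, d_out, a) - 0), 1e-8)
  # exact values at the breakpoints themselves
  expect_identical(continuity_weight(d_out, d_out, a), 1)
  expect_identical(continuity_weight(a * d_out, d_out, a), 0)
})

test_that("the continuity weight is non-increasing in the diameter ratio", {
  ratios <- seq(0.2, 4, by = 0.05)
  w <- continuity_weight(ratios * 1.5, 1.5, a = 3)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("continuity weight rejects invalid parameters", {
  expect_error(continuity_weight(1, 0, a = 3), "d_out")
  expect_error(continuity_weight(1, -2, a = 3), "d_out")
  expect_error(continuity_weight(1, 1, a = 1), "`a`")
})

test_that("6-connectivity separates diagonal structures that 26 joins", {
  d <- c(8, 8, 8)
  m <- array(FALSE, d)
  m[2:3, 2, 2] <- TRUE
  m[4:5, 3, 3] <- TRUE  # touches only diagonally
  expect_length(split_components(m, 6L), 2L)
  expect_length(split_components(m, 26L), 1L)
  # single tube
  tube <- array(FALSE, d)
  tube[2:7, 4, 4] <- TRUE
  expect_length(split_components(tube, 6L), 1L)
  expect_length(split_components(array(FALSE, d), 6L), 0L)
})

test_that("component splitting matches a brute-force flood fill on random masks", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- array(runif(10^3) < 0.25, c(10, 10, 10))
    for (conn in c(6L, 26L)) {
      comps <- split_components(m, conn)
      oracle <- flood_fill_components(m, conn)
      expect_length(comps, max(oracle))
      got <- array(0L, dim(m))
      for (cp in comps) got[cp$voxels] <- cp$id
      expect_same_partition(got, oracle)
    }
  }
})

test_that("component ids are ordered by smallest linear voxel index", {
  m <- array(FALSE, c(6, 6, 6))
  m[5, 5, 5] <- TRUE   # later in linear order
  m[2, 2, 2] <- TRUE   # earlier
  comps <- split_components(m, 6L)
  expect_equal(comps[[1L]]$voxels, which(array(seq_len(216), c(6, 6, 6)) ==
                                           (2 + 6 * (1 + 6 * 1))))
  expect_lt(comps[[1L]]$voxels, comps[[2L]]$voxels)
})

test_that("local-thickness diameters recover analytic calibres", {
  # digital cylinder of radius 2 mm at 0.5 mm spacing
  n <- 25L
  m <- array(FALSE, c(n, n, n))
  co <- (seq_len(n) - (n + 1) / 2) * 0.5
  disk <- outer(co^2, co^2, "+") <= 2^2
  for (s in seq_len(n)) m[, , s] <- disk
  d <- estimate_diameters(m, spacing = c(0.5, 0.5, 0.5))
  ctr <- (n + 1) / 2
  expect_gte(d[ctr, ctr, ctr], 3.5)
  expect_lte(d[ctr, ctr, ctr], 4.5)

  # sphere of radius 3 mm: central diameter ~6 mm
  sm <- make_sphere_mask(n = 25L, spacing = 0.5, radius = 3)
  ds <- estimate_diameters(sm, spacing = c(0.5, 0.5, 0.5))
  expect_gte(ds[13, 13, 13], 5.4)
  expect_lte(ds[13, 13, 13], 6.6)

  # single isolated voxel at 0.5 mm: diameter bounded by one voxel
  one <- array(FALSE, c(9, 9, 9))
  one[5, 5, 5] <- TRUE
  d1 <- estimate_diameters(one, spacing = c(0.5, 0.5, 0.5))
  expect_gt(d1[5, 5, 5], 0)
  expect_lte(d1[5, 5, 5], 1)

  expect_error(estimate_diameters(array(FALSE, c(4, 4, 4))), "empty")
})

# A small scene: nodule sphere in the middle, one tube crossing it along x,
# optionally a detached blob inside the nodule.
continuity_scene <- function(tube_diam = 3, blob = FALSE, n = 33L,
                             spacing = 0.5, taper = 1) {
  sp <- phantom_spec(
    shape = rep(n, 3L), spacing = rep(spacing, 3L),
    nodule = list(center = rep((n - 1) * spacing / 2, 3), radii = rep(5, 3),
                  hu = -600),
    vessels = list(list(
      points = rbind(c(0, (n - 1) * spacing / 2, (n - 1) * spacing / 2),
                     c((n - 1) * spacing, (n - 1) * spacing / 2,
                       (n - 1) * spacing / 2)),
      diameter = c(tube_diam, tube_diam * taper), hu = 50)),
    blur_sigma = 0, noise_sigma = 0, seed = 1)
  b <- generate_phantom(sp)
  init <- array(0L, rep(n, 3L))
  init[b$nodule$data > 0L] <- 3L
  init[b$truth$data == 1L] <- 1L
  if (blob) {
    ctr <- rep((n - 1) * spacing / 2, 3) + c(0, 3.4, 0)
    co <- grid_coords_local(rep(n, 3L), rep(spacing, 3L))
    bl <- (co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <= 1.2^2
    init[bl & b$nodule$data > 0L] <- 1L
  }
  list(b = b, init = label_volume(init, rep(spacing, 3L)))
}

grid_coords_local <- function(shape, spacing)
  subsolidseg:::grid_coords(shape, spacing)

test_that("a crossing tube keeps its entering vessel and high continuity weights", {
  sc <- continuity_scene(tube_diam = 3)
  fld <- continuity_field(sc$init, sc$b$outer_vessels, sc$b$nodule)
  comps <- fld$components
  expect_length(comps, 1L)
  expect_false(is.na(comps[[1L]]$entering_vessel_id))
  expect_gt(comps[[1L]]$d_out, 3 * 0.8)
  expect_lt(comps[[1L]]$d_out, 3 * 1.2)
  inner <- sc$init$data == 1L
  expect_gte(mean(fld$w_vc[inner] >= 0.9), 0.9)
})

test_that("an inner blob touching no outer vessel has no entering vessel and weight zero", {
  sc <- continuity_scene(tube_diam = 2.5, blob = TRUE)
  fld <- continuity_field(sc$init, sc$b$outer_vessels, sc$b$nodule)
  entered <- vapply(fld$components, function(cp)
    !is.na(cp$entering_vessel_id), logical(1L))
  expect_equal(sum(entered), 1L)
  blob_comp <- fld$components[[which(!entered)[1L]]]
  expect_true(all(fld$w_vc[blob_comp$voxels] == 0))
})

test_that("of two attached outer vessels the larger-calibre one is selected", {
  n <- 33L
  spacing <- 0.5
  ctr <- (n - 1) * spacing / 2
  sp <- phantom_spec(
    shape = rep(n, 3L), spacing = rep(spacing, 3L),
    nodule = list(center = rep(ctr, 3), radii = rep(5, 3), hu = -600),
    vessels = list(
      list(points = rbind(c(0, ctr, ctr), c(n - 1, ctr, ctr) * spacing),
           diameter = 2, hu = 50),
      list(points = rbind(c(ctr, 0, ctr), c(ctr, (n - 1) * spacing, ctr)),
           diameter = 4, hu = 50)),
    blur_sigma = 0, noise_sigma = 0, seed = 1)
  b <- generate_phantom(sp)
  init <- array(0L, rep(n, 3L))
  init[b$nodule$data > 0L] <- 3L
  init[b$truth$data == 1L] <- 1L
  # keep the tree permissive so both outer vessels qualify
  fld <- continuity_field(label_volume(init, rep(spacing, 3L)),
                          b$outer_vessels, b$nodule, tree_fraction = 0.01)
  comps <- fld$components
  # the two tubes cross inside the nodule: a single 6-connected component
  expect_length(comps, 1L)
  expect_gt(comps[[1L]]$d_out, 3.2)
})

test_that("identity and vanishing continuity fields act as expected on the re-argmax", {
  set.seed(31)
  d <- c(7, 7, 7)
  mask <- array(TRUE, d)
  raw <- matrix(runif(3 * prod(d), 0.05, 1), ncol = 3)
  raw <- raw / rowSums(raw)
  mk <- function(col) array(raw[, col], d)
  post <- posterior_stack(mk(1), mk(2), mk(3), mask)
  w <- class_weights(0.23, 0.13, 0.64)
  init <- initial_segmentation(post, w, smooth = FALSE)

  fld1 <- structure(list(w_vc = array(1, d), d_in = array(0, d),
                         components = list(), a = 3),
                    class = "continuity_field")
  out1 <- apply_continuity(post, w, fld1, smooth = FALSE)
  expect_equal(out1$data, init$data)

  fld0 <- structure(list(w_vc = array(0, d), d_in = array(0, d),
                         components = list(), a = 3),
                    class = "continuity_field")
  out0 <- apply_continuity(post, w, fld0, smooth = FALSE)
  expect_true(all(out0$data != 1L))
  # every formerly-vessel voxel now takes argmax of the remaining classes
  was_v <- init$data == 1L
  expect_equal(out0$data[was_v],
               ifelse(raw[was_v, 2] * 0.13 >= raw[was_v, 3] * 0.64, 2L, 3L))
})

test_that("the worked bulge example flips to ground-glass", {
  d <- c(3, 3, 3)
  mask <- array(TRUE, d)
  post <- posterior_stack(array(0.6, d), array(0.1, d), array(0.3, d), mask)
  w <- class_weights(0.23, 0.13, 0.64)
  fld <- structure(list(w_vc = array(0.25, d), d_in = array(0, d),
                        components = list(), a = 3),
                   class = "continuity_field")
  out <- apply_continuity(post, w, fld, smooth = FALSE)
  # L_v = 0.23*0.25*0.6 = 0.0345 < L_g = 0.192
  expect_true(all(out$data == 3L))
})

test_that("the final vessel set is a subset of the initial one for any field", {
  set.seed(32)
  for (rep in 1:3) {
    d <- c(8, 8, 8)
    mask <- array(runif(prod(d)) < 0.8, d)
    raw <- matrix(runif(3 * sum(mask), 0.02, 1), ncol = 3)
    raw <- raw / rowSums(raw)
    mk <- function(col) {
      a <- array(0, d)
      a[mask] <- raw[, col]
      a
    }
    post <- posterior_stack(mk(1), mk(2), mk(3), mask)
    w <- class_weights(0.3, 0.3, 0.4)
    init <- initial_segmentation(post, w, smooth = FALSE)
    fld <- structure(list(w_vc = array(runif(prod(d)), d),
                          d_in = array(0, d), components = list(), a = 3),
                     class = "continuity_field")
    fin <- apply_continuity(post, w, fld, smooth = FALSE)
    expect_true(all(which(fin$data == 1L) %in% which(init$data == 1L)))
  }
})

test_that("the default outside-vessel filter finds a tube and respects the bypass", {
  n <- 33L
  sp <- phantom_spec(
    shape = rep(n, 3L), spacing = rep(0.5, 3L),
    nodule = list(center = rep(8, 3), radii = rep(4, 3), hu = -600),
    vessels = list(list(points = rbind(c(0, 12, 12), c(16, 12, 12)),
                        diameter = 3, hu = 50)),
    blur_sigma = 0.4, noise_sigma = 5, seed = 2)
  b <- generate_phantom(sp)
  got <- outer_vessel_mask(b$volume, nodule = b$nodule)
  truth_out <- b$outer_vessels$data > 0L
  expect_gte(sum(got$data > 0L & truth_out) / sum(truth_out), 0.8)

  # vessel-free scene yields an empty mask
  sp2 <- phantom_spec(shape = rep(21L, 3L), spacing = rep(0.5, 3L),
                      nodule = list(center = rep(5, 3), radii = rep(3, 3),
                                    hu = -600),
                      blur_sigma = 0.4, noise_sigma = 5, seed = 3)
  b2 <- generate_phantom(sp2)
  got2 <- outer_vessel_mask(b2$volume, nodule = b2$nodule)
  expect_equal(sum(got2$data), 0L)

  # an externally supplied mask is passed through outside the nodule
  ext <- b$outer_vessels
  byp <- outer_vessel_mask(b$volume, nodule = b$nodule, external = ext)
  expect_equal(byp$data, ext$data)
  expect_error(outer_vessel_mask(b$volume, roi = array(FALSE, rep(n, 3L)),
                                 nodule = b$nodule), "empty ROI")
})
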