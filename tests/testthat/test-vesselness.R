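test_that("Hessian eigenvalues vanish on constants and match quadratics", {
  eg <- hessian_eigen(array(4, c(16, 16, 16)), 1)
  expect_lt(max(abs(eg$l3)), 1e-10)

  # f = a*x^2: Hessian diag(2a, 0, 0); smoothing leaves a quadratic's second
  # derivative unchanged, so interior voxels give exactly (0, 0, 2a)
  a <- 3
  d <- 24L
  v <- array(0, c(d, d, d))
  v <- v + a * (slice.index(v, 1) - 12)^2
  eg <- hessian_eigen(v, 0.8)
  mid <- 8:16
  expect_equal(mean(eg$l3[mid, mid, mid]), 2 * a, tolerance = 1e-6)
  expect_lt(max(abs(eg$l1[mid, mid, mid])), 1e-6)
  expect_lt(max(abs(eg$l2[mid, mid, mid])), 1e-6)
})

test_that("closed-form symmetric eigenvalues agree with base eigen()", {
  set.seed(15)
  for (i in 1:50) {
    M <- matrix(rnorm(9), 3, 3); M <- (M + t(M)) / 2
    h <- list(xx = array(M[1, 1], c(1, 1, 1)), yy = array(M[2, 2], c(1, 1, 1)),
              zz = array(M[3, 3], c(1, 1, 1)), xy = array(M[1, 2], c(1, 1, 1)),
              xz = array(M[1, 3], c(1, 1, 1)), yz = array(M[2, 3], c(1, 1, 1)))
    ev <- sort(unlist(pvshaar:::sym3_eigenvalues(h)))
    expect_equal(ev, sort(eigen(M, symmetric = TRUE)$values), tolerance = 1e-9)
  }
})

test_that("a bright cylinder produces the tube eigenvalue signature", {
  v <- cylinder_volume(radius = 1.2)
  eg <- hessian_eigen(v, 1)
  ctr <- 16L
  ax <- 10:22
  l1 <- eg$l1[cbind(ctr, ctr, ax)]; l2 <- eg$l2[cbind(ctr, ctr, ax)]
  l3 <- eg$l3[cbind(ctr, ctr, ax)]
  expect_true(all(abs(l1) < 0.05 * abs(l3)))
  expect_true(all(l2 < 0) && all(l3 < 0))
  expect_true(all(abs(l2 / l3) > 0.8)) # near-circular cross-section
})

test_that("the vesselness formula matches a scalar hand evaluation", {
  zero <- list(l1 = array(0, c(1, 1, 1)), l2 = array(0, c(1, 1, 1)),
               l3 = array(0, c(1, 1, 1)))
  expect_equal(as.vector(frangi_vesselness(zero)), 0)

  mk <- function(l) list(l1 = array(l[1], c(1, 1, 1)),
                         l2 = array(l[2], c(1, 1, 1)),
                         l3 = array(l[3], c(1, 1, 1)))
  S <- sqrt(200); cc <- S / 2
  tube <- frangi_vesselness(mk(c(0, -10, -10)), alpha = 0.5, beta = 0.5, c = cc)
  hand <- (1 - exp(-1 / (2 * 0.25))) * exp(0) * (1 - exp(-200 / (2 * cc^2)))
  expect_equal(as.vector(tube), hand, tolerance = 1e-12)

  blobS <- sqrt(300)
  blob <- frangi_vesselness(mk(c(-10, -10, -10)), c = blobS / 2)
  tube2 <- frangi_vesselness(mk(c(0, -sqrt(150), -sqrt(150))), c = blobS / 2)
  expect_lt(as.vector(blob), as.vector(tube2)) # blob suppressed at equal S
  # bright-tube polarity: positive lambda2/lambda3 give zero
  expect_equal(as.vector(frangi_vesselness(mk(c(0, 10, 10)), c = 1)), 0)
})

test_that("multiscale fusion is the voxel-wise maximum over scales", {
  v <- cylinder_volume(radius = 1)
  m1 <- multiscale_vesselness(v, scales = 0.5)
  m2 <- multiscale_vesselness(v, scales = 1)
  mm <- multiscale_vesselness(v, scales = c(0.5, 1))
  expect_equal(mm$values, pmax(m1$values, m2$values))
  expect_true(all(mm$values >= m1$values) && all(mm$values >= m2$values))
  expect_true(all(mm$values >= 0 & mm$values <= 1))
  expect_error(multiscale_vesselness(v, scales = numeric(0)), "scale")
})

test_that("thin tubes peak at the fine scale, thick tubes at the coarse one", {
  resp <- function(radius, s) {
    # odd grid: centerline through voxel centers, avoiding half-voxel
    # aliasing of sub-voxel radii
    v <- cylinder_volume(d = 33L, radius = radius)
    vm <- multiscale_vesselness(v, scales = s, c = 50)
    median(vm$values[17, 17, 10:24])
  }
  # gamma-normalized response peaks near s = r, so radii on either side of
  # the two working scales separate cleanly
  expect_gt(resp(0.5, 0.5), resp(0.5, 1.0))
  expect_gt(resp(1.8, 1.0), resp(1.8, 0.5))
})

test_that("vesselness is invariant to intensity shifts", {
  set.seed(16)
  v <- array(rnorm(20^3, 50, 10), c(20, 20, 20))
  a <- multiscale_vesselness(v)$values
  b <- multiscale_vesselness(v + 500)$values
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("vesselness is equivariant under 90-degree rotation", {
  v <- cylinder_volume(radius = 1.2, axis = 3L)
  vz <- multiscale_vesselness(v)$values
  vx <- multiscale_vesselness(rot_z_to_x(v))$values
  expect_equal(vx, rot_z_to_x(vz), tolerance = 1e-8)
})

test_that("thresholding and the sweep utility behave at the extremes", {
  v <- cylinder_volume(radius = 1)
  vm <- multiscale_vesselness(v)
  expect_equal(sum(threshold_segment(vm, 1)), 0L)
  expect_gt(sum(threshold_segment(vm, 0)), 0L)
  expect_error(threshold_segment(vm, 1.2), "tau")
  msk <- array(FALSE, dim(v)); msk[1:16, , ] <- TRUE
  seg <- threshold_segment(vm, 0.1, mask = msk)
  expect_equal(sum(seg[17:32, , ]), 0L)

  truth <- v > 30
  sw <- sweep_threshold(vm, truth, taus = seq(0.05, 0.9, by = 0.05))
  expect_equal(nrow(sw$curve), 18L)
  expect_equal(sw$best$DSC, max(sw$curve$DSC))
  expect_equal(sw$best_tau, sw$curve$tau[which.max(sw$curve$DSC)])
})

test_that("tube voxels score far above background on the default phantom", {
  ratios <- sapply(41:43, function(s) {
    ph <- generate_phantom(phantom_spec(dims = c(48, 48, 48), n_tubes = 6,
                                        seed = s))
    vm <- multiscale_vesselness(ph$noisy)
    mean(vm$values[ph$truth]) / mean(vm$values[!ph$truth])
  })
  expect_gt(mean(ratios), 5)
})
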