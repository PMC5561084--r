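test_that("order-8 Haar matrix has the published entries", {
  H <- haar_matrix(8)
  r8 <- 1 / sqrt(8); r4 <- 1 / sqrt(4); r2 <- 1 / sqrt(2)
  expected <- rbind(
    rep(r8, 8),
    c(rep(r8, 4), rep(-r8, 4)),
    c(r4, r4, -r4, -r4, 0, 0, 0, 0),
    c(0, 0, 0, 0, r4, r4, -r4, -r4),
    c(r2, -r2, 0, 0, 0, 0, 0, 0),
    c(0, 0, r2, -r2, 0, 0, 0, 0),
    c(0, 0, 0, 0, r2, -r2, 0, 0),
    c(0, 0, 0, 0, 0, 0, r2, -r2))
  expect_equal(H, expected, tolerance = 1e-15)
})

test_that("order-2 Haar matrix matches the recursive construction by hand", {
  expect_equal(haar_matrix(2),
               matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE) / sqrt(2),
               tolerance = 1e-15)
})

test_that("Haar matrices are orthonormal for every supported order", {
  for (K in c(2L, 4L, 8L, 16L, 32L)) {
    H <- haar_matrix(K)
    expect_lt(max(abs(H %*% t(H) - diag(K))), 1e-12)
  }
  expect_error(haar_matrix(6), "power of two")
  expect_error(haar_matrix(0), "power of two")
})

test_that("forward transform of a default group yields exactly K subbands", {
  set.seed(1)
  v <- array(rnorm(15^3), c(15, 15, 15))
  cfg <- enhance_config()
  g <- extract_cube_group(v, c(2L, 2L, 2L), cfg)
  s <- forward_transform(g)
  expect_equal(ncol(s$cubes), 8L)
  expect_s3_class(s, "subband_stack")
})

test_that("constant groups put everything in the DC subband", {
  cfg <- enhance_config()
  v <- array(3.5, c(12, 12, 12))
  g <- extract_cube_group(v, c(2L, 2L, 2L), cfg)
  expect_true(all(g$cubes == 3.5))
  s <- forward_transform(g)
  expect_equal(unname(s$cubes[, 1]), rep(3.5 * sqrt(8), 7^3))
  expect_lt(max(abs(s$cubes[, 2:8])), 1e-12)
})

test_that("cube extraction equals direct slicing at each offset", {
  cfg <- enhance_config()
  v <- array(0, c(16, 16, 16))
  v[] <- slice.index(v, 1) # ramp in x
  ref <- c(3L, 4L, 5L)
  g <- extract_cube_group(v, ref, cfg)
  expect_equal(g$corners[1, ], ref) # offset (0,0,0) is the reference cube
  for (j in 1:8) {
    cj <- g$corners[j, ]
    direct <- v[cj[1]:(cj[1] + 6), cj[2]:(cj[2] + 6), cj[3]:(cj[3] + 6)]
    expect_equal(g$cubes[, j], as.vector(direct))
  }
  expect_error(extract_cube_group(v, c(15L, 1L, 1L), cfg), "bounds")
})

test_that("forward transform matches a direct matrix-vector product per voxel", {
  set.seed(7)
  cfg <- enhance_config(cube_size = 3L)
  v <- array(rnorm(12^3), c(12, 12, 12))
  g <- extract_cube_group(v, c(4L, 4L, 4L), cfg)
  s <- forward_transform(g)
  H <- haar_matrix(8)
  for (pos in c(1L, 14L, 27L))
    expect_equal(s$cubes[pos, ], as.vector(H %*% g$cubes[pos, ]))
})

test_that("inverse transform undoes the forward transform", {
  set.seed(2)
  cfg <- enhance_config(cube_size = 4L)
  v <- array(rnorm(14^3), c(14, 14, 14))
  for (i in 1:100) {
    ref <- c(sample(1:9, 1), sample(1:9, 1), sample(1:9, 1))
    g <- extract_cube_group(v, as.integer(ref), cfg)
    s <- forward_transform(g)
    back <- inverse_transform(s)
    expect_lt(max(abs(back$cubes - g$cubes)), 1e-10)
  }
})

test_that("DC-only stacks reconstruct constant cubes", {
  cfg <- enhance_config()
  g <- extract_cube_group(array(1, c(12, 12, 12)), c(2L, 2L, 2L), cfg)
  s <- forward_transform(g)
  s$cubes[] <- 0
  s$cubes[, 1] <- sqrt(8)
  back <- inverse_transform(s)
  expect_equal(back$cubes, matrix(1, 7^3, 8))
  expect_error(inverse_transform(forward_transform(g), haar_matrix(4)),
               "does not match")
})

test_that("transform conserves energy and subband 1 is the scaled group mean", {
  set.seed(3)
  cfg <- enhance_config(cube_size = 5L)
  v <- array(rnorm(16^3, 10, 4), c(16, 16, 16))
  g <- extract_cube_group(v, c(4L, 5L, 6L), cfg)
  s <- forward_transform(g)
  expect_equal(rowSums(s$cubes^2), rowSums(g$cubes^2), tolerance = 1e-8)
  expect_equal(s$cubes[, 1], sqrt(8) * rowMeans(g$cubes), tolerance = 1e-12)
})

test_that("aggregation averages overlapping cubes and copies isolated ones", {
  n <- 3L
  mk <- function(vals, corner) {
    cube_group(matrix(vals, n^3, 1), matrix(corner, 1, 3), corner, n)
  }
  shape <- c(8L, 8L, 8L)
  solo <- aggregate_cubes(list(mk(rep(2, n^3), c(2L, 2L, 2L))), shape)
  expect_equal(solo[2:4, 2:4, 2:4], array(2, c(3, 3, 3)))
  expect_equal(solo[1, 1, 1], 0)

  two <- aggregate_cubes(list(mk(rep(1, n^3), c(1L, 1L, 1L)),
                              mk(rep(5, n^3), c(2L, 1L, 1L))), shape)
  expect_equal(two[2:3, 1:3, 1:3], array(3, c(2, 3, 3))) # overlap -> (1+5)/2
  expect_equal(two[1, 1, 1], 1)
  expect_equal(two[4, 2, 2], 5)
  expect_error(aggregate_cubes(list(), shape), "no cube groups")
})

test_that("full tiling with pass-through mapping reproduces the input", {
  set.seed(4)
  v <- array(rnorm(30^3, 100, 20), c(30, 30, 30))
  out <- enhance_volume(v, enhance_config(), mapping = "identity")
  expect_lt(max(abs(out - v)) / max(abs(v)), 1e-8)

  const <- enhance_volume(array(5, c(20, 20, 20)), enhance_config(),
                          mapping = "identity")
  expect_equal(const, array(5, c(20, 20, 20)), tolerance = 1e-12)
})

test_that("the corner offset set is a valid alternative group geometry", {
  offs <- offset_set(8L, "corners")
  expect_equal(dim(offs), c(8L, 3L))
  expect_true(all(abs(offs) == 1L))
  cfg <- enhance_config(offset_set = offs)
  v <- array(rnorm(25^3), c(25, 25, 25))
  out <- enhance_volume(v, cfg, mapping = "identity")
  expect_lt(max(abs(out - v)) / max(abs(v)), 1e-8)
})
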