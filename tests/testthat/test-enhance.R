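test_that("config validation enforces threshold and gain ordering", {
  expect_error(enhance_config(T1 = 50, T2 = 110, T3 = 150), "T1 > T2 > T3")
  expect_error(enhance_config(T3 = -1), "T1 > T2 > T3")
  expect_error(enhance_config(gamma1 = 5, gamma2 = 10), "gamma1 >= gamma2")
  expect_error(enhance_config(K = 6), "power of two")
  expect_error(enhance_config(cube_size = 1), "cube_size")
  cfg <- enhance_config()
  expect_equal(c(cfg$T1, cfg$T2, cfg$T3), c(150, 110, 50))
  expect_equal(c(cfg$gamma1, cfg$gamma2), c(24, 12))
  expect_equal(cfg$step, 7L)
})

test_that("coefficient mapping reproduces each branch", {
  cfg <- enhance_config()
  expect_equal(map_coefficient(200, cfg), 200)        # strong edge: identity
  expect_equal(map_coefficient(-120, cfg), -2880)     # gamma1 branch
  expect_equal(map_coefficient(60, cfg), 720)         # gamma2 branch
  expect_equal(map_coefficient(30, cfg), 0)           # noise floor
  # boundaries: |c| = T2 and |c| = T1 belong to gamma1; |c| = T3 suppressed
  expect_equal(map_coefficient(c(110, 150, -110, -150), cfg),
               c(2640, 3600, -2640, -3600))
  expect_equal(map_coefficient(c(50, -50), cfg), c(0, 0))
})

test_that("mapping agrees with the scalar branch oracle on a dense sweep", {
  cfg <- enhance_config()
  cs <- c(seq(-300, 300, by = 0.25), 49.999, 50.001, 109.999, 110.001,
          149.999, 150.001)
  expect_equal(map_coefficient(cs, cfg), oracle_map(cs))
})

test_that("mapping preserves sign and is piecewise homogeneous", {
  cfg <- enhance_config()
  set.seed(5)
  cs <- runif(500, -400, 400)
  expect_true(all(map_coefficient(cs, cfg) * cs >= 0))
  # scaling within the gamma2 branch (51..109 scaled by factors staying inside)
  c0 <- runif(100, 60, 100)
  lam <- runif(100, 0.9, 1.05)
  inside <- c0 * lam > 50 & c0 * lam < 110
  expect_equal(map_coefficient((c0 * lam)[inside], cfg),
               (lam * map_coefficient(c0, cfg))[inside])
})

test_that("subband mapping is element-wise with optional DC exemption", {
  set.seed(6)
  cfg <- enhance_config()
  g <- extract_cube_group(array(rnorm(16^3, 0, 100), c(16, 16, 16)),
                          c(3L, 3L, 3L), cfg)
  s <- forward_transform(g)
  m <- map_subbands(s, cfg)
  expect_equal(m$cubes, matrix(oracle_map(s$cubes), nrow(s$cubes)))
  cfg_dc <- enhance_config(exempt_dc = TRUE)
  m2 <- map_subbands(s, cfg_dc)
  expect_equal(m2$cubes[, 1], s$cubes[, 1])
  expect_equal(m2$cubes[, 2:8], matrix(oracle_map(s$cubes[, 2:8]), nrow(s$cubes)))
  z <- s; z$cubes[] <- 0
  expect_equal(map_subbands(z, cfg)$cubes, z$cubes)
})

test_that("constant volumes stay constant under enhancement", {
  # DC = 600*sqrt(8) ~ 1697 > T1 -> identity branch; details all zero
  out <- enhance_volume(array(600, c(20, 20, 20)), enhance_config())
  expect_equal(out, array(600, c(20, 20, 20)), tolerance = 1e-12)
  # DC in the gamma1 band: c*sqrt(8) = 120 -> amplified by 24 -> constant * 24
  c0 <- 120 / sqrt(8)
  out2 <- enhance_volume(array(c0, c(20, 20, 20)), enhance_config())
  expect_equal(out2, array(24 * c0, c(20, 20, 20)), tolerance = 1e-10)
  # with exempt_dc the same volume passes through unchanged
  out3 <- enhance_volume(array(c0, c(20, 20, 20)),
                         enhance_config(exempt_dc = TRUE))
  expect_equal(out3, array(c0, c(20, 20, 20)), tolerance = 1e-10)
})

test_that("sub-threshold perturbations are erased (zero noise floor)", {
  base <- array(600, c(21, 21, 21))
  # mean-free alternating perturbation: every cube group sees +a/-a in equal
  # numbers, so the DC subband is untouched while every detail coefficient
  # has magnitude < sqrt(8)*a < T3 and falls in the zero branch
  a <- 10
  pert <- base + a * (-1)^slice.index(base, 1)
  out <- enhance_volume(pert, enhance_config())
  expect_lt(max(abs(out - base)), 1e-9)
  # amplitude large enough to push details past T3 must change the output
  big <- base + 40 * (-1)^slice.index(base, 1)
  expect_gt(max(abs(enhance_volume(big, enhance_config()) - base)), 40)
})

test_that("enhancement is deterministic and rejects undersized volumes", {
  set.seed(9)
  v <- array(rnorm(18^3, 600, 15), c(18, 18, 18))
  expect_identical(enhance_volume(v), enhance_volume(v))
  expect_error(enhance_volume(array(0, c(5, 20, 20))), "smaller than one cube")
})

test_that("enhancement increases tube-to-background contrast on a phantom", {
  ph <- generate_phantom(phantom_spec(dims = c(48, 48, 48), n_tubes = 6,
                                      seed = 21))
  enh <- enhance_volume(ph$noisy)
  before <- mean(ph$noisy$data[ph$truth]) / mean(ph$noisy$data[!ph$truth])
  after <- mean(enh$data[ph$truth]) / mean(enh$data[!ph$truth])
  expect_gt(after, before)
})
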