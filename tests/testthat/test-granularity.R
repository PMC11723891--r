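test_that("scale bank is a sqrt(2) geometric sequence with midpoint edges", {
  bank <- build_scale_bank()
  expect_length(bank$scales_px, 15)
  expect_equal(bank$scales_px[1:3], c(2, 2 * sqrt(2), 4))
  expect_equal(bank$scales_px[15], 256)
  ratios <- bank$scales_px[-1] / bank$scales_px[-15]
  expect_true(all(abs(ratios - sqrt(2)) < 1e-9))
  # edges partition [2, 256] at geometric midpoints
  expect_equal(unname(bank$band_edges_px[1, "lower"]), 2)
  expect_equal(unname(bank$band_edges_px[15, "upper"]), 256)
  expect_equal(unname(bank$band_edges_px[-1, "lower"]),
               unname(bank$band_edges_px[-15, "upper"]))
  expect_equal(unname(bank$band_edges_px[1, "upper"]),
               sqrt(2 * 2 * sqrt(2)))

  single <- build_scale_bank(8, 8)
  expect_equal(single$scales_px, 8)
  expect_error(build_scale_bank(-1, 4), "min_px")
})

test_that("pattern channel averages R and G over the mask bounding box", {
  img <- uniform_image(c(0.4, 0.6, 0.9), h = 8, w = 8)
  pc <- pattern_channel(img, "animal")
  expect_equal(dim(pc$channel), c(8, 4))
  expect_true(all(pc$channel == 0.5))

  # one-pixel mask
  px <- array(runif(3 * 9), dim = c(3, 3, 3))
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  img2 <- reflectance_image(px, 20, masks = list(animal = m))
  pc2 <- pattern_channel(img2, "animal")
  expect_equal(dim(pc2$channel), c(1, 1))
  expect_equal(pc2$channel[1, 1], (px[2, 2, 1] + px[2, 2, 2]) / 2)
})

test_that("band energy localizes a pure sinusoid and vanishes for constants", {
  expect_equal(band_energy(matrix(0.7, 16, 16), c(2, 4)), 0)

  img <- sinusoid_image(wavelength = 16, size = 256, amplitude = 0.2)
  ch <- pattern_channel(img, "animal")$channel
  bank <- build_scale_bank()
  e <- vapply(seq_len(15), function(i)
    band_energy(ch, bank$band_edges_px[i, ], include_upper = i == 15),
    numeric(1))
  k16 <- which.min(abs(bank$scales_px - 16))
  expect_gt(e[k16] / sum(e), 0.999)
  # a real sinusoid of amplitude A has variance A^2/2
  expect_equal(sum(e), 0.2^2 / 2, tolerance = 1e-9)

  set.seed(3)
  noise <- matrix(rnorm(256 * 256), 256, 256)
  en <- vapply(seq_len(15), function(i)
    band_energy(noise, bank$band_edges_px[i, ], include_upper = i == 15),
    numeric(1))
  expect_true(all(en > 0))

  expect_error(band_energy(matrix(0, 8, 8), c(32, 64)), "outside")
})

test_that("band energies satisfy the Parseval identity on noise rasters", {
  bank <- build_scale_bank()
  for (seed in 1:5) {
    set.seed(seed)
    # non-square, non-power-of-two raster exercises the padding path
    x <- matrix(rnorm(96 * 120), 96, 120)
    gs <- granularity_spectrum(x, bank)
    # out-of-bank residual: sub-Nyquist wavelengths < 2 px in the diagonal
    # frequency corner (the padded raster's longest wavelength, 128 px,
    # already lies inside the bank)
    resid <- band_energy(x, c(1, 2))
    v <- mean((x - mean(x))^2)
    expect_equal(sum(gs$energy) + resid, v, tolerance = 1e-6 * v)
  }
})

test_that("band energies are isotropic and scale quadratically with contrast", {
  set.seed(11)
  x <- matrix(rnorm(64 * 64), 64, 64)
  bank <- build_scale_bank(2, 64)
  g1 <- granularity_spectrum(x, bank)
  g_rot <- granularity_spectrum(t(x[nrow(x):1, ]), bank)  # 90 degree rotation
  expect_equal(g_rot$energy, g1$energy, tolerance = 1e-10)

  g2 <- granularity_spectrum(mean(x) + 2 * (x - mean(x)), bank)
  expect_equal(g2$energy, 4 * g1$energy, tolerance = 1e-10)
  expect_equal(g2$dominant_size_px, g1$dominant_size_px)
  expect_equal(g2$diversity, g1$diversity)
})

test_that("granularity descriptors summarize the energy profile", {
  # direct arithmetic on a constructed spectrum through the public API:
  # energies (1, 1, 2) at scales (2, 2.83, 4) give contrast 4, dominant 4,
  # diversity 0.5
  bank3 <- build_scale_bank(2, 4)
  fake <- structure(list(scales_px = bank3$scales_px,
                         band_edges_px = bank3$band_edges_px),
                    class = "scale_bank")
  # build a raster whose band energies are controlled: three sinusoids
  size <- 64
  ph <- outer(rep(1, size), seq_len(size))
  # at the Nyquist wavelength (2 px) a sampled cosine alternates +/-A, so
  # its variance is A^2; away from Nyquist a sinusoid has variance A^2/2
  x <- 1 * cos(pi * ph) +
    sqrt(2) * sin(2 * pi * ph * 11 / 32) +  # wavelength 32/11 = 2.909 px
    2 * sin(2 * pi * ph / 4)
  gs <- granularity_spectrum(x, fake)
  expect_equal(gs$energy, c(1, 1, 2), tolerance = 1e-9)
  expect_equal(gs$overall_contrast, 4, tolerance = 1e-9)
  expect_equal(gs$dominant_size_px, 4)
  expect_equal(gs$diversity, 0.5, tolerance = 1e-9)
  # the of_rest convention: max / (total - max)
  gs2 <- granularity_spectrum(x, fake, diversity = "of_rest")
  expect_equal(gs2$diversity, 1, tolerance = 1e-9)

  # constant region: descriptors are flagged undefined
  g0 <- granularity_spectrum(matrix(0.3, 32, 32))
  expect_true(g0$undefined)
  expect_true(is.na(g0$dominant_size_px))
})

test_that("dominant marking size ties break toward the smallest scale", {
  bank <- build_scale_bank(2, 4)
  size <- 64
  ph <- outer(rep(1, size), seq_len(size))
  x <- cos(pi * ph) + sqrt(2) * cos(2 * pi * ph / 4)  # equal band energies
  gs <- granularity_spectrum(x, bank)
  expect_equal(gs$energy[1], gs$energy[3], tolerance = 1e-9)
  expect_equal(gs$dominant_size_px, 2)
})

test_that("pixel-scale check enforces the 15 px/mm minimum", {
  expect_true(check_pixel_scale(15))
  expect_false(check_pixel_scale(14.9))
  expect_true(check_pixel_scale(300))
  expect_error(check_pixel_scale(0), "positive")
})
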