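test_that("LoG detection finds isolated spots and nothing on blank images", {
  blank <- matrix(5, 64, 64)
  expect_equal(nrow(detect_spots(blank, 4, quality_threshold = 1)), 0)

  op <- noise_free_optics(photons_per_fluorophore = 100, psf_sigma = 1)
  spec <- data.frame(copy_number = c(100, 100), n_spots = 1)
  sc <- make_spot_scene(spec, op, field_size = 64, min_separation = 10,
                        seed = 7)
  det <- detect_spots(sc$images[[1]], 4, quality_threshold = 1)
  expect_equal(nrow(det), 2)
  # centroids within 0.3 px of truth
  for (k in 1:2) {
    d <- min(sqrt((det$x_px - sc$truth$x_px[k])^2 +
                  (det$y_px - sc$truth$y_px[k])^2))
    expect_lt(d, 0.3)
  }
})

test_that("two noise-free spots 10 px apart are resolved", {
  op <- noise_free_optics(psf_sigma = 1)
  img <- matrix(0, 48, 48)
  img <- virocount:::add_gaussian_spot(img, 19, 24, 5000, 1)
  img <- virocount:::add_gaussian_spot(img, 29, 24, 5000, 1)
  det <- detect_spots(img, 4, quality_threshold = 1)
  expect_equal(nrow(det), 2)
  expect_lt(min(abs(det$x_px - 19)), 0.3)
  expect_lt(min(abs(det$x_px - 29)), 0.3)
})

test_that("raising the detection threshold never adds spots", {
  op <- optics_model(psf_sigma = 1)
  sc <- make_spot_scene(data.frame(copy_number = 60, n_spots = 10), op,
                        128, 12, seed = 8)
  img <- sc$images[[1]]
  counts <- vapply(c(0, 5, 20, 100, 1e6),
                   function(th) nrow(detect_spots(img, 4, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0) # above max response: none
})

test_that("detection rejects diameters larger than the image", {
  expect_error(detect_spots(matrix(0, 16, 16), 20), "exceeds")
})

test_that("corrected intensity is exactly zero on any uniform image", {
  for (v in c(0, 7.3, 1000)) {
    m <- measure_corrected_intensity(matrix(v, 32, 32), c(15.2, 16.7))
    expect_equal(m$corrected_intensity, 0, tolerance = 1e-12)
  }
})

test_that("corrected intensity recovers a centred Gaussian spot's flux", {
  # sigma = 1 px: >= 99% of flux inside the 4 px inner radius
  img <- matrix(10, 64, 64) # flat background
  img <- virocount:::add_gaussian_spot(img, 31.4, 30.8, 8000, 1)
  m <- measure_corrected_intensity(img, c(31.4, 30.8))
  expect_lt(abs(m$corrected_intensity - 8000) / 8000, 0.01)
})

test_that("a linear background ramp cancels to first order", {
  op <- noise_free_optics(background_level = 20, background_gradient = 2,
                          psf_sigma = 1, photons_per_fluorophore = 100)
  sc <- make_spot_scene(data.frame(copy_number = 100, n_spots = 1), op,
                        64, 10, seed = 5)
  m <- measure_corrected_intensity(sc$images[[1]],
                                   c(sc$truth$x_px, sc$truth$y_px))
  expect_lt(abs(m$corrected_intensity - 10000) / 10000, 0.02)
})

test_that("doubling the flux doubles the corrected intensity (noise-free)", {
  img1 <- virocount:::add_gaussian_spot(matrix(3, 48, 48), 24, 24, 4000, 1)
  img2 <- virocount:::add_gaussian_spot(matrix(3, 48, 48), 24, 24, 8000, 1)
  m1 <- measure_corrected_intensity(img1, c(24, 24))$corrected_intensity
  m2 <- measure_corrected_intensity(img2, c(24, 24))$corrected_intensity
  expect_lt(abs(m2 / m1 - 2), 0.01)
})

test_that("the annulus formula reproduces brute-force background subtraction", {
  set.seed(11)
  img <- matrix(rpois(64 * 64, 50), 64, 64)
  cen <- c(30.3, 29.6)
  m <- measure_corrected_intensity(img, cen, 8, 10)
  # brute force: subtract the annulus mean from every inner-disc pixel
  inner <- virocount:::disc_pixels(cen[1], cen[2], 8, dim(img))
  outer <- virocount:::disc_pixels(cen[1], cen[2], 10, dim(img))
  key <- function(d) paste(d$x, d$y)
  ann <- outer[!key(outer) %in% key(inner), ]
  bg_mean <- mean(img[cbind(ann$y + 1, ann$x + 1)])
  brute <- sum(img[cbind(inner$y + 1, inner$x + 1)] - bg_mean)
  expect_equal(m$corrected_intensity, brute, tolerance = 1e-9)
  expect_equal(m$area_outer - m$area_inner, nrow(ann))
})

test_that("measurements near the border are flagged invalid", {
  img <- matrix(10, 32, 32)
  m <- measure_corrected_intensity(img, c(2, 16))
  expect_false(m$valid)
  expect_true(is.na(m$corrected_intensity))
})

test_that("pure-noise corrected intensities have zero mean bias", {
  set.seed(12)
  img <- matrix(rpois(400 * 400, 100) +
                  rnorm(400 * 400, 0, 2) + 50, 400, 400)
  xs <- runif(1000, 6, 393); ys <- runif(1000, 6, 393)
  v <- vapply(seq_len(1000), function(k) {
    measure_corrected_intensity(img, c(xs[k], ys[k]))$corrected_intensity
  }, numeric(1))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v)), 3 * se)
})

test_that("crowded spots are flagged when ROIs overlap", {
  spots <- data.frame(x_px = c(20, 27, 45), y_px = c(20, 20, 45))
  img <- matrix(1, 64, 64)
  m <- measure_spots(img, spots)
  expect_equal(m$crowded, c(TRUE, TRUE, FALSE))
})

test_that("channel pairing recovers which virions carry a second marker", {
  # 30 of 100 virions have secondary signal
  op <- optics_model(psf_sigma = 1, photons_per_fluorophore = 100)
  spec <- data.frame(copy_number = c(100, 0), n_spots = c(30, 70),
                     channel = 2)
  sc <- make_spot_scene(spec, op, field_size = 420, min_separation = 14,
                        seed = 13)
  prim <- data.frame(x_px = sc$truth$x_px, y_px = sc$truth$y_px)
  pc <- pair_channels(prim, sc$images[["2"]], snr_threshold = 3)
  agree <- mean(pc$paired == (sc$truth$copy_number > 0))
  expect_gte(agree, 0.95)
  expect_lt(abs(sum(pc$paired) - 30), 4)
})

test_that("pairing is monotone in the SNR threshold and degenerate cases work", {
  prim <- data.frame(x_px = c(20, 40), y_px = c(20, 40))
  zeros <- matrix(0, 64, 64)
  expect_false(any(pair_channels(prim, zeros, snr_threshold = 0.4)$paired))
  expect_true(all(pair_channels(prim, zeros, snr_threshold = -Inf)$paired))
  # spot-table route
  sec <- data.frame(x_px = 21, y_px = 20.5)
  pc <- pair_channels(prim, sec, pairing_radius = 2)
  expect_equal(pc$paired, c(TRUE, FALSE))
  # registration check
  expect_error(pair_channels(prim, matrix(0, 32, 32),
                             primary_image = matrix(0, 64, 64)),
               "registered")
})
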