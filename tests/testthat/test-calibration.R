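# Reference patch colors in linear RGB used throughout: the 24-patch card.
.ref_linear <- function() srgb_to_linear(
  as.matrix(colorchecker_layout()[, c("ref_r", "ref_g", "ref_b")]))

test_that("patch extraction returns per-patch linear means in layout order", {
  layout <- card_layout(tibble::tibble(
    patch_id = c("p1", "p2"),
    x0 = c(0, 8), y0 = c(0, 0), x1 = c(6, 14), y1 = c(6, 6),
    ref_r = c(0.2, 0.6), ref_g = c(0.2, 0.6), ref_b = c(0.2, 0.6)))
  px <- array(0, dim = c(6, 14, 3))
  px[, 1:6, ] <- 0.25
  px[, 9:14, ] <- 0.75
  img <- rgb_image(px, encoding = "linear")
  obs <- extract_patch_colors(img, layout)
  expect_equal(obs$patch_id, c("p1", "p2"))
  expect_equal(obs$r, c(0.25, 0.75), tolerance = 1e-12)
  # swapped layout order swaps the output order
  obs2 <- extract_patch_colors(img, layout[2:1, ])
  expect_equal(obs2$r, c(0.75, 0.25), tolerance = 1e-12)
})

test_that("patch means over noisy patches converge at the 3-sigma LLN rate", {
  set.seed(21)
  v <- 0.5
  n <- 100L
  px <- array(pmin(pmax(v + rnorm(n * n * 3, sd = 0.01), 0), 1),
              dim = c(n, n, 3))
  img <- rgb_image(px, encoding = "linear")
  layout <- card_layout(tibble::tibble(
    patch_id = "p", x0 = 0, y0 = 0, x1 = n, y1 = n,
    ref_r = v, ref_g = v, ref_b = v))
  obs <- extract_patch_colors(img, layout)
  expect_true(all(abs(c(obs$r, obs$g, obs$b) - v) < 3 * 0.01 / n))
})

test_that("patch extraction enforces bounds and minimum size", {
  img <- rgb_image(array(0.5, dim = c(10, 10, 3)))
  out <- card_layout(tibble::tibble(patch_id = "p", x0 = 5, y0 = 5,
                                    x1 = 12, y1 = 12,
                                    ref_r = 0.5, ref_g = 0.5, ref_b = 0.5))
  expect_error(extract_patch_colors(img, out), "outside the image")
  small <- card_layout(tibble::tibble(patch_id = "p", x0 = 0, y0 = 0,
                                      x1 = 4, y1 = 4,
                                      ref_r = 0.5, ref_g = 0.5, ref_b = 0.5))
  expect_error(extract_patch_colors(img, small), "at least 25 pixels")
})

test_that("overlapping patch rectangles are rejected at layout construction", {
  expect_error(card_layout(tibble::tibble(
    patch_id = c("a", "b"), x0 = c(0, 3), y0 = c(0, 3), x1 = c(6, 9),
    y1 = c(6, 9), ref_r = 0.5, ref_g = 0.5, ref_b = 0.5)), "overlap")
})

test_that("fitting clean reference patches returns the identity", {
  ref <- .ref_linear()
  corr <- fit_color_correction(ref, ref)
  expect_equal(corr$matrix, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(corr$offset, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(corr$fit_residual, 1e-9)
})

test_that("known affine corruptions are recovered exactly", {
  ref <- .ref_linear()
  set.seed(31)
  for (rep in 1:100) {
    cast <- random_cast()
    observed <- ref %*% t(cast$matrix) +
      matrix(cast$offset, nrow(ref), 3, byrow = TRUE)
    corr <- fit_color_correction(observed, ref)
    restored <- observed %*% t(corr$matrix) +
      matrix(corr$offset, nrow(ref), 3, byrow = TRUE)
    expect_lt(max(abs(restored - ref)), 1e-9)
  }
})

test_that("rank-deficient patch sets are rejected with a named deficiency", {
  gray <- matrix(rep(seq(0.1, 0.9, length.out = 6), 3), ncol = 3)
  expect_error(fit_color_correction(gray, gray), "rank-deficient")
})

test_that("noisy fits report a residual matching the brute-force RMS", {
  ref <- .ref_linear()
  set.seed(41)
  cast <- random_cast()
  observed <- ref %*% t(cast$matrix) +
    matrix(cast$offset, nrow(ref), 3, byrow = TRUE) +
    matrix(rnorm(length(ref), sd = 0.005), nrow(ref), 3)
  corr <- fit_color_correction(observed, ref)
  pred <- observed %*% t(corr$matrix) +
    matrix(corr$offset, nrow(ref), 3, byrow = TRUE)
  expect_equal(corr$fit_residual, sqrt(mean((pred - ref)^2)),
               tolerance = 1e-12)
  expect_lt(corr$fit_residual, 0.01)
})

test_that("applying corrections transforms pixels as the affine map dictates", {
  px <- random_srgb(48, seed = 51)
  img <- rgb_image(array(px, dim = c(48, 1, 3)))
  # identity leaves the image unchanged
  out <- apply_correction(img, identity_correction())
  expect_equal(unclass(out), unclass(img), tolerance = 1e-6,
               ignore_attr = TRUE)
  # offset-only map shifts every linear pixel by the offset before clipping
  off <- structure(list(matrix = diag(3), offset = c(0.05, -0.02, 0.01),
                        fit_residual = 0, n_patches = NA_integer_),
                   class = "color_correction")
  shifted <- apply_correction(img, off)
  lin0 <- srgb_to_linear(px)
  lin1 <- srgb_to_linear(matrix(shifted, ncol = 3))
  want <- sweep(lin0, 2, off$offset, "+")
  want[want < 0] <- 0
  want[want > 1] <- 1
  expect_equal(lin1, want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("card calibration recovers true colors from a casted photograph", {
  cast <- list(matrix = diag(c(1.12, 0.92, 1.05)), offset = c(0.02, -0.015, 0.01))
  spec <- skin_image_spec(seed = 77, cast = cast)
  syn <- generate_skin_image(spec)
  obs <- extract_patch_colors(syn$image, syn$card)
  corr <- fit_color_correction(obs, syn$card)
  res <- analyze_image(syn$image, syn$areas$irradiated, syn$areas$control,
                       correction = corr)
  got <- as.matrix(res$summaries[, c("mean_L", "mean_a", "mean_b")])
  want <- as.matrix(syn$truth$summaries[, c("mean_L", "mean_a", "mean_b")])
  expect_lt(max(abs(got - want)), 1)
  # without calibration the same measurement is badly biased
  raw <- analyze_image(syn$image, syn$areas$irradiated, syn$areas$control)
  raw_err <- max(abs(as.matrix(raw$summaries[, c("mean_L", "mean_a", "mean_b")]) - want))
  expect_gt(raw_err, 1)
})

test_that("color corrections survive a JSON round trip", {
  set.seed(61)
  ref <- .ref_linear()
  cast <- random_cast()
  corr <- fit_color_correction(
    ref %*% t(cast$matrix) + matrix(cast$offset, nrow(ref), 3, byrow = TRUE),
    ref)
  f <- withr::local_tempfile(fileext = ".json")
  write_color_correction(corr, f)
  back <- read_color_correction(f)
  expect_equal(back$matrix, corr$matrix, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$offset, corr$offset, tolerance = 1e-12)
})

test_that("card layouts load from JSON and YAML configs", {
  demo <- system.file("extdata", "colorchecker_card.json", package = "sevtools")
  lay <- read_card_layout(demo)
  expect_s3_class(lay, "card_layout")
  expect_equal(nrow(lay), 24)
  # must match the card geometry of the default synthetic photograph
  want <- generate_skin_image(skin_image_spec(seed = 1))$card
  expect_equal(lay$x0, want$x0)
  expect_equal(lay$ref_r, want$ref_r, tolerance = 1e-7)
  # same layout via YAML
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(patches = list(
    list(id = "p1", rect = c(0, 0, 6, 6), ref = c(0.2, 0.3, 0.4)),
    list(id = "p2", rect = c(8, 0, 14, 6), ref = c(0.5, 0.6, 0.7)))), f)
  ly <- read_card_layout(f)
  expect_equal(ly$patch_id, c("p1", "p2"))
  expect_equal(ly$ref_g, c(0.3, 0.6))
})
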