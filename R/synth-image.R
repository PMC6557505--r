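# Synthetic skin photographs with known ground truth.
#
# The generator emulates the measurement situation: a baseline skin tone
# near the cohort's control means, a spatially inhomogeneous erythema field
# that raises a* and lowers L* inside the "irradiated" region, per-pixel Lab
# noise, an optional global color cast in linear RGB, and a rendered
# reference card with known patch colors. Every stochastic element sits
# behind one mandatory seed, so any spec renders bit-identically.

# Run code under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-normalized truncated Gaussian smoothing matrix (n x n).
.smooth_mat <- function(n, sigma) {
  half <- ceiling(3 * sigma)
  S <- matrix(0, n, n)
  for (o in -half:half) {
    w <- stats::dnorm(o, sd = sigma)
    i <- seq_len(n)
    i <- i[i + o >= 1 & i + o <= n]
    if (length(i)) S[cbind(i, i + o)] <- w
  }
  S / rowSums(S)
}

#' Specify a synthetic skin photograph
#'
#' Defaults place the baseline tone at the control-skin means of a breast
#' radiotherapy cohort (L* = 66.66, a* = 6.91, b* = 16.53) and size the
#' erythema field so that the irradiated-area means land near the
#' post-radiotherapy values (L* = 58.60, a* = 12.83): the smoothed field is
#' rescaled to `[0, 1]`, so a peak amplitude of twice the intended mean
#' shift yields approximately that mean shift.
#'
#' @param baseline_lab Length-3 baseline skin color `(L*, a*, b*)`.
#' @param erythema_amplitude Peak increase of a* at the center of the
#'   erythema field (field values span `[0, 1]`).
#' @param erythema_l_drop Peak decrease of L*, co-varying with the redness
#'   field (erythema and pigmentation travel together).
#' @param field_smoothness Correlation length (Gaussian sigma, pixels) of
#'   the erythema field; `0` makes the field spatially uniform (value 1), so
#'   the amplitudes become exact uniform shifts.
#' @param pixel_noise_sd Per-channel Lab noise SD added to every skin pixel.
#' @param cast Optional global color corruption: a `color_correction`-style
#'   object or `list(matrix = 3 x 3, offset = length 3)` applied in linear
#'   RGB to the rendered image (card included).
#' @param include_card Render a 24-patch reference card strip at the bottom.
#' @param image_size `c(H, W)` in pixels.
#' @param seed Mandatory integer seed.
#' @return A `skin_image_spec` list.
#' @export
skin_image_spec <- function(baseline_lab = c(66.66, 6.91, 16.53),
                            erythema_amplitude = 11.8,
                            erythema_l_drop = 16.1,
                            field_smoothness = 8,
                            pixel_noise_sd = 1.0,
                            cast = NULL,
                            include_card = TRUE,
                            image_size = c(120L, 128L),
                            seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(baseline_lab) != 3L || baseline_lab[1] <= 0 || baseline_lab[1] >= 100) {
    stop("baseline L* must lie in (0, 100)", call. = FALSE)
  }
  if (erythema_amplitude < 0 || erythema_l_drop < 0) {
    stop("erythema amplitudes must be nonnegative", call. = FALSE)
  }
  if (baseline_lab[1] - erythema_l_drop < 0) {
    stop("erythema_l_drop would push L* below 0", call. = FALSE)
  }
  if (!is.null(cast)) {
    if (is.null(cast$matrix) || is.null(cast$offset)) {
      stop("`cast` must have elements `matrix` (3 x 3) and `offset` (length 3)",
           call. = FALSE)
    }
  }
  image_size <- as.integer(image_size)
  min_w <- if (include_card) 126L else 16L
  if (image_size[1] < (if (include_card) 60L else 8L) || image_size[2] < min_w) {
    stop("image too small for the requested layout", call. = FALSE)
  }
  structure(
    list(baseline_lab = as.numeric(baseline_lab),
         erythema_amplitude = erythema_amplitude,
         erythema_l_drop = erythema_l_drop,
         field_smoothness = field_smoothness,
         pixel_noise_sd = pixel_noise_sd,
         cast = cast, include_card = include_card,
         image_size = image_size, seed = as.integer(seed)),
    class = "skin_image_spec"
  )
}

#' Generate a synthetic skin photograph with ground truth
#'
#' Builds the ground-truth CIELAB scene (baseline tone + smoothed seeded
#' erythema field + pixel noise), renders it to sRGB, overlays the reference
#' card, applies the optional cast, and returns the image together with the
#' measurement-area masks and every ground-truth quantity a pipeline test
#' needs.
#'
#' @param spec A [skin_image_spec].
#' @return A `synthetic_skin_image` list: `image` (rendered [rgb_image]),
#'   `lab_truth` (pre-render [lab_image] of the scene), `areas` (list with
#'   `irradiated` and `control` [measurement_area]s), `card` (the
#'   [card_layout] or `NULL`), `truth` (list: `summaries` tibble,
#'   `sev_irradiated`, `sev_control`, `delta_sev`), `spec`.
#' @export
generate_skin_image <- function(spec) {
  stopifnot(inherits(spec, "skin_image_spec"))
  H <- spec$image_size[1]
  W <- spec$image_size[2]

  # geometry: optional card strip at the bottom, skin above it split into
  # left (irradiated) and right (control) halves
  card <- NULL
  skin_h <- H
  if (spec$include_card) {
    patch_px <- 8L; gap_px <- 2L; margin <- 4L
    card_h <- 2L * patch_px + gap_px          # 2 x 12 grid
    card <- colorchecker_layout(
      origin = c(margin, H - card_h - margin),
      patch_px = patch_px, gap_px = gap_px, nrow_card = 2L)
    skin_h <- H - card_h - 2L * margin
  }
  half <- W %/% 2L
  mask_irr <- matrix(FALSE, H, W)
  mask_ctl <- matrix(FALSE, H, W)
  mask_irr[seq_len(skin_h), seq_len(half - 1L)] <- TRUE
  mask_ctl[seq_len(skin_h), (half + 2L):W] <- TRUE

  lab <- .with_seed(spec$seed, {
    field <- if (spec$field_smoothness > 0) {
      z <- matrix(stats::rnorm(H * W), H, W)
      z <- .smooth_mat(H, spec$field_smoothness) %*% z %*%
        t(.smooth_mat(W, spec$field_smoothness))
      (z - min(z)) / (max(z) - min(z))
    } else {
      matrix(1, H, W)
    }
    L <- matrix(spec$baseline_lab[1], H, W)
    a <- matrix(spec$baseline_lab[2], H, W)
    b <- matrix(spec$baseline_lab[3], H, W)
    L[mask_irr] <- L[mask_irr] - spec$erythema_l_drop * field[mask_irr]
    a[mask_irr] <- a[mask_irr] + spec$erythema_amplitude * field[mask_irr]
    if (spec$pixel_noise_sd > 0) {
      L <- L + matrix(stats::rnorm(H * W, sd = spec$pixel_noise_sd), H, W)
      a <- a + matrix(stats::rnorm(H * W, sd = spec$pixel_noise_sd), H, W)
      b <- b + matrix(stats::rnorm(H * W, sd = spec$pixel_noise_sd), H, W)
      L[L < 0] <- 0
      L[L > 100] <- 100
    }
    lab_image(L, a, b)
  })

  img <- lab_to_rgb(lab)
  if (!is.null(card)) {
    px <- unclass(img)
    for (i in seq_len(nrow(card))) {
      rows <- (card$y0[i] + 1L):card$y1[i]
      cols <- (card$x0[i] + 1L):card$x1[i]
      px[rows, cols, 1] <- card$ref_r[i]
      px[rows, cols, 2] <- card$ref_g[i]
      px[rows, cols, 3] <- card$ref_b[i]
    }
    img <- rgb_image(px, encoding = "srgb")
  }
  if (!is.null(spec$cast)) {
    cst <- structure(list(matrix = spec$cast$matrix,
                          offset = spec$cast$offset,
                          fit_residual = 0, n_patches = NA_integer_),
                     class = "color_correction")
    img <- apply_correction(img, cst)
  }

  areas <- list(irradiated = measurement_area(mask_irr, "irradiated"),
                control = measurement_area(mask_ctl, "control"))
  sev_irr <- sev_map(lab, areas$irradiated)
  sev_ctl <- sev_map(lab, areas$control)
  structure(
    list(image = img, lab_truth = lab, areas = areas, card = card,
         truth = list(
           summaries = summarize_areas(lab, areas),
           sev_irradiated = sev_irr$mean_sev,
           sev_control = sev_ctl$mean_sev,
           delta_sev = delta_sev(sev_irr, sev_ctl)$value),
         spec = spec),
    class = "synthetic_skin_image"
  )
}

#' @export
print.synthetic_skin_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<synthetic_skin_image> %d x %d, seed %d\n",
              d[1], d[2], x$spec$seed))
  cat(sprintf("  true mean SEV: irradiated %.1f, control %.1f, delta %.1f\n",
              x$truth$sev_irradiated, x$truth$sev_control,
              x$truth$delta_sev))
  invisible(x)
}
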