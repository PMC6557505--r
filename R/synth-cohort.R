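# Synthetic patient cohorts with known ground truth.
#
# Each patient gets a baseline skin tone drawn from the cohort tone
# distribution, an arm-specific erythema effect (additive shifts of the
# irradiated-area means with between-patient scatter), summaries either
# computed analytically from the sampled Lab means (fast mode) or measured
# by the full image pipeline on rendered photographs, and CTCAE grades from
# two simulated observers who threshold the true Delta-SEV with
# observer-specific offsets plus categorical noise.

#' Specify a synthetic patient cohort
#'
#' Defaults emulate a 100-patient breast radiotherapy cohort: 66 patients
#' in the `bepanthen` arm and 34 in the `r1r2` arm; baseline tones
#' distributed as L* 66.66 (SD 6.99), a* 6.91 (SD 3.16), b* 16.53 (SD 4.75);
#' arm effects sized so the irradiated-area means land near a* 11.4 (SD 4.0)
#' under bepanthen versus 15.6 (SD 4.9) under r1r2, with a common L* drop of
#' about 8 units and no arm difference in L*.
#'
#' @param n_per_arm Named integer vector of patients per arm (>= 2 each).
#' @param baseline_mean,baseline_sd Length-3 mean and between-patient SD of
#'   the baseline `(L*, a*, b*)` tone distribution.
#' @param arm_effects Data frame with one row per arm: `arm`, `d_L`, `d_a`,
#'   `d_b` (mean additive shift of the irradiated means relative to the
#'   patient's own baseline) and `d_L_sd`, `d_a_sd`, `d_b_sd`
#'   (between-patient SDs of those shifts).
#' @param within_sd Within-area per-channel pixel SD reported in analytic
#'   mode (emulating pixel noise).
#' @param grade_thresholds Increasing Delta-SEV cutpoints between CTCAE
#'   grades (length k gives grades 1..k+1).
#' @param observer_offsets Length-2 additive threshold offsets of the two
#'   simulated observers (a positive offset makes an observer stricter,
#'   i.e. grade lower).
#' @param grade_noise Probability that an observer mis-grades by one grade.
#' @param fitzpatrick_probs Named probabilities of Fitzpatrick skin types.
#' @param seed Mandatory integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_arm = c(bepanthen = 66L, r1r2 = 34L),
                        baseline_mean = c(66.66, 6.91, 16.53),
                        baseline_sd = c(6.99, 3.16, 4.75),
                        arm_effects = tibble::tibble(
                          arm = c("bepanthen", "r1r2"),
                          d_L = c(-8.06, -8.06), d_L_sd = c(3.0, 3.0),
                          d_a = c(4.83, 8.04), d_a_sd = c(2.5, 3.7),
                          d_b = c(-2.8, -0.1), d_b_sd = c(1.5, 1.5)),
                        within_sd = 1.0,
                        grade_thresholds = c(250, 550),
                        observer_offsets = c(0, 150),
                        grade_noise = 0.1,
                        fitzpatrick_probs = c("2" = 0.32, "3" = 0.60, "4" = 0.08),
                        seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (any(n_per_arm < 2L)) stop("every arm needs n >= 2", call. = FALSE)
  if (is.null(names(n_per_arm))) {
    stop("`n_per_arm` must be named by arm", call. = FALSE)
  }
  if (any(baseline_sd < 0) || any(c(arm_effects$d_L_sd, arm_effects$d_a_sd,
                                    arm_effects$d_b_sd) < 0)) {
    stop("SDs must be nonnegative", call. = FALSE)
  }
  if (!all(names(n_per_arm) %in% arm_effects$arm)) {
    stop("`arm_effects` must cover every arm in `n_per_arm`", call. = FALSE)
  }
  if (is.unsorted(grade_thresholds, strictly = TRUE)) {
    stop("`grade_thresholds` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(n_per_arm = n_per_arm, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, arm_effects = tibble::as_tibble(arm_effects),
         within_sd = within_sd, grade_thresholds = grade_thresholds,
         observer_offsets = observer_offsets, grade_noise = grade_noise,
         fitzpatrick_probs = fitzpatrick_probs, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Observer grading model: threshold the true Delta-SEV at offset-shifted
# cutpoints, then flip by one grade with probability `noise`.
.simulate_grades <- function(dsev, thresholds, offset, noise) {
  grade <- 1L + vapply(dsev, function(d) sum(d > thresholds + offset),
                       integer(1))
  flip <- stats::runif(length(grade)) < noise
  dir <- sample(c(-1L, 1L), length(grade), replace = TRUE)
  grade[flip] <- grade[flip] + dir[flip]
  pmin(pmax(grade, 1L), length(thresholds) + 1L)
}

#' Generate a synthetic patient cohort
#'
#' In the default `"analytic"` mode the per-patient color summaries are the
#' sampled Lab means (uniform-field equivalence: for a spatially uniform
#' area, the per-pixel mean SEV equals the SEV of the mean color, so
#' Delta-SEV is computed in closed form). In `"render"` mode every patient
#' is given a small rendered photograph (uniform erythema, pixel noise, no
#' card) and the summaries are measured by the actual image pipeline.
#'
#' @param spec A [cohort_spec].
#' @param mode `"analytic"` (fast, exact means) or `"render"` (full image
#'   pipeline per patient).
#' @param image_size Image size used per patient in `"render"` mode.
#' @return A tibble with one row per patient: `patient_id`, `arm`,
#'   `fitzpatrick`, `mean_L_ctrl` ... `mean_b_irr`, `sd_*` columns,
#'   `sev_irr`, `sev_ctrl`, `delta_sev`, `grade_obs1`, `grade_obs2`. The
#'   `"truth"` attribute holds the spec and the per-patient true shifts.
#' @export
generate_cohort <- function(spec, mode = c("analytic", "render"),
                            image_size = c(60L, 64L)) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  arms <- rep(names(spec$n_per_arm), spec$n_per_arm)
  n <- length(arms)
  eff <- spec$arm_effects[match(arms, spec$arm_effects$arm), ]

  .with_seed(spec$seed, {
    base_L <- pmin(pmax(stats::rnorm(n, spec$baseline_mean[1], spec$baseline_sd[1]), 1), 99)
    base_a <- stats::rnorm(n, spec$baseline_mean[2], spec$baseline_sd[2])
    base_b <- stats::rnorm(n, spec$baseline_mean[3], spec$baseline_sd[3])
    d_L <- stats::rnorm(n, eff$d_L, eff$d_L_sd)
    d_a <- stats::rnorm(n, eff$d_a, eff$d_a_sd)
    d_b <- stats::rnorm(n, eff$d_b, eff$d_b_sd)
    d_L <- pmax(d_L, 1 - base_L)   # keep irradiated L* >= 1
    fitz <- sample(as.integer(names(spec$fitzpatrick_probs)), n,
                   replace = TRUE, prob = spec$fitzpatrick_probs)

    irr_L <- base_L + d_L
    irr_a <- base_a + d_a
    irr_b <- base_b + d_b

    if (mode == "analytic") {
      sev_ctrl <- (100 - base_L) * base_a
      sev_irr <- (100 - irr_L) * irr_a
      sums <- tibble::tibble(
        mean_L_ctrl = base_L, mean_a_ctrl = base_a, mean_b_ctrl = base_b,
        sd_L_ctrl = spec$within_sd, sd_a_ctrl = spec$within_sd,
        sd_b_ctrl = spec$within_sd,
        mean_L_irr = irr_L, mean_a_irr = irr_a, mean_b_irr = irr_b,
        sd_L_irr = spec$within_sd, sd_a_irr = spec$within_sd,
        sd_b_irr = spec$within_sd
      )
    } else {
      per_patient <- purrr::map(seq_len(n), function(i) {
        im_spec <- skin_image_spec(
          baseline_lab = c(base_L[i], base_a[i], base_b[i]),
          erythema_amplitude = max(d_a[i], 0),
          erythema_l_drop = max(-d_L[i], 0),
          field_smoothness = 0,                 # uniform: sampled means exact
          pixel_noise_sd = spec$within_sd,
          include_card = FALSE, image_size = image_size,
          seed = sample.int(.Machine$integer.max, 1L))
        syn <- generate_skin_image(im_spec)
        lab <- rgb_to_lab(syn$image)
        s <- summarize_areas(lab, syn$areas)
        sv_i <- sev_map(lab, syn$areas$irradiated)
        sv_c <- sev_map(lab, syn$areas$control)
        list(s = s, sev_irr = sv_i$mean_sev, sev_ctrl = sv_c$mean_sev)
      })
      wide <- purrr::map_dfr(per_patient, function(p) {
        s <- p$s
        i <- which(s$label == "irradiated")
        c0 <- which(s$label == "control")
        tibble::tibble(
          mean_L_ctrl = s$mean_L[c0], mean_a_ctrl = s$mean_a[c0],
          mean_b_ctrl = s$mean_b[c0], sd_L_ctrl = s$sd_L[c0],
          sd_a_ctrl = s$sd_a[c0], sd_b_ctrl = s$sd_b[c0],
          mean_L_irr = s$mean_L[i], mean_a_irr = s$mean_a[i],
          mean_b_irr = s$mean_b[i], sd_L_irr = s$sd_L[i],
          sd_a_irr = s$sd_a[i], sd_b_irr = s$sd_b[i]
        )
      })
      sums <- wide
      sev_irr <- purrr::map_dbl(per_patient, "sev_irr")
      sev_ctrl <- purrr::map_dbl(per_patient, "sev_ctrl")
    }

    dsev <- sev_irr - sev_ctrl
    true_dsev <- (100 - irr_L) * irr_a - (100 - base_L) * base_a
    g1 <- .simulate_grades(true_dsev, spec$grade_thresholds,
                           spec$observer_offsets[1], spec$grade_noise)
    g2 <- .simulate_grades(true_dsev, spec$grade_thresholds,
                           spec$observer_offsets[2], spec$grade_noise)

    cohort <- dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%03d", seq_len(n)), arm = arms,
                     fitzpatrick = fitz),
      sums,
      tibble::tibble(sev_irr = sev_irr, sev_ctrl = sev_ctrl,
                     delta_sev = dsev, grade_obs1 = g1, grade_obs2 = g2)
    )
    attr(cohort, "truth") <- list(
      spec = spec,
      effects = tibble::tibble(patient_id = cohort$patient_id, arm = arms,
                               d_L = d_L, d_a = d_a, d_b = d_b,
                               true_delta_sev = true_dsev)
    )
    cohort
  })
}
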