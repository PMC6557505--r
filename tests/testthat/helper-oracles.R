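# Independent oracles: deliberately scalar, loop-based transcriptions of the
# defining equations, kept free of the vectorized package code paths.

# Scalar sRGB -> CIELAB oracle (D65, 2-degree observer; reference white =
# channel sums of the sRGB matrix, the package's documented convention).
oracle_srgb_to_lab <- function(r, g, b) {
  dec <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  rl <- dec(r); gl <- dec(g); bl <- dec(b)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  xn <- 0.4124564 + 0.3575761 + 0.1804375
  yn <- 0.2126729 + 0.7151522 + 0.0721750
  zn <- 0.0193339 + 0.1191920 + 0.9503041
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(x / xn); fy <- f(y / yn); fz <- f(z / zn)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Loop-based mean and population SD over masked pixels.
oracle_mask_summary <- function(channel, mask) {
  vals <- c()
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) vals <- c(vals, channel[i, j])
  }
  m <- sum(vals) / length(vals)
  s <- sqrt(sum((vals - m)^2) / length(vals))
  c(mean = m, sd = s)
}

# Direct-summation Pearson chi-square.
oracle_chisq <- function(counts) {
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  c(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Closed-form pooled two-sample t-test from summaries.
oracle_pooled_t <- function(m1, s1, n1, m2, s2, n2, conf = 0.95) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - (1 - conf) / 2, df)
  c(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
    lo = (m1 - m2) - tc * se, hi = (m1 - m2) + tc * se)
}

# Closed-form power of the pooled two-sided t-test at alpha = 0.05 via the
# noncentral t distribution.
oracle_t_power <- function(diff, s1, n1, s2, n2) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  ncp <- diff / se
  tc <- stats::qt(0.975, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

# Small uniform Lab image + full-frame area.
make_uniform_lab <- function(L, a, b, h = 4, w = 4) {
  lab_image(matrix(L, h, w), matrix(a, h, w), matrix(b, h, w))
}

full_area <- function(h, w, label = "other") {
  measurement_area(matrix(TRUE, h, w), label)
}

# Random in-gamut sRGB pixel matrix (n x 3).
random_srgb <- function(n, seed) {
  set.seed(seed)
  matrix(runif(3 * n), ncol = 3)
}

# Random near-identity affine cast in linear RGB.
random_cast <- function() {
  list(matrix = diag(runif(3, 0.85, 1.15)) + matrix(runif(9, -0.03, 0.03), 3),
       offset = runif(3, -0.04, 0.04))
}
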