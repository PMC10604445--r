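# Independent brute-force oracles, deliberately naive (per-candidate mean()
# calls, explicit pair loops) so they share no code path with the package.

brute_force_otsu <- function(v) {
  u <- sort(unique(v))
  best <- -Inf; best_k <- NA
  for (k in seq_len(length(u) - 1)) {
    g1 <- v[v <= u[k]]; g2 <- v[v > u[k]]
    bcv <- length(g1) * length(g2) * (mean(g1) - mean(g2))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  (u[best_k] + u[best_k + 1]) / 2
}

brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

rank_formula_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# single-region fixture: one 20x20 image holding an elliptical ROI
single_region_phantom <- function(fat_fraction, mu_muscle = 70, mu_fat = 100,
                                  noise_sd = 0, bias = c(1, 0, 0, 0, 0, 0),
                                  seed = 1, size = 40) {
  regions <- list(list(label = 1L, muscle = "PPM", side = "left",
                       center = c(size / 2, size / 2),
                       semi_axes = c(size / 2.6, size / 3.1)))
  generate_phantom(phantom_spec(
    image_height_px = size, image_width_px = size, regions = regions,
    true_fat_fraction = fat_fraction, mu_muscle = mu_muscle, mu_fat = mu_fat,
    noise_sd = noise_sd, bias_coefficients = bias, seed = seed))
}

# a minimal cohort-like table for the statistics stage
toy_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  fi_ppm <- runif(n, 20, 80)
  data.frame(
    id = sprintf("T%03d", 1:n),
    sex = rep(c("female", "male"), length.out = n),
    age = rnorm(n, 65, 8), bmi = rnorm(n, 28, 4),
    height_m = rnorm(n, 1.7, 0.07),
    race = "caucasian", race_other = rbinom(n, 1, 0.1),
    FI_PPM = fi_ppm,
    FI_Psoas = pmax(0, 12 - 0.2 * fi_ppm + rnorm(n, 0, 2)),
    CSA_PPM = rlnorm(n, log(19), 0.2), CSA_Psoas = rlnorm(n, log(8), 0.25),
    LL = rnorm(n, 50, 12),
    stringsAsFactors = FALSE) |>
    within({
      FAT_PPM <- CSA_PPM * FI_PPM / 100
      fCSA_PPM <- CSA_PPM - FAT_PPM
      FAT_Psoas <- CSA_Psoas * FI_Psoas / 100
      fCSA_Psoas <- CSA_Psoas - FAT_Psoas
      FI_group <- classify_fi_group(FI_PPM)$collapsed
      FI_group3 <- classify_fi_group(FI_PPM)$group3
    })
}
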