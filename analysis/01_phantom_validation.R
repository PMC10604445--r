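#!/usr/bin/env Rscript
# Validates the composition core on phantoms with known ground truth:
# (a) FI recovery across fat fractions on clean images, (b) the benefit of
# quadratic bias-field correction when coil shading overlaps the two
# intensity classes. Writes results/phantom_recovery.csv and
# results/bias_benefit.csv.

library(musclefi)
dir.create("results", showWarnings = FALSE)
seed <- 1L

region <- list(list(label = 1L, muscle = "PPM", side = "left",
                    center = c(30, 30), semi_axes = c(23, 19)))
phantom <- function(f, bias = c(1, 0, 0, 0, 0, 0), noise = 0, s = seed)
  generate_phantom(phantom_spec(60, 60, regions = region,
                                true_fat_fraction = f, mu_muscle = 70,
                                mu_fat = 100, noise_sd = noise,
                                bias_coefficients = bias, seed = s))

rec <- do.call(rbind, lapply(seq(0.05, 0.60, 0.05), function(f) {
  ph <- phantom(f)
  comp <- measure_muscle(ph$image, ph$masks, 1L)
  data.frame(true_fraction = f,
             truth_FI = 100 * ph$truth_fat_fraction[["1"]],
             measured_FI = comp$FI, n_pixels = comp$n_pixels)
}))
rec$abs_error <- abs(rec$measured_FI - rec$truth_FI)
write.csv(rec, "results/phantom_recovery.csv", row.names = FALSE)
cat(sprintf("FI recovery on clean phantoms: max |error| %.4f FI points (one pixel = %.3f)\n",
            max(rec$abs_error), 100 / rec$n_pixels[1]))

# shading with max/min ratio ~1.5 across the slice; classes 70 vs 100 overlap
bias <- c(1, 0.25, 0.15, 0, 0, 0)
bb <- do.call(rbind, lapply(1:20, function(s) {
  ph <- phantom(0.35, bias = bias, s = s)
  truth <- 100 * ph$truth_fat_fraction[["1"]]
  corr <- measure_muscle(ph$image, ph$masks, 1L)$FI
  raw <- measure_muscle(ph$image, ph$masks, 1L,
                        measure_config(bias_correction = FALSE))$FI
  data.frame(seed = s, truth_FI = truth, corrected_FI = corr,
             uncorrected_FI = raw,
             err_corrected = abs(corr - truth),
             err_uncorrected = abs(raw - truth))
}))
write.csv(bb, "results/bias_benefit.csv", row.names = FALSE)
cat(sprintf("bias correction: mean |FI error| %.3f with vs %.3f without (20 phantoms)\n",
            mean(bb$err_corrected), mean(bb$err_uncorrected)))
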