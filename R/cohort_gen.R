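#' Generate a synthetic patient cohort
#'
#' Per patient: sex ~ Bernoulli(p_female); age and BMI from location-scale
#' normal laws (scale = IQR/1.349) clamped to plausible ranges; height normal;
#' race categorical; FI_PPM from the per-sex logit-normal law, with its latent
#' normal correlated to the age draw at `age_fi_corr`; FI_Psoas from the
#' generating linear model plus Gaussian residual, clipped to \eqn{[0,100]};
#' per-muscle CSA from log-normal laws with FAT = CSA * FI / 100 and
#' fCSA = CSA - FAT; LL normal given sex and collapsed FI group. If more than
#' 5\% of FI_Psoas values are clipped a warning reports the rate.
#'
#' @param spec a [cohort_spec()], e.g. [calibrate_defaults()].
#' @param seed RNG seed; defaults to the spec's seed.
#' @return data.frame of class `cohort_table`, one row per patient, with
#'   attributes `spec_hash`, `seed` and `clip_rate`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n
  sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
  race <- names(spec$race_probs)[
    1L + findInterval(stats::runif(n), cumsum(spec$race_probs),
                      rightmost.closed = TRUE)]
  race_other <- as.integer(race != names(spec$race_probs)[1])

  age <- bmi <- height <- fi_ppm <- csa_ppm <- csa_psoas <- numeric(n)
  for (s in c("female", "male")) {
    i <- which(sex == s)
    if (!length(i)) next
    b <- spec[[if (s == "female") "female" else "male"]]
    z_fi <- stats::rnorm(length(i))
    z_age <- b$age_fi_corr * z_fi +
      sqrt(1 - b$age_fi_corr^2) * stats::rnorm(length(i))
    fi_ppm[i] <- 100 * stats::plogis(b$fi_ppm_logit_mu +
                                     b$fi_ppm_logit_sigma * z_fi)
    age[i] <- pmin(pmax(b$age_median + diff(b$age_iqr) / 1.349 * z_age, 18), 95)
    bmi[i] <- pmin(pmax(b$bmi_median + diff(b$bmi_iqr) / 1.349 *
                          stats::rnorm(length(i)), 15), 60)
    height[i] <- pmin(pmax(stats::rnorm(length(i), b$height_mean, b$height_sd),
                           1.40), 2.10)
    csa_ppm[i] <- stats::rlnorm(length(i), log(b$csa_ppm_median), b$csa_ppm_sdlog)
    csa_psoas[i] <- stats::rlnorm(length(i), log(b$csa_psoas_median),
                                  b$csa_psoas_sdlog)
  }

  cf <- spec$coefficients
  female <- as.integer(sex == "female")
  lp <- cf["intercept"] + cf["fi_ppm"] * fi_ppm + cf["age"] * age +
    cf["bmi"] * bmi + cf["sex_female"] * female + cf["race_other"] * race_other
  resid_sd <- ifelse(sex == "female", spec$female$resid_sd, spec$male$resid_sd)
  fi_psoas_raw <- as.numeric(lp) + stats::rnorm(n, 0, resid_sd)
  fi_psoas <- pmin(pmax(fi_psoas_raw, 0), 100)
  clip_rate <- mean(fi_psoas_raw < 0 | fi_psoas_raw > 100)
  if (clip_rate > 0.05)
    warning(sprintf("FI_Psoas clipped to [0,100] for %.1f%% of records", 100 * clip_rate))

  groups <- classify_fi_group(fi_ppm)
  ll <- numeric(n)
  for (s in c("female", "male")) {
    b <- spec[[if (s == "female") "female" else "male"]]
    for (g in 1:2) {
      i <- which(sex == s &
                 groups$collapsed == c("low_moderate", "high")[g])
      if (length(i))
        ll[i] <- stats::rnorm(length(i), b$ll_mean[g], b$ll_sd[g])
    }
  }

  tab <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    sex = sex, age = age, bmi = bmi, height_m = height,
    race = race, race_other = race_other,
    FI_PPM = fi_ppm, FI_Psoas = fi_psoas,
    CSA_PPM = csa_ppm, FAT_PPM = csa_ppm * fi_ppm / 100,
    fCSA_PPM = csa_ppm * (1 - fi_ppm / 100),
    CSA_Psoas = csa_psoas, FAT_Psoas = csa_psoas * fi_psoas / 100,
    fCSA_Psoas = csa_psoas * (1 - fi_psoas / 100),
    LL = ll,
    FI_group3 = groups$group3, FI_group = groups$collapsed,
    stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  attr(tab, "seed") <- seed
  attr(tab, "spec_hash") <- spec_hash(spec)
  attr(tab, "clip_rate") <- clip_rate
  tab
}

#' Hash of a serializable object (for provenance stamps)
#'
#' @param x any jsonlite-serializable object.
#' @return md5 hex string of its canonical JSON form.
#' @keywords internal
spec_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(x), digits = NA, auto_unbox = TRUE,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
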