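# Synthetic neonatal cohort: TsB distribution, clinical covariates, and the
# phenomenological channel-effect model used to render glabella image patches.

#' Truncated log-normal total plasma bilirubin profile
#'
#' Describes the TsB (total plasma bilirubin, umol/L) distribution of the
#' simulated cohort as a log-normal truncated to `[lower, upper]`. The
#' log-scale location is solved numerically so that the *truncated* median
#' equals `median`; the defaults reproduce a cohort with median 155 umol/L and
#' range 28-289 umol/L, the summaries a clinical screening cohort of healthy
#' near-term newborns presents in their first week.
#'
#' A `sdlog` of 0 gives a degenerate (point-mass) distribution at `median`,
#' useful for deterministic tests.
#'
#' @param median target median TsB of the truncated distribution, umol/L.
#' @param lower,upper truncation bounds, umol/L; must lie within [0, 600].
#' @param sdlog log-scale standard deviation (>= 0). Default 0.5 gives a
#'   right-skewed distribution with SD about 59 umol/L inside the default
#'   bounds.
#' @return An object of class `tsb_profile` with elements `meanlog`, `sdlog`,
#'   `lower`, `upper`, `median`.
#' @examples
#' p <- tsb_profile()
#' q <- qlnorm(0.5, p$meanlog, p$sdlog) # untruncated median differs slightly
#' @export
tsb_profile <- function(median = 155, lower = 28, upper = 289, sdlog = 0.5) {
  if (!is.numeric(median) || length(median) != 1 || median <= 0)
    stopf("tsb_profile: 'median' must be a positive number")
  if (sdlog < 0) stopf("tsb_profile: 'sdlog' must be >= 0")
  if (lower < 0 || upper > 600 || lower >= upper)
    stopf("tsb_profile: truncation bounds must satisfy 0 <= lower < upper <= 600")
  if (median <= lower || median >= upper)
    stopf("tsb_profile: 'median' must lie strictly inside the truncation bounds")
  if (sdlog == 0) {
    meanlog <- log(median)
  } else {
    trunc_median <- function(mu) {
      flo <- stats::plnorm(lower, mu, sdlog)
      fhi <- stats::plnorm(upper, mu, sdlog)
      stats::qlnorm((flo + fhi) / 2, mu, sdlog) - median
    }
    meanlog <- stats::uniroot(trunc_median, c(log(lower), log(upper)),
                              tol = 1e-10)$root
  }
  structure(list(meanlog = meanlog, sdlog = sdlog,
                 lower = lower, upper = upper, median = median),
            class = "tsb_profile")
}

#' Moments of a truncated TsB profile
#'
#' Mean and standard deviation of the truncated log-normal, by numeric
#' integration. Used to calibrate the channel-effect model analytically.
#'
#' @param profile a [tsb_profile()].
#' @return list with `mean` and `sd` (umol/L).
#' @export
tsb_moments <- function(profile) {
  stopifnot(inherits(profile, "tsb_profile"))
  if (profile$sdlog == 0) return(list(mean = profile$median, sd = 0))
  mass <- stats::plnorm(profile$upper, profile$meanlog, profile$sdlog) -
    stats::plnorm(profile$lower, profile$meanlog, profile$sdlog)
  m1 <- stats::integrate(function(x) x * stats::dlnorm(x, profile$meanlog, profile$sdlog),
                         profile$lower, profile$upper, rel.tol = 1e-10)$value / mass
  m2 <- stats::integrate(function(x) x^2 * stats::dlnorm(x, profile$meanlog, profile$sdlog),
                         profile$lower, profile$upper, rel.tol = 1e-10)$value / mass
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

## Default covariate sampling profiles. Targets: gestational age median 40
## (35-41) weeks, birth weight median 3455 (2440-4900) g, postnatal age median
## 3 (3-9) days, haemoglobin median 12.4 (9.1-16.9) mmol/L, sexes ~50/50.
default_covariates <- function() {
  list(
    ga_weeks  = list(dist = "truncnorm", mean = 39.8, sd = 1.3,
                     lower = 35, upper = 41, digits = 0),
    age_days  = list(dist = "discrete", values = 3:9,
                     probs = local({p <- 0.55^(0:6); p / sum(p)})),
    weight_g  = list(dist = "truncnorm", mean = 3455, sd = 480,
                     lower = 2440, upper = 4900, digits = 0),
    hb_mmol_l = list(dist = "truncnorm", mean = 12.4, sd = 1.5,
                     lower = 9.1, upper = 16.9, digits = 1),
    sex       = list(dist = "binary", levels = c("female", "male"), prob = 0.5),
    tcb_sd    = 15
  )
}

validate_covariates <- function(cov) {
  for (nm in setdiff(names(cov), "tcb_sd")) {
    d <- cov[[nm]]
    if (is.null(d$dist)) stopf("cohort_config: covariate '%s' lacks a 'dist' field", nm)
    if (d$dist == "truncnorm") {
      if (d$sd < 0) stopf("cohort_config: covariate '%s' has negative sd", nm)
      if (d$lower >= d$upper) stopf("cohort_config: covariate '%s' has inverted bounds", nm)
    } else if (d$dist == "discrete") {
      if (length(d$values) != length(d$probs) || any(d$probs < 0) ||
          abs(sum(d$probs) - 1) > 1e-8)
        stopf("cohort_config: covariate '%s' has invalid discrete probabilities", nm)
    } else if (d$dist == "binary") {
      if (d$prob < 0 || d$prob > 1)
        stopf("cohort_config: covariate '%s' has invalid probability", nm)
    } else stopf("cohort_config: covariate '%s' has unknown dist '%s'", nm, d$dist)
  }
  invisible(cov)
}

#' Cohort sampling configuration
#'
#' @param n_subjects number of newborns to simulate (>= 2). Default 51, the
#'   size of the analysable dermatoscope cohort the defaults emulate.
#' @param tsb a [tsb_profile()] describing the TsB distribution.
#' @param covariates named list of covariate sampling profiles; see
#'   `biliscreen:::default_covariates()` for the expected shape.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 51, tsb = tsb_profile(),
                          covariates = default_covariates(), seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stopf("cohort_config: 'n_subjects' must be >= 2")
  if (!inherits(tsb, "tsb_profile"))
    stopf("cohort_config: 'tsb' must be a tsb_profile object")
  validate_covariates(covariates)
  structure(list(n_subjects = as.integer(n_subjects), tsb = tsb,
                 covariates = covariates, seed = as.integer(seed)),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  flo <- stats::pnorm(lower, mean, sd)
  fhi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(flo + stats::runif(n) * (fhi - flo), mean, sd)
}

rtrunc_lnorm <- function(n, profile) {
  if (profile$sdlog == 0) return(rep(profile$median, n))
  flo <- stats::plnorm(profile$lower, profile$meanlog, profile$sdlog)
  fhi <- stats::plnorm(profile$upper, profile$meanlog, profile$sdlog)
  stats::qlnorm(flo + stats::runif(n) * (fhi - flo), profile$meanlog, profile$sdlog)
}

#' Sample a synthetic neonatal cohort
#'
#' Draws `n_subjects` newborns with TsB from the configured truncated
#' log-normal (inverse-CDF sampling, so no draw can escape the truncation
#' bounds) and clinical covariates drawn independently per subject. TcB, the
#' transcutaneous estimate, is generated as TsB plus Gaussian error
#' (`covariates$tcb_sd`, default 15 umol/L) -- the two modalities track each
#' other closely, and no TcB-specific statistics are computed downstream.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per subject and columns `subject_id`,
#'   `tsb_umol_l`, `tcb_umol_l`, `ga_weeks`, `age_days`, `weight_g`,
#'   `hb_mmol_l`, `sex`.
#' @examples
#' subj <- sample_cohort(cohort_config(n_subjects = 10, seed = 42))
#' median(subj$tsb_umol_l)
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  cov <- config$covariates
  with_seed(config$seed, {
    tsb <- rtrunc_lnorm(n, config$tsb)
    draw <- function(d) {
      switch(d$dist,
        truncnorm = round(rtrunc_norm(n, d$mean, d$sd, d$lower, d$upper),
                          d$digits %||% 0),
        discrete  = d$values[1 + findInterval(stats::runif(n),
                                              cumsum(d$probs), left.open = TRUE)],
        binary    = d$levels[1 + (stats::runif(n) >= d$prob)])
    }
    ga  <- draw(cov$ga_weeks)
    age <- draw(cov$age_days)
    wt  <- draw(cov$weight_g)
    hb  <- draw(cov$hb_mmol_l)
    sex <- draw(cov$sex)
    tcb <- round(pmax(tsb + stats::rnorm(n, 0, cov$tcb_sd %||% 15), 0), 1)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      tsb_umol_l = round(tsb, 1),
      tcb_umol_l = tcb,
      ga_weeks = ga, age_days = age, weight_g = wt, hb_mmol_l = hb,
      sex = sex, stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Channel-effect model for rendering skin patches
#'
#' A phenomenological forward model for the mean red/green/blue intensity of a
#' glabella image patch: for channel c the subject-level expected intensity is
#' `alpha_c + beta_c * TsB + sum(covariate slopes) + N(0, sigma_subj_c)`, and
#' each pixel adds independent `N(0, sigma_pix_c)` noise before 8-bit
#' quantisation. Slopes for green and blue are positive: under dermatoscope
#' illumination the empirical channel-intensity/TsB correlations are positive,
#' and the model reproduces those statistics rather than absorption physics
#' (the spectral module models the physics, where the blue channel *decreases*
#' with bilirubin).
#'
#' @param alpha named intensity intercepts, 0-255 scale, order red/green/blue.
#' @param beta named TsB slopes, intensity units per umol/L.
#' @param covariate_slopes named list (per channel) of named numeric slopes on
#'   cohort covariates, intensity units per covariate unit.
#' @param sigma_subj named per-channel subject-level noise SDs (>= 0).
#' @param sigma_pix named per-channel pixel noise SDs (>= 0).
#' @param tsb_bounds TsB range (umol/L) over which expected intensities must
#'   stay inside [0, 255]; violating models raise a calibration error.
#' @return object of class `channel_effect_model`.
#' @seealso [default_effect_model()] for the calibrated default.
#' @export
channel_effect_model <- function(alpha, beta,
                                 covariate_slopes = list(),
                                 sigma_subj = c(red = 0, green = 0, blue = 0),
                                 sigma_pix = c(red = 0, green = 0, blue = 0),
                                 tsb_bounds = c(28, 289)) {
  ch <- c("red", "green", "blue")
  for (v in list(alpha = alpha, beta = beta, sigma_subj = sigma_subj,
                 sigma_pix = sigma_pix))
    if (!all(ch %in% names(v)))
      stopf("channel_effect_model: parameter vectors need names red, green, blue")
  if (any(sigma_subj < 0) || any(sigma_pix < 0))
    stopf("channel_effect_model: noise SDs must be >= 0")
  # covariate ranges used for the in-gamut check (age is the only default slope)
  cov_rng <- list(age_days = c(1, 14), ga_weeks = c(35, 42),
                  weight_g = c(2000, 5000), hb_mmol_l = c(8, 18))
  for (c in ch) {
    ends <- alpha[[c]] + beta[[c]] * tsb_bounds
    sl <- covariate_slopes[[c]]
    if (!is.null(sl)) for (nm in names(sl)) {
      rng <- cov_rng[[nm]] %||% c(0, 0)
      ends <- range(outer(ends, sl[[nm]] * rng, "+"))
    }
    if (min(ends) < 0 || max(ends) > 255)
      stopf("channel_effect_model: expected %s intensity leaves [0, 255] over TsB range (calibration error)", c)
  }
  structure(list(alpha = alpha[ch], beta = beta[ch],
                 covariate_slopes = covariate_slopes,
                 sigma_subj = sigma_subj[ch], sigma_pix = sigma_pix[ch],
                 tsb_bounds = tsb_bounds),
            class = "channel_effect_model")
}

#' Default calibrated channel-effect model
#'
#' Solves the subject-level noise SDs in closed form so that, under the given
#' TsB profile, the theoretical Pearson correlation between extracted mean
#' channel intensity and TsB equals the calibration targets (green 0.59, blue
#' 0.46, red 0.21 -- red non-significant at n = 51 in most cohorts). With
#' subject mean M = alpha + beta*TsB + gamma*age + e_subj and an extracted mean
#' over `region_pixels` pixels,
#' `r = beta*sd(TsB) / sqrt(beta^2 var(TsB) + gamma^2 var(age) + sigma_subj^2 +
#' sigma_pix^2 / region_pixels)`, which is inverted for `sigma_subj`.
#'
#' @param tsb a [tsb_profile()]; its analytic moments enter the calibration.
#' @param target_r named target Pearson correlations per channel.
#' @param covariates covariate profiles (for the postnatal-age variance).
#' @param region_pixels number of pixels in the analysed uniform region
#'   (default 256 = 16 x 16).
#' @return a [channel_effect_model()].
#' @export
default_effect_model <- function(tsb = tsb_profile(),
                                 target_r = c(red = 0.21, green = 0.59, blue = 0.46),
                                 covariates = default_covariates(),
                                 region_pixels = 256) {
  alpha <- c(red = 170, green = 150, blue = 130)
  beta  <- c(red = 0.05, green = 0.15, blue = 0.10)
  gamma_age <- c(red = 0, green = 0.5, blue = 0)  # small age term for regression tests
  sigma_pix <- c(red = 4, green = 4, blue = 4)
  mom <- tsb_moments(tsb)
  ad <- covariates$age_days
  age_var <- sum(ad$probs * ad$values^2) - sum(ad$probs * ad$values)^2
  signal_sd <- beta * mom$sd
  total_sd <- signal_sd / target_r[names(beta)]
  sigma_subj <- sqrt(pmax(total_sd^2 - signal_sd^2 - gamma_age^2 * age_var -
                            sigma_pix^2 / region_pixels, 0))
  channel_effect_model(
    alpha = alpha, beta = beta,
    covariate_slopes = list(green = c(age_days = gamma_age[["green"]])),
    sigma_subj = sigma_subj, sigma_pix = sigma_pix,
    tsb_bounds = c(tsb$lower, tsb$upper))
}

#' Render a synthetic glabella image patch
#'
#' Generates an `height x width` 8-bit RGB patch for one subject under a
#' [channel_effect_model()]. Pixel values are
#' `round(alpha_c + beta_c*TsB + covariate terms + subject noise + pixel noise)`
#' with round-half-away-from-zero, clipped to [0, 255]. Deterministic given
#' `seed`.
#'
#' @param subject one-row data.frame as produced by [sample_cohort()].
#' @param effects a [channel_effect_model()].
#' @param height,width patch dimensions in pixels (>= 8). Default 64.
#' @param seed integer seed for subject- and pixel-level noise.
#' @return a [skin_image()] with `method = "dermatoscope"`.
#' @examples
#' subj <- sample_cohort(cohort_config(n_subjects = 2, seed = 1))
#' img <- render_image(subj[1, ], default_effect_model(), seed = 7)
#' dim(img$pixels)
#' @export
render_image <- function(subject, effects, height = 64, width = 64, seed = 1L) {
  stopifnot(inherits(effects, "channel_effect_model"))
  if (height < 8 || width < 8)
    stopf("render_image: height and width must be >= 8")
  ch <- c("red", "green", "blue")
  mu <- vapply(ch, function(c) {
    m <- effects$alpha[[c]] + effects$beta[[c]] * subject$tsb_umol_l
    sl <- effects$covariate_slopes[[c]]
    if (!is.null(sl)) for (nm in names(sl)) m <- m + sl[[nm]] * subject[[nm]]
    m
  }, numeric(1))
  if (any(mu < 0 | mu > 255))
    stopf("render_image: expected mean intensity outside [0, 255] (calibration error)")
  px <- with_seed(seed, {
    subj_noise <- stats::rnorm(3, 0, effects$sigma_subj)
    arr <- array(0, dim = c(height, width, 3))
    for (k in 1:3) {
      noise <- if (effects$sigma_pix[[k]] > 0)
        stats::rnorm(height * width, 0, effects$sigma_pix[[k]]) else 0
      arr[, , k] <- clip8(round_half_away(mu[k] + subj_noise[k] + noise))
    }
    storage.mode(arr) <- "integer"
    arr
  })
  skin_image(px, method = "dermatoscope", subject_id = subject$subject_id,
             metadata = list(expected_mean = mu, seed = seed))
}

#' Artifact specification for quality-control testing
#'
#' Describes hair-streak and specular-reflection artifacts to stamp onto a
#' rendered patch, emulating the irregularities (hair, skin differences,
#' glare) that force real images to be excluded.
#'
#' @param hair_streak_count number of dark line segments (>= 0).
#' @param hair_streak_darkening intensity drop along a streak, 0-255.
#' @param specular_spot_count number of saturated bright blobs (>= 0).
#' @param specular_level intensity the blobs are set to (<= 255).
#' @param seed RNG seed for artifact placement.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(hair_streak_count = 0, hair_streak_darkening = 80,
                          specular_spot_count = 0, specular_level = 255,
                          seed = 1L) {
  if (hair_streak_count < 0 || specular_spot_count < 0)
    stopf("artifact_spec: counts must be >= 0")
  if (specular_level > 255) stopf("artifact_spec: specular_level must be <= 255")
  structure(list(hair_streak_count = as.integer(hair_streak_count),
                 hair_streak_darkening = hair_streak_darkening,
                 specular_spot_count = as.integer(specular_spot_count),
                 specular_level = specular_level, seed = as.integer(seed)),
            class = "artifact_spec")
}

# Rasterise a line segment (row1,col1)-(row2,col2) to pixel indices.
line_pixels <- function(r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1)) + 1
  cbind(round(seq(r1, r2, length.out = n)), round(seq(c1, c2, length.out = n)))
}

#' Stamp hair and specular artifacts onto an image
#'
#' Adds seeded dark line segments ("hair") and saturated circular blobs
#' ("specular glare") to a [skin_image()]. The altered pixel count and mask are
#' recorded in the image metadata (`artifact_pixels`, `artifact_mask`) so QC
#' tests can compare detected against injected fractions. Zero counts return
#' the input unchanged apart from the (empty) metadata.
#'
#' @param image a [skin_image()].
#' @param spec an [artifact_spec()].
#' @return the modified [skin_image()].
#' @export
inject_artifacts <- function(image, spec) {
  stopifnot(inherits(image, "skin_image"), inherits(spec, "artifact_spec"))
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  px <- image$pixels
  mask <- matrix(FALSE, h, w)
  with_seed(spec$seed, {
    if (spec$hair_streak_count > 0) for (i in seq_len(spec$hair_streak_count)) {
      r1 <- sample.int(h, 1); c1 <- sample.int(w, 1)
      ang <- stats::runif(1, 0, 2 * pi)
      len <- max(h, w) * 0.6
      r2 <- min(max(round(r1 + len * sin(ang)), 1), h)
      c2 <- min(max(round(c1 + len * cos(ang)), 1), w)
      ij <- line_pixels(r1, c1, r2, c2)
      for (k in 1:3)
        px[cbind(ij, k)] <- clip8(px[cbind(ij, k)] - spec$hair_streak_darkening)
      mask[ij] <- TRUE
    }
    if (spec$specular_spot_count > 0) for (i in seq_len(spec$specular_spot_count)) {
      rc <- c(sample.int(h, 1), sample.int(w, 1))
      rad <- sample(2:3, 1)
      rows <- pmin(pmax((rc[1] - rad):(rc[1] + rad), 1), h)
      cols <- pmin(pmax((rc[2] - rad):(rc[2] + rad), 1), w)
      grid <- expand.grid(r = unique(rows), c = unique(cols))
      keep <- (grid$r - rc[1])^2 + (grid$c - rc[2])^2 <= rad^2
      ij <- as.matrix(grid[keep, , drop = FALSE])
      for (k in 1:3) px[cbind(ij, k)] <- as.integer(spec$specular_level)
      mask[ij] <- TRUE
    }
  })
  storage.mode(px) <- "integer"
  out <- image
  out$pixels <- px
  out$metadata$artifact_pixels <- sum(mask)
  out$metadata$artifact_mask <- mask
  out
}
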