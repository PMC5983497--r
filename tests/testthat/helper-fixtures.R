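# Shared in-code fixtures for the test suite.

# A constant-valued skin image.
constant_image <- function(value = c(200, 180, 160), h = 16, w = 16,
                           subject_id = "S001") {
  px <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- as.integer(value[k])
  skin_image(px, subject_id = subject_id)
}

# A seeded random-noise image.
random_image <- function(seed, h = 16, w = 16) {
  px <- biliscreen:::with_seed(seed,
    array(sample.int(256, h * w * 3, replace = TRUE) - 1L, dim = c(h, w, 3)))
  skin_image(px)
}

# Noise-free effect model with unit-named parameters for exact-arithmetic tests.
zero_noise_model <- function(alpha = c(red = 200, green = 180, blue = 160),
                             beta = c(red = 0, green = 0, blue = 0),
                             covariate_slopes = list()) {
  channel_effect_model(alpha = alpha, beta = beta,
                       covariate_slopes = covariate_slopes,
                       sigma_subj = c(red = 0, green = 0, blue = 0),
                       sigma_pix = c(red = 0, green = 0, blue = 0))
}

# One-row subject data.frame with explicit values.
fixed_subject <- function(tsb = 150, age_days = 3) {
  data.frame(subject_id = "S001", tsb_umol_l = tsb, tcb_umol_l = tsb,
             ga_weeks = 40, age_days = age_days, weight_g = 3455,
             hb_mmol_l = 12.4, sex = "female", stringsAsFactors = FALSE)
}

# Brute-force oracle: per-channel mean over a mask by explicit double loop.
naive_mask_mean <- function(image, mask) {
  out <- c(red = 0, green = 0, blue = 0)
  for (k in 1:3) {
    total <- 0; count <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        total <- total + image$pixels[i, j, k]
        count <- count + 1
      }
    }
    out[k] <- total / count
  }
  out
}

# Brute-force oracle: scan every window position, computing the summed
# within-window population variance per channel with var()'s definition
# adjusted to denominator n.
naive_best_window <- function(image, side) {
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  best <- NULL; best_score <- Inf
  scores <- matrix(NA_real_, h - side + 1, w - side + 1)
  for (i in seq_len(h - side + 1)) for (j in seq_len(w - side + 1)) {
    sc <- 0
    for (k in 1:3) {
      v <- as.numeric(image$pixels[i:(i + side - 1), j:(j + side - 1), k])
      sc <- sc + mean(v^2) - mean(v)^2
    }
    scores[i, j] <- sc
    if (sc < best_score) {
      best_score <- sc
      best <- c(i, j)
    }
  }
  list(top = best[1], left = best[2], score = best_score, scores = scores)
}
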