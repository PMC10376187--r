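# Shared fixtures: phantoms generated in code at test time.

# A compact phantom for fast unit tests (small field of view, short TEA).
small_spec <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_slices = 5L, image_size = 256L, tea_length = 6.5,
                   noise_sd = 30, seed = seed)
  do.call(phantom_spec, modifyList(defaults, args))
}

# A phantom with parameters drawn from the study ranges (sulcus 110-160,
# ratio 0.3-0.7, TEA 7-9 cm, TEA-PFA 0-10 deg) at full 512 resolution.
varied_spec <- function(seed, ...) {
  pars <- patellometry:::with_seed(seed * 131L + 7L, list(
    sulcus_angle = runif(1, 110, 160),
    asymmetry_ratio = runif(1, 0.3, 0.7),
    tea_length = runif(1, 7, 9),
    tea_pfa_angle = runif(1, 0, 10)))
  do.call(phantom_spec, modifyList(c(pars, seed = seed), list(...)))
}

varied_phantom <- function(seed, ...) generate_phantom(varied_spec(seed, ...))

# Rebuild a landmark-only series after applying a rigid transform to every
# landmark of every slice.
transform_landmarks <- function(series, fun) {
  out <- series
  for (k in seq_along(out$slices)) {
    lm <- out$slices[[k]]$landmarks
    if (is.null(lm)) next
    lm2 <- t(apply(lm, 1, fun))
    dimnames(lm2) <- dimnames(lm)
    out$slices[[k]]$image <- NULL
    out$slices[[k]]$landmarks <- lm2
  }
  out$image_size <- NULL
  class(out) <- "knee_series"
  out
}

measurement_vector <- function(m) {
  c(tea = m$tea_length_cm, pfa = m$tea_pfa_angle_deg,
    ratio = m$asymmetry_ratio, sulcus = m$sulcus_angle_deg)
}
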