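# Shared internal helpers: deterministic seed derivation and small checks.

# Deterministic 32-bit seed derived from a master seed plus arbitrary labels.
# Numeric parts are folded mod 2^31-1; characters via their UTF-8 code points.
# All arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      for (cp in utf8ToInt(paste(p, collapse = "/"))) {
        h <- (h * 69069 + cp) %% 2147483647
      }
    } else {
      for (v in as.numeric(p)) {
        h <- (h * 69069 + (v %% 2147483647)) %% 2147483647
      }
    }
  }
  as.integer(h %% 2147483629L + 1)
}

# Quintic smoothstep: C2, zero first and second derivative at both ends.
smoothstep5 <- function(s) s^3 * (10 - 15 * s + 6 * s^2)

# Unimodal bump with zero slope at both ends, peak 1 at s = 1/2.
bump <- function(s) sin(pi * s)^2

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

conditions_all <- function() c("normal", "fast", "leaning", "leaning_fast")

parameters_all <- function() {
  c("cog_x", "cog_y", "cog_z",
    "hip_moment", "knee_moment", "ankle_moment",
    "sd_x", "sd_y", "error_distance", "step_time")
}

is_leaning <- function(condition) condition %in% c("leaning", "leaning_fast")
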