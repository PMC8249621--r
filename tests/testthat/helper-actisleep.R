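# shared fixtures and independent oracles, built in code

NOON <- as.POSIXct("2017-07-15 12:00:00", tz = "UTC")

make_series <- function(counts, start = NOON, id = "P1", gender = "woman",
                        location = "village", age = 30, offwrist = NULL) {
  epoch_series(counts, start, id, gender, location, age, offwrist = offwrist)
}

# one noon-to-noon day of counts: `high` outside [sleep_from, sleep_to)
# clock hours, `low` inside; optional extra intervals as list(c(from, to, value))
day_counts <- function(sleep_from, sleep_to, high = 1000, low = 0,
                       extra = list()) {
  h <- ((12 * 60 + 0:1439) %% 1440) / 60 # clock hour of each minute
  x <- rep(high, 1440)
  inside <- if (sleep_from <= sleep_to) h >= sleep_from & h < sleep_to
            else h >= sleep_from | h < sleep_to
  x[inside] <- low
  for (e in extra) {
    sel <- if (e[1] <= e[2]) h >= e[1] & h < e[2] else h >= e[1] | h < e[2]
    x[sel] <- e[3]
  }
  x
}

# scoring config with a unit centre weight: classification is exactly
# count <= threshold, so constructions are fully hand-checkable
unit_scoring <- function(threshold = 50) {
  scoring_config(window_weights = c(1), threshold = threshold)
}

# brute-force M10/L5 oracle: plain loop over all circular start minutes,
# wrapping by doubling the profile
m10_l5_oracle <- function(profile, width) {
  n <- length(profile)
  p2 <- c(profile, profile)
  vapply(seq_len(n), function(s) mean(p2[s:(s + width - 1)]), numeric(1))
}

# independent JZS oracle: fine-grid quadrature over the standardized effect
# delta with a Cauchy prior, using the noncentral-t likelihood (a different
# derivation path from the package's g-integral)
jzs_oracle <- function(a, b, rscale = sqrt(2) / 2) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  delta <- seq(-30, 30, length.out = 40001)
  # dt() warns that the noncentral series is truncated at each tail point;
  # the truncation is far below the quadrature tolerance
  lik <- suppressWarnings(dt(t, df = nu, ncp = delta * sqrt(neff)))
  prior <- stats::dcauchy(delta, 0, rscale)
  num <- sum(lik * prior) * (delta[2] - delta[1])
  num / dt(t, df = nu)
}

# brute-force bout enumeration for the fragmentation index
fragmentation_oracle <- function(states) {
  r <- rle(states)
  imm <- r$lengths[r$values == "sleep"]
  mob_min <- sum(r$lengths[r$values == "wake"])
  100 * mob_min / sum(imm) + 100 * sum(imm <= 1) / length(imm)
}
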