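# Independent brute-force oracles used to validate the package implementations.
# Each recomputes its quantity from first principles, by a different route than
# the package code.

# --- Phansalkar: per-pixel recomputation from the explicit neighborhood list ---

# reflect an out-of-range index back into 1..n (edge pixel mirrored)
reflect_px <- function(i, n) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))

phansalkar_oracle <- function(img, radius, k = 0.25, r = 0.5, p = 2, q = 10) {
  n <- nrow(img); m <- ncol(img)
  d <- seq.int(-radius, radius)
  off <- expand.grid(dx = d, dy = d)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  out <- matrix(NA, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      vals <- img[cbind(reflect_px(i + off$dx, n), reflect_px(j + off$dy, m))]
      mu <- mean(vals)
      sg <- sqrt(mean((vals - mu)^2))
      th <- mu * (1 + p * exp(-q * mu) + k * (sg / r - 1))
      out[i, j] <- img[i, j] <= th
    }
  }
  out
}

# --- Connected components: iterative min-label propagation ---

cc_oracle <- function(mask, connectivity = 8) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  lab[mask] <- seq_len(sum(mask))
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    old <- lab
    for (o in offs) {
      di <- o[1]; dj <- o[2]
      si <- max(1, 1 + di):min(n, n + di)
      sj <- max(1, 1 + dj):min(m, m + dj)
      cur <- lab[si, sj, drop = FALSE]
      nb <- lab[si - di, sj - dj, drop = FALSE]
      upd <- cur > 0L & nb > 0L & nb < cur
      cur[upd] <- nb[upd]
      lab[si, sj] <- cur
    }
    if (identical(lab, old)) break
  }
  sizes <- as.integer(table(lab[lab > 0L]))
  list(n = length(sizes), sizes = sort(sizes))
}

# --- Wilcoxon signed-rank: exact two-sided p by bitmask enumeration ---

wilcoxon_oracle_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  allv <- vapply(0:(2^n - 1), function(s) {
    sum(rk[as.logical(intToBits(s)[seq_len(n)])])
  }, numeric(1))
  min(1, 2 * min(mean(allv <= v + 1e-9), mean(allv >= v - 1e-9)))
}

# --- ICC(2,1): mean squares via stats::aov on the long data, then the formula ---

icc2_oracle <- function(values) {
  n <- nrow(values); k <- ncol(values)
  long <- data.frame(y = as.vector(values),
                     row = factor(rep(seq_len(n), k)),
                     col = factor(rep(seq_len(k), each = n)))
  ms <- anova(lm(y ~ row + col, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# --- Studentized range upper tail by direct numerical integration ---

ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    k * stats::integrate(function(z) {
      stats::dnorm(z) * pmax(stats::pnorm(z) - stats::pnorm(z - q * s), 0)^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-9)$value
  }
  # S = sqrt(chi2_df / df) has density 2 * df * s * dchisq(df s^2, df)
  cdf <- stats::integrate(function(s) {
    vapply(s, function(si) 2 * df * si * stats::dchisq(df * si^2, df) * inner(si),
           numeric(1))
  }, 0, Inf, rel.tol = 1e-8)$value
  1 - cdf
}

# --- Small synthetic scene at full physical resolution but reduced extent ---

small_scene <- function(target = 0.45, seed = 1, grid = 256, extent_mm = 0.75) {
  generate_cc_pattern(vessel_params(target_fd_fraction = target, seed = seed),
                      fine_grid_px = grid, extent_mm = extent_mm)
}

# matching small device profile (same 7.5 um pitch as the 400 px / 3 mm grid)
small_sd_device <- function(noise_sd = 0) {
  device_profile("sd_v1", scan_extent_mm = 0.75, grid_px = 100L, noise_sd = noise_sd)
}
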