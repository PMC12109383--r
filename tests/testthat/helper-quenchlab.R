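# Shared fixtures, all built in code.

PROPERTY_SEED <- 42

# Single Gaussian band sampled on a grid.
gaussian_spectrum <- function(center, amp = 1000, sd = 25,
                              grid = seq(300, 500, by = 1), meta = list()) {
  spectrum(grid, amp * exp(-(grid - center)^2 / (2 * sd^2)), meta = meta)
}

# Exact Stern-Volmer table: f = f0 / (1 + ksv q).
exact_sv_table <- function(ksv, q = dilution_ladder(), f0 = 3300,
                           temperature = 298) {
  quench_table(q, f0 / (1 + ksv * q), temperature = temperature)
}

# Published per-temperature quenching constants (L/mol) and binding
# constants (L/mol) used as fixture inputs.
TABLE1_KSV <- c("298" = 0.50e5, "304" = 0.49e5, "310" = 0.40e5)
TABLE1_KA <- c("298" = 7.16e4, "304" = 5.56e4, "310" = 5.45e4)

# Independent closed-form OLS (covariance / variance), used as the oracle
# against lm-based fits.
closed_form_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Exhaustive search over (lg ka, n) minimising SSE of the double-log model.
double_log_grid_oracle <- function(t, lgka_range, n_range, step = 0.001) {
  keep <- t$q > 0 & t$f < t$f0
  x <- log10(t$q[keep])
  y <- log10((t$f0 - t$f[keep]) / t$f[keep])
  lgka <- seq(lgka_range[1], lgka_range[2], by = step)
  nn <- seq(n_range[1], n_range[2], by = step)
  best <- c(lgka = NA, n = NA, sse = Inf)
  for (n1 in nn) {
    r <- y - n1 * x
    # for fixed n the optimal intercept is mean(r); restrict to the grid
    ic <- lgka[which.min(abs(lgka - mean(r)))]
    sse <- sum((r - ic)^2)
    if (sse < best[["sse"]]) best <- c(lgka = ic, n = n1, sse = sse)
  }
  best
}

# Exhaustive simplex search (step `coarse`, refined to `fine`) minimising
# ||A f - b|| over compositions f >= 0 summing to 1.
simplex_grid_oracle <- function(A, b, coarse = 0.01, fine = 0.0005) {
  best <- NULL
  best_sse <- Inf
  search <- function(grid1, grid2, grid3) {
    for (f1 in grid1) for (f2 in grid2) {
      if (f1 + f2 > 1 + 1e-12) next
      for (f3 in grid3) {
        f4 <- 1 - f1 - f2 - f3
        if (f3 + f1 + f2 > 1 + 1e-12 || f4 < -1e-12) next
        f <- c(f1, f2, f3, max(f4, 0))
        sse <- sum((A %*% f - b)^2)
        if (sse < best_sse) {
          best_sse <<- sse
          best <<- f
        }
      }
    }
  }
  g <- seq(0, 1, by = coarse)
  search(g, g, g)
  w <- 2 * coarse
  refine <- function(center) seq(max(0, center - w), min(1, center + w), by = fine)
  search(refine(best[1]), refine(best[2]), refine(best[3]))
  best
}
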