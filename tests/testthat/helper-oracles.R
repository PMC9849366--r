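# Independent oracles, deliberately dumber than the implementation paths
# they check.

# brute-force kobs estimate: grid search minimising SSE with offset and
# amplitude profiled out by OLS at each candidate rate
oracle_grid_kobs <- function(times, signal, lo, hi, n_grid = 4000) {
  grid <- seq(lo, hi, length.out = n_grid)
  sse <- vapply(grid, function(k) {
    X <- cbind(1, exp(-k * times))
    sum(lm.fit(X, signal)$residuals^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# closed-form OLS slope/intercept
oracle_ols <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  slope <- sum(dx * dy) / sum(dx^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# two-stage displacement asymptote: grid over candidate asymptotes, fitting
# log(kobs - a) linearly in d, picking the candidate with least SSE on the
# original scale
oracle_displacement_koff <- function(d, kobs, n_grid = 2000) {
  cands <- seq(0, min(kobs) * 0.999, length.out = n_grid)
  sse <- vapply(cands, function(a) {
    z <- kobs - a
    if (any(z <= 0)) return(Inf)
    cf <- oracle_ols(d, log(z))
    sum((a + exp(cf["intercept"] + cf["slope"] * d) - kobs)^2)
  }, numeric(1))
  cands[which.min(sse)]
}

# per-injection one-site heats via numeric root finding of the binding
# quadratic (free-concentration form), independent of the closed form
oracle_one_site_heats <- function(kd_nM, dh_kJmol, n, cell_uM, syr_uM,
                                  v0_uL, inj_uL) {
  V0 <- v0_uL * 1e-6; Kd <- kd_nM * 1e-9
  dH_cal <- dh_kJmol * 1000 / 4.184
  dV <- cumsum(inj_uL) * 1e-6
  Mt <- cell_uM * 1e-6 * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  Xt <- syr_uM * 1e-6 * (dV / V0) / (1 + dV / (2 * V0))
  bound <- mapply(function(M, X) {
    # solve [MX] from Kd = (nM - b)(X - b)/b for the bound concentration b
    f <- function(b) (n * M - b) * (X - b) - Kd * b
    uniroot(f, c(0, min(n * M, X) * (1 - 1e-15)), tol = 1e-18)$root
  }, Mt, Xt)
  Q <- bound * dH_cal * V0
  Qp <- c(0, Q[-length(Q)])
  (Q - Qp + (inj_uL * 1e-6 / V0) * (Q + Qp) / 2) * 1e6
}

# flat helix-fraction profile over the synthetic peptide
flat_profile <- function(fraction, variant = "WT") {
  sq <- synthetic_dreb2a_sequence(variant)
  helix_profile(sq$sequence, rep(fraction, nchar(sq$sequence)),
                first_residue = sq$first_residue)
}
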