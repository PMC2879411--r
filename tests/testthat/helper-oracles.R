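# Independent brute-force oracles used to check the closed-form and
# numeric solvers. These deliberately avoid the package's own code paths.

# bisection on the mass-action equation (A0-C)(L0-C) = Kd*C
bisect_complex <- function(A0, L0, Kd) {
  f <- function(C) (A0 - C) * (L0 - C) - Kd * C
  lo <- 0
  hi <- min(A0, L0)
  if (hi == 0) return(0)
  for (i in 1:200) { # 200 halvings: interval shrinks below double precision
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# bisection on free actin for the ternary competition system
bisect_competition <- function(A0, E0, K_E, T0, K_T) {
  g <- function(a) a + E0 * a / (K_E + a) + T0 * a / (K_T + a) - A0
  lo <- 0; hi <- A0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  c(free_actin = a, AE = E0 * a / (K_E + a), AT = T0 * a / (K_T + a))
}

# closed-form weighted least squares via the normal equations
wls_closed_form <- function(X, y, w = rep(1, length(y))) {
  W <- diag(w, nrow = length(w))
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  resid <- y - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(solve(XtWX)) * sigma2))
}

# idealized 18-residue amphipathic helix: hydrophobic (L) wherever the
# wheel angle falls within +/-90 degrees of the 0-degree axis, basic (K)
# elsewhere -- a one-sided hydrophobic face by construction
ideal_amphipathic_18 <- function(step = 100) {
  ang <- ((0:17) * step) %% 360
  paste(ifelse(ang < 90 | ang > 270, "L", "K"), collapse = "")
}
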