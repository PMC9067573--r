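# Independent brute-force transcription of the UNIQUAC activity-coefficient
# equations, written in plain loops directly from the combinatorial +
# residual formulas. Deliberately separate from the production code: used
# as the oracle it is checked against.
uniquac_oracle <- function(r, q, U, T, x) {
  Rg <- 8.314462618
  z <- 10
  n <- length(x)
  tau <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) tau[i, j] <- exp(-(U[i, j] - U[j, j]) / (Rg * T))
  phi <- r * x / sum(r * x)
  th <- q * x / sum(q * x)
  l <- z / 2 * (r - q) - (r - 1)
  out <- numeric(n)
  for (i in 1:n) {
    comb <- log(phi[i] / x[i]) + z / 2 * q[i] * log(th[i] / phi[i]) + l[i] -
      phi[i] / x[i] * sum(x * l)
    s1 <- sum(th * tau[, i])
    s2 <- 0
    for (j in 1:n) s2 <- s2 + th[j] * tau[i, j] / sum(th * tau[, j])
    out[i] <- comb + q[i] * (1 - log(s1) - s2)
  }
  out
}

# random UNIQUAC instance: geometries, symmetric energies, state
rand_instance <- function(n, T_range = c(200, 600)) {
  r <- stats::runif(n, 1, 10)
  q <- r * stats::runif(n, 0.75, 1.1)
  U <- matrix(stats::runif(n * n, -3000, 1000), n, n)
  U <- (U + t(U)) / 2
  x <- stats::rgamma(n, 1)
  x <- x / sum(x)
  # keep strictly interior
  x <- 0.98 * x + 0.02 / n
  x <- x / sum(x)
  ids <- paste0("c", seq_len(n))
  list(ids = ids, r = r, q = q, U = U,
       T = stats::runif(1, T_range[1], T_range[2]), x = x,
       geometries = component_geometry(ids, r, q),
       interactions = symmetric_interactions(ids, U))
}

# small two-component fixture used across VLE tests
vle_fixture <- function() {
  ids <- c("A", "B")
  list(
    ids = ids,
    geometries = component_geometry(ids, r = c(2.1, 3.2), q = c(1.9, 2.8)),
    antoine = antoine_table(ids, A = c(7.0, 6.8), B = c(1700, 1600),
                            C = c(-40, -50), T_min = c(250, 250),
                            T_max = c(550, 550)),
    interactions = symmetric_interactions(
      ids, matrix(c(-2500, -2100, -2100, -2000), 2, 2))
  )
}
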