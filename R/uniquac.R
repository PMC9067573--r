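#' Mixture state
#'
#' A liquid-mixture state: component roster, mole-fraction vector and
#' temperature. Mole fractions must be non-negative and sum to 1 within
#' 1e-12.
#'
#' @param component_ids character vector, length n >= 2.
#' @param x mole fractions (mol/mol).
#' @param T temperature, K, > 0.
#' @return A `mixture_state` object.
#' @export
mixture_state <- function(component_ids, x, T) {
  component_ids <- as.character(component_ids)
  .assert(length(component_ids) >= 2L, "need at least 2 components")
  .assert(!anyDuplicated(component_ids), "duplicate component ids")
  .assert(length(x) == length(component_ids), "x must match component_ids")
  .assert(all(is.finite(x)) && all(x >= 0), "mole fractions must be finite and >= 0")
  .assert(abs(sum(x) - 1) <= 1e-12, "mole fractions must sum to 1 within 1e-12")
  .assert(is.numeric(T) && length(T) == 1L && is.finite(T) && T > 0, "T must be > 0 (K)")
  structure(list(component_ids = component_ids, x = as.numeric(x), T = as.numeric(T)),
            class = "mixture_state")
}

#' UNIQUAC activity coefficients
#'
#' Evaluates ln gamma_i for every component of a mixture as the sum of the
#' combinatorial (size/shape) and residual (energetic) contributions of the
#' UNIQUAC Gibbs-excess-energy model. With volume fractions
#' Phi_i = r_i x_i / sum_j r_j x_j, surface fractions
#' theta_i = q_i x_i / sum_j q_j x_j and l_i = (z/2)(r_i - q_i) - (r_i - 1):
#'
#'   ln gamma_i^C = ln(Phi_i/x_i) + (z/2) q_i ln(theta_i/Phi_i) + l_i
#'                  - (Phi_i/x_i) sum_j x_j l_j
#'   ln gamma_i^R = q_i \[1 - ln(sum_j theta_j tau_ji)
#'                  - sum_j theta_j tau_ij / (sum_k theta_k tau_kj)\]
#'
#' with tau from [tau_matrix()] and z = 10. Works for any number of
#' components n >= 2. Mole fractions must lie strictly inside (0, 1); use
#' [ln_gamma_inf()] for the infinite-dilution limit.
#'
#' @param geometries a [component_geometry()] table covering all components.
#' @param interactions a [symmetric_interactions()] or
#'   [asymmetric_interactions()] set covering all components.
#' @param state a [mixture_state()].
#' @return Named numeric vector of ln gamma_i, one per component.
#' @export
ln_gamma <- function(geometries, interactions, state) {
  .assert(inherits(state, "mixture_state"), "state must be a mixture_state")
  ids <- state$component_ids
  x <- state$x
  if (any(x <= 0) || any(x >= 1)) {
    stop("mole fractions must be strictly inside (0, 1); use ln_gamma_inf() for infinite dilution",
         call. = FALSE)
  }
  rq <- .geom_rq(geometries, ids)
  r <- rq$r; q <- rq$q
  tau <- tau_matrix(interactions, state$T, ids)
  z2 <- .Z_COORD / 2

  phi_over_x <- r / sum(r * x)           # Phi_i / x_i
  theta <- q * x / sum(q * x)
  l <- z2 * (r - q) - (r - 1)
  comb <- log(phi_over_x) + z2 * q * log((q / sum(q * x)) / phi_over_x) +
    l - phi_over_x * sum(x * l)

  s <- as.vector(crossprod(tau, theta))  # s_j = sum_k theta_k tau_kj
  resid <- q * (1 - log(s) - as.vector(tau %*% (theta / s)))
  out <- comb + resid
  names(out) <- ids
  out
}

#' Infinite-dilution activity coefficient
#'
#' Closed-form limit of ln gamma for a solute at vanishing mole fraction in
#' a binary solute-solvent mixture:
#'
#'   ln gamma^inf = ln(r1/r2) + (z/2) q1 ln(q1 r2 / (q2 r1)) + l1 - (r1/r2) l2
#'                  + q1 \[1 - ln tau_21 - tau_12\]
#'
#' where index 1 is the solute and 2 the solvent. Avoids the 0 log 0
#' ambiguity of evaluating [ln_gamma()] on the composition boundary.
#'
#' @inheritParams ln_gamma
#' @param solute_id,solvent_id component identifiers, distinct.
#' @param T temperature, K.
#' @return Scalar ln gamma^inf (dimensionless).
#' @export
ln_gamma_inf <- function(geometries, interactions, solute_id, solvent_id, T) {
  .assert(!identical(as.character(solute_id), as.character(solvent_id)),
          "solute and solvent must differ")
  ids <- c(as.character(solute_id), as.character(solvent_id))
  rq <- .geom_rq(geometries, ids)
  r <- rq$r; q <- rq$q
  tau <- tau_matrix(interactions, T, ids)
  z2 <- .Z_COORD / 2
  l <- z2 * (r - q) - (r - 1)
  comb <- log(r[1] / r[2]) + z2 * q[1] * log(q[1] * r[2] / (q[2] * r[1])) +
    l[1] - (r[1] / r[2]) * l[2]
  resid <- q[1] * (1 - log(tau[2, 1]) - tau[1, 2])
  unname(comb + resid)
}

# ---- vectorized binary predictor with analytic energy gradients -----------
#
# Workhorse used by inference: evaluates ln gamma of the *measured* species
# (index 1) over vectors of binary records, together with the partial
# derivatives w.r.t. the three pair energies expressed in Kelvin units
# (u = U/R). `x1 = 0` rows are treated as infinite-dilution records.
#
# Arguments are equal-length vectors: r1,q1 (measured species), r2,q2
# (partner), x1, T (K), and energies u11, u22, u12 (K).
# Returns list(value, g11, g22, g12) with d ln gamma / d u.. (1/K).
.binary_lngamma_grad <- function(r1, q1, r2, q2, x1, T, u11, u22, u12,
                                 grad = TRUE) {
  z2 <- .Z_COORD / 2
  t12 <- exp(.clip_exponent(-(u12 - u22) / T))
  t21 <- exp(.clip_exponent(-(u12 - u11) / T))
  l1 <- z2 * (r1 - q1) - (r1 - 1)
  l2 <- z2 * (r2 - q2) - (r2 - 1)

  inf <- x1 == 0
  x2 <- 1 - x1
  # guard against 0/0 in the finite branch; masked rows are overwritten below
  x1s <- ifelse(inf, 0.5, x1)
  x2s <- 1 - x1s

  den_r <- r1 * x1s + r2 * x2s
  den_q <- q1 * x1s + q2 * x2s
  th1 <- q1 * x1s / den_q
  th2 <- q2 * x2s / den_q
  comb <- log(r1 / den_r) + z2 * q1 * log(q1 * den_r / (den_q * r1)) +
    l1 - (r1 / den_r) * (x1s * l1 + x2s * l2)
  S1 <- th1 + th2 * t21
  S2 <- th2 + th1 * t12
  resid <- q1 * (1 - log(S1) - (th1 / S1 + th2 * t12 / S2))

  comb_inf <- log(r1 / r2) + z2 * q1 * log(q1 * r2 / (q2 * r1)) +
    l1 - (r1 / r2) * l2
  resid_inf <- q1 * (1 - log(t21) - t12)

  value <- ifelse(inf, comb_inf + resid_inf, comb + resid)
  if (!grad) return(list(value = value))

  # d resid / d tau, finite branch
  dt21 <- q1 * th2 * (th1 / S1^2 - 1 / S1)
  dt12 <- -q1 * th2^2 / S2^2
  # infinite-dilution branch
  dt21 <- ifelse(inf, -q1 / t21, dt21)
  dt12 <- ifelse(inf, -q1, dt12)

  g12 <- dt12 * (-t12 / T) + dt21 * (-t21 / T)
  g11 <- dt21 * (t21 / T)
  g22 <- dt12 * (t12 / T)
  list(value = value, g11 = g11, g22 = g22, g12 = g12)
}
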