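test_that("tau follows the Boltzmann form, with limits and guards", {
  ids <- c("a", "b")
  U <- matrix(c(-1000, -1000, -1000, -1000), 2, 2)
  si <- symmetric_interactions(ids, U)
  # zero energy difference: tau = 1 at any T
  expect_equal(unname(tau_matrix(si, 320)), matrix(1, 2, 2))

  U2 <- matrix(c(-2000, -1000, -1000, -500), 2, 2)
  si2 <- symmetric_interactions(ids, U2)
  # direct scalar evaluation: U_12 - U_22 = -500 J/mol at 300 K
  expect_equal(tau_matrix(si2, 300)["a", "b"],
               exp(-(-1000 - -500) / (8.314462618 * 300)))
  # Boltzmann factor tends to 1 as T grows
  expect_equal(unname(tau_matrix(si2, 1e9)), matrix(1, 2, 2), tolerance = 1e-6)
  expect_true(all(tau_matrix(si2, 250) > 0))
  expect_error(tau_matrix(si2, -10), "T must be")
  expect_error(tau_matrix(si2, 0), "T must be")

  # extreme exponents are clipped, warned about, and counted
  reset_tau_clip_count()
  U3 <- matrix(c(0, -1e8, -1e8, 0), 2, 2)
  expect_warning(tau_matrix(symmetric_interactions(ids, U3), 10), "clipped")
  expect_gt(tau_clip_count(), 0L)
  reset_tau_clip_count()
})

test_that("ln_gamma matches an independent brute-force transcription", {
  set.seed(401)
  worst <- 0
  for (rep in 1:200) {
    inst <- rand_instance(sample(2:5, 1))
    v <- ln_gamma(inst$geometries, inst$interactions,
                  mixture_state(inst$ids, inst$x, inst$T))
    worst <- max(worst, max(abs(v - uniquac_oracle(inst$r, inst$q, inst$U,
                                                   inst$T, inst$x))))
  }
  expect_lt(worst, 1e-10)
})

test_that("ideal-solution and pure-component limits are respected", {
  ids <- c("a", "b")
  geo <- component_geometry(ids, r = c(3, 3), q = c(2.4, 2.4))
  si <- symmetric_interactions(ids, matrix(-700, 2, 2))
  # identical geometry and equal energies: ideal solution, ln gamma = 0
  for (x1 in c(0.2, 0.5, 0.9)) {
    expect_equal(unname(ln_gamma(geo, si, mixture_state(ids, c(x1, 1 - x1), 400))),
                 c(0, 0))
  }
  # pure-component normalization
  inst <- local({ set.seed(77); rand_instance(2) })
  v <- ln_gamma(inst$geometries, inst$interactions,
                mixture_state(inst$ids, c(1 - 1e-10, 1e-10), 350))
  expect_lt(abs(v[1]), 1e-6)
  # composition boundary is refused, pointing to the closed-form limit
  expect_error(ln_gamma(inst$geometries, inst$interactions,
                        mixture_state(inst$ids, c(1, 0), 350)),
               "ln_gamma_inf")
  # unknown component
  expect_error(ln_gamma(inst$geometries, inst$interactions,
                        mixture_state(c("c1", "zz"), c(0.5, 0.5), 350)),
               "unknown")
})

test_that("a trace third component reduces to the binary evaluation", {
  set.seed(55)
  inst <- rand_instance(3)
  v3 <- ln_gamma(inst$geometries, inst$interactions,
                 mixture_state(inst$ids, c(0.4, 0.6 - 1e-12, 1e-12), 330))
  v2 <- ln_gamma(inst$geometries, inst$interactions,
                 mixture_state(inst$ids[1:2], c(0.4, 0.6), 330))
  expect_equal(v3[1:2], v2, tolerance = 1e-8)
})

test_that("symmetric and converted-deltaU parameterizations agree to rounding", {
  set.seed(66)
  for (rep in 1:20) {
    inst <- rand_instance(sample(2:4, 1))
    st <- mixture_state(inst$ids, inst$x, inst$T)
    v1 <- ln_gamma(inst$geometries, inst$interactions, st)
    v2 <- ln_gamma(inst$geometries, delta_from_symmetric(inst$interactions), st)
    expect_lt(max(abs(v1 - v2)), 1e-12)
  }
})

test_that("infinite-dilution closed form equals the numerical limit", {
  set.seed(88)
  for (rep in 1:50) {
    inst <- rand_instance(2)
    vinf <- ln_gamma_inf(inst$geometries, inst$interactions,
                         inst$ids[1], inst$ids[2], inst$T)
    vlim <- ln_gamma(inst$geometries, inst$interactions,
                     mixture_state(inst$ids, c(1e-9, 1 - 1e-9), inst$T))[1]
    expect_equal(vinf, unname(vlim), tolerance = 1e-6)
  }
  # swapping solute and solvent changes the value for an asymmetric system
  inst <- local({ set.seed(3); rand_instance(2) })
  expect_gt(abs(ln_gamma_inf(inst$geometries, inst$interactions,
                             inst$ids[1], inst$ids[2], 350) -
                ln_gamma_inf(inst$geometries, inst$interactions,
                             inst$ids[2], inst$ids[1], 350)), 1e-4)
  expect_error(ln_gamma_inf(inst$geometries, inst$interactions,
                            inst$ids[1], inst$ids[1], 350), "differ")
})

test_that("binary activity coefficients satisfy the Gibbs-Duhem relation", {
  set.seed(99)
  h <- 1e-6
  worst <- 0
  for (rep in 1:20) {
    inst <- rand_instance(2)
    for (x1 in seq(0.06, 0.94, length.out = 10)) {
      lg <- function(xx) ln_gamma(inst$geometries, inst$interactions,
                                  mixture_state(inst$ids, c(xx, 1 - xx), inst$T))
      d <- (lg(x1 + h) - lg(x1 - h)) / (2 * h)
      worst <- max(worst, abs(x1 * d[1] + (1 - x1) * d[2]))
    }
  }
  expect_lt(worst, 1e-6)
})
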