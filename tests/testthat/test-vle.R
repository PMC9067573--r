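test_that("Antoine vapor pressures follow the closed form and its guards", {
  ant <- antoine_table("w", A = 7.0, B = 1700, C = -40,
                       T_min = 250, T_max = 550)
  expect_equal(vapor_pressure(ant, "w", 373.15), 10^(7.0 - 1700 / (373.15 - 40)))
  # degenerate coefficients give 1 kPa at any temperature
  ant0 <- antoine_table("z", A = 0, B = 0, C = -40, T_min = 250, T_max = 550)
  expect_equal(vapor_pressure(ant0, "z", 300), 1)
  # monotone increasing in T for B > 0
  Ts <- seq(260, 540, by = 20)
  ps <- vapor_pressure(ant, "w", Ts)
  expect_true(all(diff(ps) > 0))
  expect_warning(vapor_pressure(ant, "w", 600), "extrapolation")
  expect_error(vapor_pressure(ant, "w", 30), "T \\+ C")
})

test_that("bubble points reduce to Antoine inversion for pure liquids and match a grid oracle for ideal mixtures", {
  fx <- vle_fixture()
  # pure component: T solves p_s(T) = P
  P400 <- vapor_pressure(fx$antoine, "A", 400)
  bp <- bubble_point_T(P400, c(1, 0), fx$ids, fx$geometries, fx$interactions,
                       fx$antoine)
  expect_equal(bp$T, 400, tolerance = 1e-6)
  expect_equal(unname(bp$y), c(1, 0))

  # ideal mixture (identical geometry, equal energies -> gamma = 1):
  # compare against a dense temperature-grid search of Raoult's law
  ids <- fx$ids
  geo_id <- component_geometry(ids, r = c(2, 2), q = c(2, 2))
  si_id <- symmetric_interactions(ids, matrix(-1000, 2, 2))
  for (case in list(c(0.3, 50), c(0.7, 101.325))) {
    x1 <- case[1]; P <- case[2]
    bb <- bubble_point_T(P, c(x1, 1 - x1), ids, geo_id, si_id, fx$antoine)
    Tg <- seq(300, 450, by = 5e-4)
    f <- x1 * 10^(7.0 - 1700 / (Tg - 40)) + (1 - x1) * 10^(6.8 - 1600 / (Tg - 50)) - P
    expect_lt(abs(bb$T - Tg[which.min(abs(f))]), 0.01)
  }

  # relabeling symmetry: identical components mirror around x1 = 1/2
  geo_s <- component_geometry(ids, r = c(3, 3), q = c(2.5, 2.5))
  ant_s <- antoine_table(ids, A = c(7, 7), B = c(1700, 1700), C = c(-40, -40),
                         T_min = c(250, 250), T_max = c(550, 550))
  si_s <- symmetric_interactions(ids, matrix(c(-2000, -1500, -1500, -2000), 2, 2))
  b1 <- bubble_point_T(101.325, c(0.23, 0.77), ids, geo_s, si_s, ant_s)
  b2 <- bubble_point_T(101.325, c(0.77, 0.23), ids, geo_s, si_s, ant_s)
  expect_equal(b1$T, b2$T, tolerance = 1e-8)
})

test_that("dew points agree with bubble points at purity and close the round trip", {
  fx <- vle_fixture()
  bpure <- bubble_point_T(101.325, c(0, 1), fx$ids, fx$geometries,
                          fx$interactions, fx$antoine)
  dpure <- dew_point_T(101.325, c(0, 1), fx$ids, fx$geometries,
                       fx$interactions, fx$antoine)
  expect_equal(bpure$T, dpure$T)

  # ideal mixture dew point against the grid oracle
  ids <- fx$ids
  geo_id <- component_geometry(ids, r = c(2, 2), q = c(2, 2))
  si_id <- symmetric_interactions(ids, matrix(-1000, 2, 2))
  y1 <- 0.4; P <- 80
  dd <- dew_point_T(P, c(y1, 1 - y1), ids, geo_id, si_id, fx$antoine)
  Tg <- seq(300, 450, by = 5e-4)
  f <- y1 * P / 10^(7.0 - 1700 / (Tg - 40)) +
    (1 - y1) * P / 10^(6.8 - 1600 / (Tg - 50)) - 1
  expect_lt(abs(dd$T - Tg[which.min(abs(f))]), 0.01)

  # round trip: bubble at the dew-point liquid reproduces (T, y)
  for (y1 in c(0.2, 0.5, 0.8)) {
    dd <- dew_point_T(101.325, c(y1, 1 - y1), fx$ids, fx$geometries,
                      fx$interactions, fx$antoine)
    bb <- bubble_point_T(101.325, dd$x, fx$ids, fx$geometries,
                         fx$interactions, fx$antoine)
    expect_lt(abs(bb$T - dd$T), 1e-6)
    expect_lt(abs(bb$y[1] - y1), 1e-6)
    expect_lt(abs(sum(dd$x) - 1), 1e-10)
    expect_lt(abs(sum(bb$y) - 1), 1e-10)
  }
})

test_that("isobaric diagrams pin their endpoints, bracket dew above bubble, and are parameterization invariant", {
  fx <- vle_fixture()
  d1 <- isobaric_diagram(101.325, fx$ids, fx$geometries, fx$interactions,
                         fx$antoine, n_grid = 21)
  TbA <- 1700 / (7.0 - log10(101.325)) + 40
  TbB <- 1600 / (6.8 - log10(101.325)) + 50
  expect_equal(d1$T_bubble_K[d1$x1 == 1], TbA, tolerance = 1e-6)
  expect_equal(d1$T_bubble_K[d1$x1 == 0], TbB, tolerance = 1e-6)
  expect_equal(d1$T_dew_K[d1$x1 == 1], TbA, tolerance = 1e-6)
  # dew curve lies at or above the bubble curve at the same composition value
  expect_true(all(d1$T_dew_K >= d1$T_bubble_K - 1e-8))
  # identical diagram under the converted deltaU parameterization
  d2 <- isobaric_diagram(101.325, fx$ids, fx$geometries,
                         delta_from_symmetric(fx$interactions), fx$antoine,
                         n_grid = 21)
  expect_lt(max(abs(d1$T_bubble_K - d2$T_bubble_K)), 1e-10)
  expect_lt(max(abs(d1$T_dew_K - d2$T_dew_K)), 1e-10)
  expect_true(all(d1$y1_at_bubble >= -1e-10 & d1$y1_at_bubble <= 1 + 1e-10))
})

test_that("azeotropes are found exactly when symmetry forces them and not for ideal mixtures", {
  ids <- c("A", "B")
  geo <- component_geometry(ids, r = c(2.1, 3.2), q = c(1.9, 2.8))
  ant_diff <- antoine_table(ids, A = c(7.0, 6.8), B = c(1700, 1600),
                            C = c(-40, -50), T_min = c(250, 250),
                            T_max = c(550, 550))
  # ideal mixture with different boiling points: no azeotrope
  geo_id <- component_geometry(ids, r = c(2, 2), q = c(2, 2))
  si_id <- symmetric_interactions(ids, matrix(-1000, 2, 2))
  expect_false(find_azeotrope(101.325, ids, geo_id, si_id, ant_diff)$exists)

  # identical Antoine parameters with a nonzero interaction: an azeotrope
  # exists by symmetry, and it satisfies the root contract
  ant_same <- antoine_table(ids, A = c(7, 7), B = c(1700, 1700), C = c(-40, -40),
                            T_min = c(250, 250), T_max = c(550, 550))
  si_pos <- symmetric_interactions(ids, matrix(c(-2500, 500, 500, -2500), 2, 2))
  az <- find_azeotrope(101.325, ids, geo, si_pos, ant_same)
  expect_true(az$exists)
  bb <- bubble_point_T(101.325, c(az$x1, 1 - az$x1), ids, geo, si_pos, ant_same)
  expect_lt(abs(bb$y[1] - az$x1), 1e-8)
  # strong positive deviation: minimum-boiling azeotrope below both pure points
  expect_lt(az$T, 1700 / (7 - log10(101.325)) + 40)
})

test_that("ternary vapor predictions honor vertices, edges, and the simplex", {
  ids3 <- c("A", "B", "C")
  geo3 <- component_geometry(ids3, r = c(2.1, 3.2, 4), q = c(1.9, 2.8, 3.5))
  ant3 <- antoine_table(ids3, A = c(7, 6.8, 6.5), B = c(1700, 1600, 1500),
                        C = c(-40, -50, -45), T_min = rep(250, 3),
                        T_max = rep(550, 3))
  U3 <- matrix(c(-2500, -500, -800, -500, -2000, -300, -800, -300, -1500), 3, 3)
  si3 <- symmetric_interactions(ids3, U3)

  # vertex: pure boiling point, vapor at the same vertex
  v <- predict_ternary_vapor(101.325, c(0, 0, 1), ids3, geo3, si3, ant3)
  expect_equal(v$T, 1500 / (6.5 - log10(101.325)) + 45, tolerance = 1e-6)
  expect_equal(unname(v$y), c(0, 0, 1))

  # edge x3 = 0 reduces to the binary bubble point of components 1-2
  t3 <- predict_ternary_vapor(101.325, c(0.4, 0.6, 0), ids3, geo3, si3, ant3)
  b2 <- bubble_point_T(101.325, c(0.4, 0.6), ids3[1:2], geo3, si3, ant3)
  expect_lt(abs(t3$T - b2$T), 1e-8)
  expect_lt(max(abs(t3$y[1:2] - b2$y)), 1e-8)

  # interior compositions: vapor on the simplex
  set.seed(71)
  for (rep in 1:20) {
    x <- rgamma(3, 1); x <- x / sum(x)
    x <- 0.97 * x + 0.01; x <- x / sum(x)
    t3 <- predict_ternary_vapor(101.325, x, ids3, geo3, si3, ant3)
    expect_lt(abs(sum(t3$y) - 1), 1e-8)
    expect_true(all(t3$y >= 0))
  }
})

test_that("Antoine tables round-trip with their dialect header", {
  fx <- vle_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_antoine(fx$antoine, path)
  expect_match(readLines(path, n = 1), "log10\\(p_s/kPa\\)")
  back <- read_antoine(path)
  expect_equal(back$A, fx$antoine$A)
  expect_equal(back$T_max_K, fx$antoine$T_max_K)
})
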