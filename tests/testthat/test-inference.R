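# small dense synthetic problem reused across fitting tests
tiny_problem <- function(noise = 0, seed = 31L, N = 8L, K = 2L,
                         fraction = 1, records = 10L) {
  cfg <- generator_config(N_components = N, K_true = K,
                          observed_system_fraction = fraction,
                          records_per_system = records,
                          infinite_dilution_fraction = 0.2,
                          noise_scale = noise, seed = seed)
  truth <- generate_truth(cfg)
  list(truth = truth, obs = generate_observations(truth), cfg = cfg)
}

test_that("dataset construction enforces the record invariants", {
  base <- data.frame(id_i = "a", id_j = "b", T_K = 300, x_i = 0.5,
                     ln_gamma = 0.2, record_type = "finite")
  expect_s3_class(observation_dataset(base), "gamma_dataset")
  bad <- base; bad$x_i <- 0
  expect_error(observation_dataset(bad), "infinite_dilution")
  bad <- base; bad$record_type <- "infinite_dilution"
  expect_error(observation_dataset(bad), "infinite_dilution")
  bad <- base; bad$T_K <- -5
  expect_error(observation_dataset(bad), "T_K")
  bad <- base; bad$id_j <- "a"
  expect_error(observation_dataset(bad), "distinct")
})

test_that("splitting is by system, deterministic, and exhaustive", {
  set.seed(41)
  ids <- sprintf("c%02d", 1:5)
  pairs <- t(combn(ids, 2))  # 10 systems
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    data.frame(id_i = pairs[k, 1], id_j = pairs[k, 2],
               T_K = runif(3, 280, 400), x_i = runif(3, 0.1, 0.9),
               ln_gamma = rnorm(3), record_type = "finite")
  }))
  ds <- observation_dataset(recs)
  sp <- split_by_system(ds, c(0.8, 0.1, 0.1), seed = 5L)
  expect_identical(as.integer(table(sp$split)[c("train", "validation", "test")]),
                   c(8L, 1L, 1L))
  # records inherit the label of their system
  lab <- sp$split[sp$records$system_key]
  expect_true(all(!is.na(lab)))
  # determinism
  sp2 <- split_by_system(ds, c(0.8, 0.1, 0.1), seed = 5L)
  expect_identical(sp$split, sp2$split)
  # no system straddles partitions, over many seeds
  for (s in 1:100) {
    spl <- split_by_system(ds, c(0.6, 0.2, 0.2), seed = s)$split
    expect_identical(sort(names(spl)), sort(unique(ds$records$system_key)))
    expect_identical(anyDuplicated(names(spl)), 0L)
  }
  expect_error(split_by_system(observation_dataset(recs[1:3, ]), seed = 1),
               "at least 3 systems")
})

test_that("log_joint equals the analytic prior maximum with no data and adds exact likelihood terms", {
  ids <- c("a", "b")
  geo <- component_geometry(ids, r = c(2, 3), q = c(1.8, 2.6))
  priors <- prior_spec()
  K <- 2L
  empty <- observation_dataset(
    data.frame(id_i = character(), id_j = character(), T_K = numeric(),
               x_i = numeric(), ln_gamma = numeric(), record_type = character()))
  # prior mode: zero features, like energies at the prior location
  f_mode <- latent_features(ids, matrix(0, 2, K), matrix(0, 2, K),
                            rep(priors$like_energy_loc, 2))
  # analytic maximum of the log prior (internal Kelvin parameterization)
  sf <- (300^2 / (2 * K))^(1 / 4)
  sl <- priors$like_energy_scale / 8.314462618
  lp_max <- -2 * 2 * K * log(sf * sqrt(2 * pi)) - 2 * log(sl * sqrt(2 * pi))
  expect_equal(log_joint(f_mode, empty, priors, geo), lp_max)
  # any other parameter value scores lower
  f_off <- latent_features(ids, matrix(5, 2, K), matrix(-3, 2, K), c(100, -100))
  expect_lt(log_joint(f_off, empty, priors, geo), lp_max)

  # one record placed exactly at the model prediction adds -log(sigma sqrt(2 pi))
  si <- assemble_interactions(f_off)
  pred <- ln_gamma(geo, si, mixture_state(ids, c(0.3, 0.7), 350))[1]
  one <- observation_dataset(data.frame(id_i = "a", id_j = "b", T_K = 350,
                                        x_i = 0.3, ln_gamma = unname(pred),
                                        record_type = "finite"))
  expect_equal(log_joint(f_off, one, priors, geo) -
                 log_joint(f_off, empty, priors, geo),
               -log(priors$likelihood_scale * sqrt(2 * pi)))
})

test_that("analytic log-joint gradients match central differences", {
  prob <- tiny_problem(noise = 0.05, seed = 43L, N = 4L)
  priors <- prior_spec()
  roster <- prob$truth$features$component_ids
  n <- length(roster); K <- 2L
  pd <- mcmuniquac:::.prep_records(prob$obs$records, prob$truth$geometries, roster)
  set.seed(9)
  theta <- matrix(rnorm(n * K, 0, 5), n, K)
  beta <- matrix(rnorm(n * K, 0, 5), n, K)
  ulike <- rnorm(n, -300, 50)
  g <- mcmuniquac:::.log_joint_grad(pd, theta, beta, ulike, priors, K)
  pack <- mcmuniquac:::.pack(theta, beta, ulike)
  ga <- mcmuniquac:::.pack(g$gtheta, g$gbeta, g$gulike)
  h <- 1e-4
  for (idx in sample(length(pack), 12)) {
    up <- pack; up[idx] <- up[idx] + h
    dn <- pack; dn[idx] <- dn[idx] - h
    fu <- mcmuniquac:::.unpack(up, n, K)
    fd <- mcmuniquac:::.unpack(dn, n, K)
    gn <- (mcmuniquac:::.log_joint_grad(pd, fu$theta, fu$beta, fu$ulike,
                                        priors, K, grad = FALSE)$lp -
             mcmuniquac:::.log_joint_grad(pd, fd$theta, fd$beta, fd$ulike,
                                          priors, K, grad = FALSE)$lp) / (2 * h)
    expect_equal(ga[idx], gn, tolerance = 1e-4)
  }
})

test_that("MAP fitting interpolates noise-free data and is deterministic", {
  prob <- tiny_problem(noise = 0, seed = 31L)
  priors <- prior_spec()
  fit <- fit_map(prob$obs, priors, prob$truth$geometries, K = 2, seed = 8L)
  expect_lt(evaluate_fit(fit, prob$obs, split = NULL)$MAE, 0.01)
  fit2 <- fit_map(prob$obs, priors, prob$truth$geometries, K = 2, seed = 8L)
  expect_identical(fit$features$theta, fit2$features$theta)
  expect_identical(fit$features$like_energies, fit2$features$like_energies)

  # a weaker data term (larger likelihood scale) cannot improve the data fit
  loose <- prior_spec(likelihood_scale = 2 * priors$likelihood_scale)
  fit_loose <- fit_map(prob$obs, loose, prob$truth$geometries, K = 2, seed = 8L)
  expect_gte(evaluate_fit(fit_loose, prob$obs, split = NULL)$MAE + 1e-9,
             evaluate_fit(fit, prob$obs, split = NULL)$MAE)
})

test_that("variational fitting agrees with MAP and orders uncertainty by information", {
  prob <- tiny_problem(noise = 0.05, seed = 7L, N = 8L, records = 12L)
  priors <- prior_spec(likelihood_scale = 0.1)
  map <- fit_map(prob$obs, priors, prob$truth$geometries, K = 2, seed = 5L)
  vi <- fit_vi(prob$obs, priors, prob$truth$geometries, K = 2, seed = 5L,
               n_steps = 3000)
  ids <- prob$truth$features$component_ids
  pr <- t(combn(ids, 2))
  pe_map <- pair_energy_summary(map, pr[, 1], pr[, 2])
  pe_vi <- pair_energy_summary(vi, pr[, 1], pr[, 2], n_draws = 2000, seed = 3)
  expect_true(all(is.na(pe_map$sd)))
  expect_true(all(pe_vi$sd > 0))
  z <- abs(pe_vi$mean - pe_map$mean) / pe_vi$sd
  expect_gte(mean(z < 2), 0.95)

  # pairs with data have tighter posteriors than never-observed pairs
  prob_sparse <- tiny_problem(noise = 0.05, seed = 8L, N = 10L, fraction = 0.4,
                              records = 12L)
  vi_sp <- fit_vi(prob_sparse$obs, priors, prob_sparse$truth$geometries,
                  K = 2, seed = 5L, n_steps = 3000)
  ids_sp <- prob_sparse$truth$features$component_ids
  allp <- t(combn(ids_sp, 2))
  keys <- mcmuniquac:::system_key(allp[, 1], allp[, 2])
  seen <- keys %in% unique(prob_sparse$obs$records$system_key)
  pe <- pair_energy_summary(vi_sp, allp[, 1], allp[, 2], n_draws = 1000, seed = 4)
  expect_lt(median(pe$sd[seen]), median(pe$sd[!seen]))
})

test_that("a priors-only variational fit returns the prior", {
  ids <- c("a", "b", "c")
  geo <- component_geometry(ids, r = c(2, 3, 4), q = c(1.8, 2.6, 3.4))
  empty <- observation_dataset(
    data.frame(id_i = character(), id_j = character(), T_K = numeric(),
               x_i = numeric(), ln_gamma = numeric(), record_type = character()))
  priors <- prior_spec()
  vi <- fit_vi(empty, priors, geo, K = 2, seed = 2L, n_steps = 2000)
  # variational means near the prior mode, sds near the prior scale
  sf_ext <- (300^2 / 4)^(1 / 4) * sqrt(8.314462618)
  expect_lt(mean(abs(vi$features$theta)), 0.5 * sf_ext)
  expect_lt(abs(mean(vi$features$like_energies) - priors$like_energy_loc),
            0.5 * priors$like_energy_scale)
  expect_gt(median(vi$sd$theta) / sf_ext, 0.5)
})

test_that("per-system baselines nest as expected and expose the deltaU inconsistency", {
  # noise-free symmetric truth: both parameterizations reach ~zero residual
  prob0 <- tiny_problem(noise = 0, seed = 31L)
  b0U <- fit_per_system_baseline(prob0$obs, prob0$truth$geometries, "U")
  b0D <- fit_per_system_baseline(prob0$obs, prob0$truth$geometries, "deltaU")
  expect_lt(b0U$MAE, 1e-3)
  expect_lt(b0D$MAE, 1e-3)

  # noisy data: the 2-parameter-per-system fit is at least as flexible
  prob <- tiny_problem(noise = 0.1, seed = 21L, N = 10L, fraction = 0.8,
                       records = 15L)
  bU <- fit_per_system_baseline(prob$obs, prob$truth$geometries, "U")
  bD <- fit_per_system_baseline(prob$obs, prob$truth$geometries, "deltaU")
  expect_lte(bD$MSE, bU$MSE + 1e-10)

  # independently fitted deltaU over >= 3 noisy systems cannot be explained
  # by any symmetric energy set
  rep <- check_delta_consistency(baseline_delta_set(bD))
  expect_false(rep$consistent)
  expect_gt(rep$max_abs_residual, 1)

  # a system with a single record and two parameters is flagged
  recs1 <- prob$obs$records
  one_sys <- recs1$system_key == recs1$system_key[1]
  few <- observation_dataset(rbind(recs1[which(one_sys)[1], , drop = FALSE],
                                   recs1[!one_sys, ][1:30, ]))
  expect_warning(fit_per_system_baseline(few, prob$truth$geometries, "deltaU"),
                 "fewer records")
})

test_that("evaluation metrics follow their closed forms", {
  prob <- tiny_problem(noise = 0, seed = 31L, N = 4L, records = 4L)
  fit <- fit_map(prob$obs, prior_spec(), prob$truth$geometries, K = 2, seed = 8L)
  ev <- evaluate_fit(fit, prob$obs, split = NULL)
  # noise-free interpolation: MAE and MSE ~ 0
  expect_lt(ev$MAE, 0.01)
  expect_identical(ev$n_records, nrow(prob$obs$records))

  # constant offset delta: MAE = |delta|, MSE = delta^2
  delta <- 0.37
  shifted <- prob$obs
  shifted$records$ln_gamma <- shifted$records$ln_gamma + delta
  ev2 <- evaluate_fit(fit, shifted, split = NULL)
  expect_equal(ev2$MAE, delta, tolerance = 0.01)
  expect_equal(ev2$MSE, delta^2, tolerance = 0.01)

  # MAE <= sqrt(MSE) on arbitrary prediction/observation vectors
  set.seed(61)
  for (rep in 1:20) {
    e <- rnorm(50, sd = runif(1, 0.1, 3))
    expect_lte(mean(abs(e)), sqrt(mean(e^2)))
  }
  sp <- split_by_system(prob$obs, seed = 3L)
  expect_error(evaluate_fit(fit, sp, split = "nope"), "empty")
})

test_that("hyperparameter selection returns the validation argmin", {
  prob <- tiny_problem(noise = 0.05, seed = 51L, N = 8L, fraction = 0.9,
                       records = 8L)
  ds <- split_by_system(prob$obs, seed = 4L)
  grid1 <- data.frame(K = 2L)
  sel1 <- select_hyperparameters(ds, prob$truth$geometries, grid1, seed = 6L)
  expect_identical(sel1$best$K, 2L)

  grid <- data.frame(K = c(1L, 2L, 3L))
  sel <- select_hyperparameters(ds, prob$truth$geometries, grid, seed = 6L)
  expect_true(all(sel$best$validation_MAE <=
                    sel$results$validation_MAE[!is.na(sel$results$validation_MAE)]))
  expect_equal(evaluate_fit(sel$best_fit, ds, "validation")$MAE,
               sel$best$validation_MAE)
})
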