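#' Prior and likelihood specification
#'
#' Priors for end-to-end training of the hybrid model. Internally the model
#' works with energies expressed as U/R in Kelvin for numerical
#' conditioning; all interface values are in J/mol. `feature_scale` is a
#' dimensionless multiplier of a conditioned base scale chosen so that at
#' `feature_scale = 1` the prior standard deviation of a reconstructed
#' unlike pair energy U_ij/R is about 300 K regardless of the latent
#' dimension K.
#'
#' @param feature_scale dimensionless prior-scale multiplier for the latent
#'   features (> 0).
#' @param like_energy_loc,like_energy_scale Gaussian prior location and
#'   scale for the like energies U_ii, in J/mol (scale > 0; the default
#'   scale corresponds to 500 K on U_ii/R).
#' @param likelihood_family `"gaussian"` or `"cauchy"` observation noise on
#'   ln gamma.
#' @param likelihood_scale scale of the observation-noise distribution on
#'   ln gamma (> 0).
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(feature_scale = 1,
                       like_energy_loc = 0,
                       like_energy_scale = 500 * 8.314462618,
                       likelihood_family = c("gaussian", "cauchy"),
                       likelihood_scale = 0.15) {
  likelihood_family <- match.arg(likelihood_family)
  .assert(feature_scale > 0 && like_energy_scale > 0 && likelihood_scale > 0,
          "all scales must be > 0")
  structure(list(feature_scale = feature_scale,
                 like_energy_loc = like_energy_loc,
                 like_energy_scale = like_energy_scale,
                 likelihood_family = likelihood_family,
                 likelihood_scale = likelihood_scale),
            class = "prior_spec")
}

# prior sd (Kelvin units) of one latent feature entry such that
# sd(U_ij/R) = sqrt(2 K sf^4) ~= 300 K at feature_scale = 1
.feature_base_scale <- function(K) (300^2 / (2 * K))^(1 / 4)

# ---- internal fit-data preparation ----------------------------------------

# Flattens the records of one split into aligned vectors indexed against a
# component roster; precomputes r, q and pair keys. Energies handled in K.
.prep_records <- function(records, geometries, roster) {
  ia <- .match_ids(records$id_i, roster)
  ib <- .match_ids(records$id_j, roster)
  rqa <- .geom_rq(geometries, records$id_i)
  rqb <- .geom_rq(geometries, records$id_j)
  n <- length(roster)
  pmin_i <- pmin(ia, ib); pmax_i <- pmax(ia, ib)
  list(ia = ia, ib = ib,
       r1 = rqa$r, q1 = rqa$q, r2 = rqb$r, q2 = rqb$q,
       x1 = records$x_i, T = records$T_K, obs = records$ln_gamma,
       pair_key = (pmin_i - 1L) * n + pmax_i,
       n_roster = n, n_records = nrow(records))
}

# model predictions (and energy gradients) for prepared records, given
# internal parameters: theta, beta (N x K, Kelvin-unit features), ulike (K)
.predict_prepped <- function(pd, theta, beta, ulike, grad = FALSE) {
  P <- tcrossprod(theta, beta)
  Usym <- P + t(P)                      # u_ij (K), diagonal irrelevant
  u12 <- Usym[cbind(pd$ia, pd$ib)]
  u11 <- ulike[pd$ia]
  u22 <- ulike[pd$ib]
  .binary_lngamma_grad(pd$r1, pd$q1, pd$r2, pd$q2, pd$x1, pd$T,
                       u11, u22, u12, grad = grad)
}

# log likelihood value and d(loglik)/d(prediction) per record
.loglik_terms <- function(e, priors) {
  s <- priors$likelihood_scale
  if (priors$likelihood_family == "gaussian") {
    list(lp = sum(-e^2 / (2 * s^2)) - length(e) * log(s * sqrt(2 * pi)),
         w = -e / s^2)
  } else {
    list(lp = sum(stats::dcauchy(e, 0, s, log = TRUE)),
         w = -2 * e / (s^2 + e^2))
  }
}

# Full log joint (Kelvin-unit parameters) with analytic gradients.
# Returns list(lp, gtheta, gbeta, gulike).
.log_joint_grad <- function(pd, theta, beta, ulike, priors, K, grad = TRUE) {
  n <- length(ulike)
  sf <- priors$feature_scale * .feature_base_scale(K)
  loc <- priors$like_energy_loc / .R_GAS
  sl <- priors$like_energy_scale / .R_GAS

  lp <- -sum(theta^2 + beta^2) / (2 * sf^2) -
    2 * n * K * log(sf * sqrt(2 * pi)) -
    sum((ulike - loc)^2) / (2 * sl^2) - n * log(sl * sqrt(2 * pi))

  if (pd$n_records > 0L) {
    pr <- .predict_prepped(pd, theta, beta, ulike, grad = grad)
    ll <- .loglik_terms(pr$value - pd$obs, priors)
    lp <- lp + ll$lp
  }
  if (!grad) return(list(lp = lp))

  gtheta <- -theta / sf^2
  gbeta <- -beta / sf^2
  gulike <- -(ulike - loc) / sl^2
  if (pd$n_records > 0L) {
    w <- ll$w
    # gradient w.r.t. each unlike energy, aggregated over records per pair
    agg <- rowsum(w * pr$g12, pd$pair_key)
    keys <- as.integer(rownames(agg))
    G <- matrix(0, n, n)
    a <- (keys - 1L) %/% n + 1L
    b <- (keys - 1L) %% n + 1L
    G[cbind(a, b)] <- agg[, 1L]
    G[cbind(b, a)] <- agg[, 1L]
    gtheta <- gtheta + G %*% beta
    gbeta <- gbeta + G %*% theta
    g1 <- rowsum(w * pr$g11, pd$ia)
    g2 <- rowsum(w * pr$g22, pd$ib)
    gulike[as.integer(rownames(g1))] <- gulike[as.integer(rownames(g1))] + g1[, 1L]
    gulike[as.integer(rownames(g2))] <- gulike[as.integer(rownames(g2))] + g2[, 1L]
  }
  list(lp = lp, gtheta = gtheta, gbeta = gbeta, gulike = gulike)
}

# parameter packing for the optimizer (internal Kelvin units)
.pack <- function(theta, beta, ulike) c(as.vector(theta), as.vector(beta), ulike)
.unpack <- function(par, n, K) {
  list(theta = matrix(par[seq_len(n * K)], n, K),
       beta = matrix(par[n * K + seq_len(n * K)], n, K),
       ulike = par[2L * n * K + seq_len(n)])
}

# convert internal (Kelvin) parameters to an interface latent_features
# object in J/mol: features scale with sqrt(R), like energies with R
.features_external <- function(roster, theta, beta, ulike) {
  latent_features(roster, theta * sqrt(.R_GAS), beta * sqrt(.R_GAS),
                  ulike * .R_GAS)
}
.features_internal <- function(features) {
  list(theta = features$theta / sqrt(.R_GAS),
       beta = features$beta / sqrt(.R_GAS),
       ulike = features$like_energies / .R_GAS)
}

#' Log joint density of the hybrid model
#'
#' Sum of the log prior over all latent features and like energies and the
#' log likelihood of the observed ln gamma records around the model
#' predictions ([ln_gamma()] for finite records, [ln_gamma_inf()] for
#' infinite-dilution records). Only the train split is used when the
#' dataset carries split labels.
#'
#' @param params a [latent_features()] object (interface units, J/mol).
#' @param dataset a [observation_dataset()].
#' @param priors a [prior_spec()].
#' @param geometries a [component_geometry()] table.
#' @param split which split to use (default `"train"` when labels exist,
#'   otherwise all records).
#' @return Scalar log joint density.
#' @export
log_joint <- function(params, dataset, priors, geometries,
                      split = if (is.null(dataset$split)) NULL else "train") {
  .assert(inherits(params, "latent_features"), "params must be latent_features")
  recs <- .split_records(dataset, split)
  pd <- .prep_records(recs, geometries, params$component_ids)
  ip <- .features_internal(params)
  .log_joint_grad(pd, ip$theta, ip$beta, ip$ulike, priors, params$K,
                  grad = FALSE)$lp
}

# shared seeded initialization for MAP and VI (internal units)
.init_params <- function(n, K, priors, seed, init_scale = 0.5) {
  sf <- priors$feature_scale * .feature_base_scale(K)
  with_seed(seed, list(
    theta = matrix(stats::rnorm(n * K, 0, init_scale * sf), n, K),
    beta = matrix(stats::rnorm(n * K, 0, init_scale * sf), n, K),
    ulike = rep(priors$like_energy_loc / .R_GAS, n)
  ))
}

# Ridge-penalized rank-K factorization of observed symmetric pair energies:
# minimize sum_p (theta_a.beta_b + theta_b.beta_a - u_p)^2 / (2 su^2)
#          + (|theta|^2 + |beta|^2) / (2 sf^2)
# over component features, for sparse observed pairs (a_p, b_p). Used to
# warm-start the end-to-end fit from per-system energy estimates.
#
# Direct optimization at the target rank is prone to deep local minima, so
# the solve is run overparameterized (K_over latent dimensions, where it
# reliably finds the global structure), the reconstruction is compressed
# back to rank K through its eigendecomposition -- the symmetric form
# theta beta' + beta theta' equals A A' - B B' with A = (theta + beta)/sqrt(2),
# B = (theta - beta)/sqrt(2), so the top-K positive and top-K negative
# eigenpairs convert exactly to K-dimensional features -- and the result is
# refined at rank K. Deterministic given `seeds`; best candidate by
# penalized objective wins.
.factorize_pairs <- function(a, b, u_obs, n, K, sf, seeds, su = 10) {
  make_fg <- function(Kf, sff) {
    function(par, want_grad) {
      th <- matrix(par[seq_len(n * Kf)], n, Kf)
      be <- matrix(par[n * Kf + seq_len(n * Kf)], n, Kf)
      pred <- rowSums(th[a, , drop = FALSE] * be[b, , drop = FALSE]) +
        rowSums(th[b, , drop = FALSE] * be[a, , drop = FALSE])
      e <- pred - u_obs
      if (!want_grad) {
        return(sum(e^2) / (2 * su^2) + (sum(th^2) + sum(be^2)) / (2 * sff^2))
      }
      W <- matrix(0, n, n)
      w <- e / su^2
      agg <- rowsum(w, (pmin(a, b) - 1L) * n + pmax(a, b))
      keys <- as.integer(rownames(agg))
      ka <- (keys - 1L) %/% n + 1L; kb <- (keys - 1L) %% n + 1L
      W[cbind(ka, kb)] <- agg[, 1L]; W[cbind(kb, ka)] <- agg[, 1L]
      c(as.vector(W %*% be + th / sff^2), as.vector(W %*% th + be / sff^2))
    }
  }
  solve_at <- function(Kf, sff, init) {
    fg <- make_fg(Kf, sff)
    stats::optim(init, function(p) fg(p, FALSE), function(p) fg(p, TRUE),
                 method = "L-BFGS-B",
                 control = list(maxit = 1500L, factr = 1e7))
  }
  unpack2 <- function(par, Kf) {
    list(theta = matrix(par[seq_len(n * Kf)], n, Kf),
         beta = matrix(par[n * Kf + seq_len(n * Kf)], n, Kf))
  }

  # overparameterized solve, best of `seeds` starts
  K_over <- max(2L * K + 2L, 8L)
  sf_over <- .feature_base_scale(K_over) * sf / .feature_base_scale(K)
  best_over <- NULL
  for (s in seeds) {
    init <- with_seed(s, stats::rnorm(2L * n * K_over, 0, 0.5 * sf_over))
    opt <- solve_at(K_over, sf_over, init)
    if (is.null(best_over) || opt$value < best_over$value) best_over <- opt
  }
  po <- unpack2(best_over$par, K_over)
  # eigencompression of the reconstruction to rank K
  M <- tcrossprod(po$theta, po$beta)
  M <- M + t(M)
  ev <- eigen(M, symmetric = TRUE)
  pos <- which(ev$values > 0)
  pos <- pos[order(ev$values[pos], decreasing = TRUE)]
  neg <- which(ev$values < 0)
  neg <- neg[order(ev$values[neg])]
  npos <- min(K, length(pos)); nneg <- min(K, length(neg))
  A <- cbind(ev$vectors[, pos[seq_len(npos)], drop = FALSE] %*%
               diag(sqrt(ev$values[pos[seq_len(npos)]]), npos),
             matrix(0, n, K - npos))
  B <- cbind(ev$vectors[, neg[seq_len(nneg)], drop = FALSE] %*%
               diag(sqrt(-ev$values[neg[seq_len(nneg)]]), nneg),
             matrix(0, n, K - nneg))
  init_c <- c(as.vector((A + B) / sqrt(2)), as.vector((A - B) / sqrt(2)))

  # refine at the target rank; direct random starts serve as fallback
  best <- solve_at(K, sf, init_c)
  for (s in seeds) {
    init <- with_seed(s + 1L, stats::rnorm(2L * n * K, 0, 0.5 * sf))
    opt <- solve_at(K, sf, init)
    if (opt$value < best$value) best <- opt
  }
  unpack2(best$par, K)
}

#' Maximum-a-posteriori fit of the hybrid model
#'
#' Maximizes the log joint ([log_joint()]) over all latent features and
#' like energies with the L-BFGS-B quasi-Newton optimizer driven by
#' analytic gradients. The end-to-end objective is nonconvex, so the
#' default initialization is a deterministic two-stage warm start: (A) a
#' conventional per-system symmetric UNIQUAC fit estimates one pair energy
#' per observed system plus shared like energies; (B) those estimates are
#' factorized into rank-K features by seeded ridge-penalized least squares
#' (several restarts, best kept); (C) the end-to-end objective is then
#' refined from there, with the likelihood scale annealed down to its
#' target value over a few stages (graduated optimization). `init =
#' "random"` instead runs `n_starts` plain seeded random initializations.
#' Both routes are deterministic given `seed`. Returns point estimates (no
#' posterior standard deviations); use
#' [fit_vi()] for uncertainty quantification.
#'
#' @param dataset a [observation_dataset()]; the train split is used when
#'   split labels exist, otherwise all records.
#' @param priors a [prior_spec()].
#' @param geometries a [component_geometry()] table.
#' @param K latent dimension (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @param init `"warm"` (default) or `"random"`.
#' @param n_starts number of factorization (warm) or full (random) restarts.
#' @param maxit iteration cap for the end-to-end stage.
#' @param init_scale initialization sd as a fraction of the feature prior sd.
#' @return An `mcm_fit` object: latent features (J/mol), geometries, priors
#'   and diagnostics (`converged`, `final_log_joint`, `iterations`).
#' @export
fit_map <- function(dataset, priors, geometries, K, seed,
                    init = c("warm", "random"),
                    n_starts = 3L, maxit = 5000L, init_scale = 0.5) {
  .assert(inherits(priors, "prior_spec"), "priors must be a prior_spec")
  .assert(K >= 1L, "K must be >= 1")
  init <- match.arg(init)
  split_name <- if (is.null(dataset$split)) NULL else "train"
  recs <- .split_records(dataset, split_name)
  .assert(nrow(recs) > 0L, "train split is empty")
  roster <- sort(unique(c(dataset$records$id_i, dataset$records$id_j)))
  n <- length(roster)
  pd <- .prep_records(recs, geometries, roster)

  # Graduated optimization: the activity-coefficient likelihood is extremely
  # sharp around records with large |ln gamma| (Boltzmann-factor sensitivity),
  # so the noise scale is annealed down to its target value over a few
  # L-BFGS stages; each stage starts from the previous optimum.
  anneal <- unique(c(pmax(priors$likelihood_scale, c(2, 0.6)),
                     priors$likelihood_scale))
  run_stages <- function(par) {
    iters <- 0L
    for (sig in anneal) {
      pri <- priors
      pri$likelihood_scale <- sig
      fn <- function(p) {
        q <- .unpack(p, n, K)
        -.log_joint_grad(pd, q$theta, q$beta, q$ulike, pri, K, grad = FALSE)$lp
      }
      gr <- function(p) {
        q <- .unpack(p, n, K)
        g <- .log_joint_grad(pd, q$theta, q$beta, q$ulike, pri, K)
        -.pack(g$gtheta, g$gbeta, g$gulike)
      }
      opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = maxit, factr = 1e7))
      par <- opt$par
      iters <- iters + opt$counts[["function"]]
    }
    opt$counts[["function"]] <- iters
    opt
  }

  sf <- priors$feature_scale * .feature_base_scale(K)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_starts))
  best <- NULL
  if (init == "warm") {
    warm <- tryCatch({
      bl <- suppressWarnings(
        fit_per_system_baseline(dataset, geometries, "U", split = split_name))
      like_hat <- bl$like_energies / .R_GAS
      u_hat <- bl$systems$U_ab / .R_GAS
      # The per-system solution is only identified up to a global additive
      # shift of all energies (predictions depend on energy differences).
      # Center the pair energies -- the feature model reconstructs pair
      # energies with near-zero mean -- so the factorization target is low
      # rank; the like energies are shifted consistently.
      c_star <- mean(u_hat)
      ulike0 <- rep(priors$like_energy_loc / .R_GAS, n)
      ulike0[match(names(like_hat), roster)] <- like_hat - c_star
      a <- match(bl$systems$id_a, roster)
      b <- match(bl$systems$id_b, roster)
      fac <- .factorize_pairs(a, b, u_hat - c_star, n, K, sf,
                              seeds = sub_seeds)
      .pack(fac$theta, fac$beta, ulike0)
    }, error = function(e) {
      message("warm start failed (", conditionMessage(e), "); using random init")
      NULL
    })
    if (!is.null(warm)) best <- run_stages(warm)
  }
  if (is.null(best)) {
    for (s in sub_seeds) {
      ini <- .init_params(n, K, priors, s, init_scale)
      opt <- run_stages(.pack(ini$theta, ini$beta, ini$ulike))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  p <- .unpack(best$par, n, K)
  feats <- .features_external(roster, p$theta, p$beta, p$ulike)
  structure(list(features = feats,
                 sd = NULL,
                 geometries = geometries,
                 priors = priors, K = K, seed = seed, method = "map",
                 diagnostics = list(converged = best$convergence == 0L,
                                    final_log_joint = -best$value,
                                    iterations = best$counts[["function"]],
                                    n_starts = n_starts)),
            class = "mcm_fit")
}

#' @export
print.mcm_fit <- function(x, ...) {
  cat(sprintf("MCM-UNIQUAC %s fit: N = %d components, K = %d, log joint = %.3f%s\n",
              toupper(x$method), length(x$features$component_ids), x$K,
              x$diagnostics$final_log_joint,
              if (isTRUE(x$diagnostics$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Mean-field variational fit of the hybrid model
#'
#' Approximate Bayesian inference with a fully factorized Gaussian
#' variational family over all latent features and like energies. The
#' evidence lower bound is maximized by reparameterized stochastic
#' gradients (Adam, with step-size decay); the analytic model gradients of
#' [log_joint()] drive the estimator. Returns variational means and
#' standard deviations; per-pair energy summaries are obtained by sampling
#' the variational posterior (see [pair_energy_summary()]).
#'
#' @inheritParams fit_map
#' @param n_steps number of stochastic gradient steps.
#' @param n_samples Monte-Carlo samples per step.
#' @param lr Adam learning rate (decayed as 1/(1 + t/1000)).
#' @param init `"warm"` (default) initializes the variational means at the
#'   [fit_map()] optimum; `"random"` uses a seeded random initialization.
#' @return An `mcm_fit` object whose `sd` field holds per-parameter
#'   standard deviations (`theta`, `beta`, `like`, interface units).
#' @export
fit_vi <- function(dataset, priors, geometries, K, seed,
                   n_steps = 4000L, n_samples = 1L, lr = 0.02,
                   init = c("warm", "random"), init_scale = 0.5) {
  .assert(inherits(priors, "prior_spec"), "priors must be a prior_spec")
  init <- match.arg(init)
  recs <- .split_records(dataset, if (is.null(dataset$split)) NULL else "train")
  roster <- sort(unique(c(dataset$records$id_i, dataset$records$id_j)))
  if (!length(roster)) roster <- sort(geometries$component_id)  # priors-only fit
  n <- length(roster)
  pd <- .prep_records(recs, geometries, roster)

  sf <- priors$feature_scale * .feature_base_scale(K)
  sl <- priors$like_energy_scale / .R_GAS
  prior_sd <- c(rep(sf, 2L * n * K), rep(sl, n))
  P <- length(prior_sd)

  if (init == "warm" && nrow(recs) > 0L) {
    map <- fit_map(dataset, priors, geometries, K, seed)
    ip <- .features_internal(map$features)
    m <- .pack(ip$theta, ip$beta, ip$ulike)
  } else {
    ini <- .init_params(n, K, priors, seed, init_scale)
    m <- .pack(ini$theta, ini$beta, ini$ulike)
  }
  s <- log(0.1 * prior_sd)            # log posterior sd, started tight

  # Adam state
  mm <- vv <- ms <- vs <- numeric(P)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  elbo_trace <- numeric(0)

  with_seed(seed, {
    for (t in seq_len(n_steps)) {
      gm <- gs <- numeric(P)
      lp_acc <- 0
      for (k in seq_len(n_samples)) {
        z <- stats::rnorm(P)
        par <- m + exp(s) * z
        p <- .unpack(par, n, K)
        g <- .log_joint_grad(pd, p$theta, p$beta, p$ulike, priors, K)
        gv <- .pack(g$gtheta, g$gbeta, g$gulike)
        gm <- gm + gv
        gs <- gs + gv * z * exp(s) + 1    # + d entropy / d s
        lp_acc <- lp_acc + g$lp
      }
      gm <- gm / n_samples; gs <- gs / n_samples
      if (anyNA(gm) || anyNA(gs) || !is.finite(lp_acc)) {
        stop(sprintf("ELBO diverged (NaN) at step %d; last mean |m| = %.3g, mean sd = %.3g",
                     t, mean(abs(m)), mean(exp(s))), call. = FALSE)
      }
      lr_t <- lr / (1 + t / 1000)
      mm <- b1 * mm + (1 - b1) * gm; vv <- b2 * vv + (1 - b2) * gm^2
      ms <- b1 * ms + (1 - b1) * gs; vs <- b2 * vs + (1 - b2) * gs^2
      ch <- 1 - b1^t; cv <- 1 - b2^t
      m <- m + lr_t * (mm / ch) / (sqrt(vv / cv) + eps)
      s <- s + lr_t * (ms / ch) / (sqrt(vs / cv) + eps)
      if (t %% 100L == 0L) {
        elbo_trace <- c(elbo_trace,
                        lp_acc / n_samples + sum(s) + 0.5 * P * log(2 * pi * exp(1)))
      }
    }
  })

  pm <- .unpack(m, n, K)
  ps <- .unpack(exp(s), n, K)
  feats <- .features_external(roster, pm$theta, pm$beta, pm$ulike)
  structure(list(features = feats,
                 sd = list(theta = ps$theta * sqrt(.R_GAS),
                           beta = ps$beta * sqrt(.R_GAS),
                           like = ps$ulike * .R_GAS),
                 geometries = geometries,
                 priors = priors, K = K, seed = seed, method = "vi",
                 diagnostics = list(converged = TRUE,
                                    final_log_joint = utils::tail(elbo_trace, 1L),
                                    elbo_trace = elbo_trace,
                                    iterations = n_steps)),
            class = "mcm_fit")
}

#' Posterior mean and sd of unlike pair energies
#'
#' For a variational fit, draws from the factorized posterior over the
#' latent features of the two components and summarizes the reconstructed
#' U_ij; for a point-estimate (MAP) fit the mean is the plug-in
#' reconstruction and the sd is `NA`. Symmetric in (i, j) by construction.
#'
#' @param fit an `mcm_fit` or [latent_features()] object.
#' @param id_i,id_j equal-length vectors of component ids (i != j).
#' @param n_draws Monte-Carlo draws for the sd (default 1000).
#' @param seed RNG seed for the draws.
#' @return List with numeric vectors `mean` and `sd` (J/mol).
#' @export
pair_energy_summary <- function(fit, id_i, id_j, n_draws = 1000L, seed = 1L) {
  feats <- if (inherits(fit, "mcm_fit")) fit$features else fit
  npair <- length(id_i)
  .assert(length(id_j) == npair, "id_i and id_j must have equal length")
  mean_pt <- vapply(seq_len(npair), function(k)
    predict_pair_energy(feats, id_i[k], id_j[k]), numeric(1))
  if (!inherits(fit, "mcm_fit") || is.null(fit$sd)) {
    return(list(mean = mean_pt, sd = rep(NA_real_, npair)))
  }
  ii <- .match_ids(id_i, feats$component_ids)
  jj <- .match_ids(id_j, feats$component_ids)
  K <- feats$K
  out_mean <- out_sd <- numeric(npair)
  with_seed(seed, {
    for (k in seq_len(npair)) {
      a <- ii[k]; b <- jj[k]
      ta <- matrix(stats::rnorm(n_draws * K, feats$theta[a, ], fit$sd$theta[a, ]),
                   n_draws, K, byrow = TRUE)
      tb <- matrix(stats::rnorm(n_draws * K, feats$theta[b, ], fit$sd$theta[b, ]),
                   n_draws, K, byrow = TRUE)
      ba <- matrix(stats::rnorm(n_draws * K, feats$beta[a, ], fit$sd$beta[a, ]),
                   n_draws, K, byrow = TRUE)
      bb <- matrix(stats::rnorm(n_draws * K, feats$beta[b, ], fit$sd$beta[b, ]),
                   n_draws, K, byrow = TRUE)
      u <- rowSums(ta * bb) + rowSums(tb * ba)
      out_mean[k] <- mean(u)
      out_sd[k] <- stats::sd(u)
    }
  })
  list(mean = out_mean, sd = out_sd)
}

# ---- per-system baselines --------------------------------------------------

#' Conventional per-system UNIQUAC baseline fits
#'
#' Fits UNIQUAC directly to the observed systems, without any latent-feature
#' sharing, by least squares on ln gamma. Two parameterizations:
#' `"deltaU"` fits the two conventional parameters dU_ij and dU_ji
#' independently per system (2 free parameters per system); `"U"` fits one
#' symmetric unlike energy U_ij per system plus like energies U_ii shared
#' and co-fitted across all systems.
#'
#' @param dataset a [observation_dataset()].
#' @param geometries a [component_geometry()] table.
#' @param mode `"U"` or `"deltaU"`.
#' @param split which split to fit on (`NULL` = all records).
#' @return A `uniquac_baseline` object with per-system parameters (J/mol),
#'   shared like energies for mode `"U"`, training `MAE`/`MSE`, and a
#'   `flagged` vector naming unidentifiable systems (fewer records than
#'   free parameters).
#' @export
fit_per_system_baseline <- function(dataset, geometries, mode = c("U", "deltaU"),
                                    split = NULL) {
  mode <- match.arg(mode)
  recs <- .split_records(dataset, split)
  .assert(nrow(recs) > 0L, "no records to fit")
  roster <- sort(unique(c(recs$id_i, recs$id_j)))
  pd <- .prep_records(recs, geometries, roster)
  keys <- sort(unique(recs$system_key))
  key_of_rec <- recs$system_key
  sys_idx <- match(key_of_rec, keys)
  S <- length(keys)
  n <- length(roster)

  # id_a < id_b per system
  parts <- strsplit(keys, "|", fixed = TRUE)
  id_a <- vapply(parts, `[`, character(1), 1L)
  id_b <- vapply(parts, `[`, character(1), 2L)

  if (mode == "deltaU") {
    # record-level: is the measured species the canonical 'a' of its system?
    meas_is_a <- recs$id_i == id_a[sys_idx]
    fit_one <- function(si) {
      sel <- which(sys_idx == si)
      obj <- function(par) {  # par = (du_ab, du_ba) in K
        da <- par[1]; db <- par[2]
        # measured = a: tau12 = tau_ab = exp(-da/T), tau21 = tau_ba = exp(-db/T)
        u22 <- ifelse(meas_is_a[sel], -da, -db)
        u11 <- ifelse(meas_is_a[sel], -db, -da)
        pr <- .binary_lngamma_grad(pd$r1[sel], pd$q1[sel], pd$r2[sel], pd$q2[sel],
                                   pd$x1[sel], pd$T[sel], u11, u22, 0, grad = TRUE)
        e <- pr$value - pd$obs[sel]
        grad_da <- sum(2 * e * ifelse(meas_is_a[sel], -pr$g22, -pr$g11))
        grad_db <- sum(2 * e * ifelse(meas_is_a[sel], -pr$g11, -pr$g22))
        structure(sum(e^2), gradient = c(grad_da, grad_db))
      }
      # a few fixed starts guard against the local minima of the
      # two-parameter tau surface
      starts <- list(c(0, 0), c(1000, 1000), c(-1000, -1000),
                     c(1500, -500), c(-500, 1500))
      best <- NULL
      for (st in starts) {
        opt <- stats::optim(st, function(p) obj(p),
                            function(p) attr(obj(p), "gradient"),
                            method = "BFGS", control = list(maxit = 500))
        if (is.null(best) || opt$value < best$value) best <- opt
      }
      best$par
    }
    par_mat <- t(vapply(seq_len(S), fit_one, numeric(2)))
    systems <- data.frame(system_key = keys, id_a = id_a, id_b = id_b,
                          dU_ab = par_mat[, 1L] * .R_GAS,
                          dU_ba = par_mat[, 2L] * .R_GAS,
                          stringsAsFactors = FALSE)
    flagged <- keys[tabulate(sys_idx, S) < 2L]
    like <- NULL
  } else {
    # joint least squares: u_pair (S) + shared u_like (n), Kelvin units
    obj <- function(par, want_grad = FALSE) {
      upair <- par[seq_len(S)]
      ulike <- par[S + seq_len(n)]
      u12 <- upair[sys_idx]
      pr <- .binary_lngamma_grad(pd$r1, pd$q1, pd$r2, pd$q2, pd$x1, pd$T,
                                 ulike[pd$ia], ulike[pd$ib], u12,
                                 grad = want_grad)
      e <- pr$value - pd$obs
      if (!want_grad) return(sum(e^2))
      w <- 2 * e
      gpair <- rowsum(w * pr$g12, sys_idx)
      gp <- numeric(S); gp[as.integer(rownames(gpair))] <- gpair[, 1L]
      gl <- numeric(n)
      g1 <- rowsum(w * pr$g11, pd$ia); gl[as.integer(rownames(g1))] <- g1[, 1L]
      g2 <- rowsum(w * pr$g22, pd$ib)
      gl[as.integer(rownames(g2))] <- gl[as.integer(rownames(g2))] + g2[, 1L]
      c(gp, gl)
    }
    init <- c(rep(-300, S), rep(-300, n))
    opt <- stats::optim(init, function(p) obj(p), function(p) obj(p, TRUE),
                        method = "L-BFGS-B",
                        control = list(maxit = 3000L, factr = 1e7))
    systems <- data.frame(system_key = keys, id_a = id_a, id_b = id_b,
                          U_ab = opt$par[seq_len(S)] * .R_GAS,
                          stringsAsFactors = FALSE)
    like <- stats::setNames(opt$par[S + seq_len(n)] * .R_GAS, roster)
    flagged <- character(0)
  }
  if (length(flagged)) {
    warning(sprintf("%d system(s) have fewer records than free parameters: %s",
                    length(flagged), paste(utils::head(flagged, 5), collapse = ", ")),
            call. = FALSE)
  }
  out <- structure(list(mode = mode, systems = systems, like_energies = like,
                        geometries = geometries, flagged = flagged),
                   class = "uniquac_baseline")
  pred <- .predict_for_records(out, recs)
  out$MAE <- mean(abs(pred - recs$ln_gamma))
  out$MSE <- mean((pred - recs$ln_gamma)^2)
  out
}

#' @export
print.uniquac_baseline <- function(x, ...) {
  cat(sprintf("Per-system UNIQUAC (%s) baseline: %d systems, training MAE = %.4f\n",
              if (x$mode == "U") "U" else "deltaU", nrow(x$systems), x$MAE))
  invisible(x)
}

#' Convert a mode-"deltaU" baseline to an asymmetric interaction set
#'
#' Collects the independently fitted per-system dU parameters into an
#' [asymmetric_interactions()] set (components outside any fitted system
#' are dropped; pairs never fitted are set to 0).
#'
#' @param baseline a mode-`"deltaU"` `uniquac_baseline`.
#' @return An [asymmetric_interactions()] set.
#' @export
baseline_delta_set <- function(baseline) {
  .assert(inherits(baseline, "uniquac_baseline") && baseline$mode == "deltaU",
          "baseline must be a mode-'deltaU' uniquac_baseline")
  ids <- sort(unique(c(baseline$systems$id_a, baseline$systems$id_b)))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  a <- match(baseline$systems$id_a, ids)
  b <- match(baseline$systems$id_b, ids)
  D[cbind(a, b)] <- baseline$systems$dU_ab
  D[cbind(b, a)] <- baseline$systems$dU_ba
  asymmetric_interactions(ids, D)
}

# ---- prediction and evaluation --------------------------------------------

# model predictions of ln gamma for a record data frame
.predict_for_records <- function(object, recs) {
  if (inherits(object, "mcm_fit") || inherits(object, "latent_features")) {
    feats <- if (inherits(object, "mcm_fit")) object$features else object
    geoms <- if (inherits(object, "mcm_fit")) object$geometries else
      stop("latent_features need an mcm_fit wrapper or explicit geometries", call. = FALSE)
    roster <- feats$component_ids
    pd <- .prep_records(recs, geoms, roster)
    ip <- .features_internal(feats)
    .predict_prepped(pd, ip$theta, ip$beta, ip$ulike, grad = FALSE)$value
  } else if (inherits(object, "uniquac_baseline")) {
    keys <- object$systems$system_key
    si <- match(recs$system_key, keys)
    .assert(!anyNA(si), "records reference systems absent from the baseline fit")
    rq1 <- .geom_rq(object$geometries, recs$id_i)
    rq2 <- .geom_rq(object$geometries, recs$id_j)
    meas_is_a <- recs$id_i == object$systems$id_a[si]
    if (object$mode == "deltaU") {
      da <- object$systems$dU_ab[si] / .R_GAS
      db <- object$systems$dU_ba[si] / .R_GAS
      u22 <- ifelse(meas_is_a, -da, -db)
      u11 <- ifelse(meas_is_a, -db, -da)
      u12 <- 0
    } else {
      u12 <- object$systems$U_ab[si] / .R_GAS
      u11 <- object$like_energies[recs$id_i] / .R_GAS
      u22 <- object$like_energies[recs$id_j] / .R_GAS
    }
    .binary_lngamma_grad(rq1$r, rq1$q, rq2$r, rq2$q, recs$x_i, recs$T_K,
                         u11, u22, u12, grad = FALSE)$value
  } else {
    stop("cannot predict from object of class ", paste(class(object), collapse = "/"),
         call. = FALSE)
  }
}

#' Evaluate predictions on a dataset split
#'
#' Computes the mean absolute error and mean squared error of model
#' predictions of ln gamma over the records of one split, with standard
#' errors of the means and per-system error summaries.
#'
#' @param object an `mcm_fit` or `uniquac_baseline`.
#' @param dataset a [observation_dataset()].
#' @param split `"train"`, `"validation"`, `"test"`, or `NULL` for all
#'   records.
#' @return List with `MAE`, `MSE`, `se_MAE`, `se_MSE`, `n_records`, and a
#'   `per_system` data frame.
#' @export
evaluate_fit <- function(object, dataset, split = "test") {
  recs <- .split_records(dataset, split)
  .assert(nrow(recs) > 0L, "split is empty")
  pred <- .predict_for_records(object, recs)
  ae <- abs(pred - recs$ln_gamma)
  se2 <- (pred - recs$ln_gamma)^2
  per_sys <- stats::aggregate(cbind(MAE = ae, MSE = se2),
                       by = list(system_key = recs$system_key), FUN = mean)
  list(MAE = mean(ae), MSE = mean(se2),
       se_MAE = stats::sd(ae) / sqrt(length(ae)),
       se_MSE = stats::sd(se2) / sqrt(length(se2)),
       n_records = length(ae),
       per_system = per_sys)
}

#' Hyperparameter selection on the validation split
#'
#' Fits the model on the train split for every grid configuration and
#' returns the configuration minimizing validation MAE; ties are broken by
#' smaller `K`, then smaller `feature_scale`. Individual fit failures are
#' skipped with a message; an error is raised only if every configuration
#' fails.
#'
#' @param dataset a split [observation_dataset()].
#' @param geometries a [component_geometry()] table.
#' @param grid data frame with columns `K` and optionally `feature_scale`,
#'   `likelihood_scale` (missing columns take the `priors` defaults).
#' @param priors baseline [prior_spec()] whose fields the grid overrides.
#' @param seed integer RNG seed.
#' @param method `"map"` (default) or `"vi"`.
#' @param ... further arguments to [fit_map()] / [fit_vi()].
#' @return List with `best` (row of the grid), `best_fit`, and `results`
#'   (the grid with a `validation_MAE` column).
#' @export
select_hyperparameters <- function(dataset, geometries, grid, priors = prior_spec(),
                                   seed = 1L, method = c("map", "vi"), ...) {
  method <- match.arg(method)
  .assert(is.data.frame(grid) && nrow(grid) >= 1L && "K" %in% names(grid),
          "grid must be a data frame with a K column")
  .assert(!is.null(dataset$split) && any(dataset$split == "validation"),
          "dataset needs a nonempty validation split")
  if (is.null(grid$feature_scale)) grid$feature_scale <- priors$feature_scale
  if (is.null(grid$likelihood_scale)) grid$likelihood_scale <- priors$likelihood_scale
  grid$validation_MAE <- NA_real_
  fits <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pri <- prior_spec(feature_scale = grid$feature_scale[g],
                      like_energy_loc = priors$like_energy_loc,
                      like_energy_scale = priors$like_energy_scale,
                      likelihood_family = priors$likelihood_family,
                      likelihood_scale = grid$likelihood_scale[g])
    fit <- tryCatch(
      if (method == "map") fit_map(dataset, pri, geometries, grid$K[g], seed, ...)
      else fit_vi(dataset, pri, geometries, grid$K[g], seed, ...),
      error = function(e) {
        message(sprintf("grid point %d (K = %d) failed: %s", g, grid$K[g],
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) next
    fits[[g]] <- fit
    grid$validation_MAE[g] <- evaluate_fit(fit, dataset, "validation")$MAE
  }
  if (all(is.na(grid$validation_MAE))) stop("all grid points failed", call. = FALSE)
  ord <- order(grid$validation_MAE, grid$K, grid$feature_scale)
  best <- ord[1L]
  list(best = grid[best, , drop = FALSE],
       best_fit = fits[[best]],
       results = grid)
}
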