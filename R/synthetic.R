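#' Synthetic-data generator configuration
#'
#' Settings for generating a ground-truth component roster with latent
#' interaction structure and sparse, noisy activity-coefficient
#' observations that mimic the statistics of large experimental
#' thermophysical databases: thousands of possible binary systems of which
#' only a few percent are observed, several (T, x) points per observed
#' system, a mix of finite-composition and infinite-dilution records, and
#' temperatures spanning roughly 183-638 K.
#'
#' @param N_components roster size N (>= 2).
#' @param K_true latent dimension of the generating truth.
#' @param observed_system_fraction fraction of the N(N-1)/2 systems that
#'   carry data, in (0, 1].
#' @param records_per_system observations drawn per observed system.
#' @param infinite_dilution_fraction probability that a record is an
#'   infinite-dilution one, in \[0, 1\].
#' @param T_range temperature range (K, K).
#' @param x_range liquid-composition range for finite records, inside (0, 1).
#' @param noise_family `"gaussian"` or `"cauchy"` measurement noise on
#'   ln gamma.
#' @param noise_scale noise scale on ln gamma (0 = exact model values).
#' @param pair_sd_K target standard deviation of (U_ij - U_jj)/R across
#'   pairs, in K; calibrates the latent-feature scale.
#' @param like_mean_K,like_sd_K Gaussian parameters of U_ii/R, in K.
#' @param seed integer RNG seed (mandatory).
#' @return A `generator_config` object.
#' @export
generator_config <- function(N_components = 60L, K_true = 3L,
                             observed_system_fraction = 0.3,
                             records_per_system = 20L,
                             infinite_dilution_fraction = 0.2,
                             T_range = c(183, 638),
                             x_range = c(0.01, 0.99),
                             noise_family = c("gaussian", "cauchy"),
                             noise_scale = 0.1,
                             pair_sd_K = 300, like_mean_K = -300, like_sd_K = 150,
                             seed = 1L) {
  noise_family <- match.arg(noise_family)
  .assert(N_components >= 2L && K_true >= 1L, "need N >= 2 and K_true >= 1")
  .assert(observed_system_fraction > 0 && observed_system_fraction <= 1,
          "observed_system_fraction must be in (0, 1]")
  .assert(infinite_dilution_fraction >= 0 && infinite_dilution_fraction <= 1,
          "infinite_dilution_fraction must be in [0, 1]")
  .assert(T_range[1] < T_range[2] && T_range[1] > 0, "T_range must be ordered and positive")
  .assert(x_range[1] > 0 && x_range[2] < 1 && x_range[1] < x_range[2],
          "x_range must be an ordered interval inside (0, 1)")
  .assert(noise_scale >= 0, "noise_scale must be >= 0")
  .assert(pair_sd_K > like_sd_K,
          "pair_sd_K must exceed like_sd_K (the like-energy spread is part of the pair spread)")
  structure(list(N_components = as.integer(N_components), K_true = as.integer(K_true),
                 observed_system_fraction = observed_system_fraction,
                 records_per_system = as.integer(records_per_system),
                 infinite_dilution_fraction = infinite_dilution_fraction,
                 T_range = T_range, x_range = x_range,
                 noise_family = noise_family, noise_scale = noise_scale,
                 pair_sd_K = pair_sd_K, like_mean_K = like_mean_K,
                 like_sd_K = like_sd_K, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a ground-truth roster, geometries and interaction structure
#'
#' Draws component geometries r ~ U(1, 10), q = r U(0.75, 1.1); latent
#' features theta, beta with entries N(0, s), s calibrated so that the
#' spread of (U_ij - U_jj)/R across pairs matches `pair_sd_K` (300 K by
#' default, giving realistic infinite-dilution ln gamma magnitudes); and
#' like energies U_ii/R ~ N(like_mean_K, like_sd_K). Fully reproducible
#' from the config seed.
#'
#' @param config a [generator_config()].
#' @return A `synthetic_truth` object: `geometries`, `features`
#'   ([latent_features()], J/mol), `full_U` (the assembled
#'   [symmetric_interactions()] set), and `config`.
#' @export
generate_truth <- function(config) {
  .assert(inherits(config, "generator_config"), "config must be a generator_config")
  n <- config$N_components
  K <- config$K_true
  ids <- sprintf("C%04d", seq_len(n))
  # per-entry feature sd so that var(U_ij/R) = 2 K s^4 matches the target
  # pair spread after removing the like-energy contribution
  s_feat <- ((config$pair_sd_K^2 - config$like_sd_K^2) / (2 * K))^(1 / 4)
  out <- with_seed(config$seed, {
    r <- stats::runif(n, 1, 10)
    q <- r * stats::runif(n, 0.75, 1.1)
    theta <- matrix(stats::rnorm(n * K, 0, s_feat), n, K)
    beta <- matrix(stats::rnorm(n * K, 0, s_feat), n, K)
    ulike <- stats::rnorm(n, config$like_mean_K, config$like_sd_K)
    list(r = r, q = q, theta = theta, beta = beta, ulike = ulike)
  })
  # out$theta/beta/ulike are in Kelvin units; convert to interface J/mol
  feats <- .features_external(ids, out$theta, out$beta, out$ulike)
  geoms <- component_geometry(ids, out$r, out$q)
  structure(list(geometries = geoms, features = feats,
                 full_U = assemble_interactions(feats), config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n <- x$config$N_components
  cat(sprintf("Synthetic truth: N = %d components, K_true = %d, %d possible binary systems\n",
              n, x$config$K_true, choose(n, 2)))
  invisible(x)
}

#' Generate sparse noisy activity-coefficient observations
#'
#' Samples ceiling(fraction * N(N-1)/2) systems uniformly without
#' replacement; per system draws `records_per_system` records. With
#' probability `infinite_dilution_fraction` a record is an
#' infinite-dilution one (x_i = 0, ln gamma from the closed-form limit),
#' otherwise a finite-composition one with x_i ~ U(x_range). The measured
#' species is chosen uniformly from the pair; T ~ U(T_range); noise of the
#' configured family and scale is added to the exact model value.
#'
#' @param truth a `synthetic_truth` from [generate_truth()].
#' @param config a [generator_config()] (defaults to the truth's own).
#' @return A [observation_dataset()].
#' @export
generate_observations <- function(truth, config = truth$config) {
  .assert(inherits(truth, "synthetic_truth"), "truth must be a synthetic_truth")
  n <- length(truth$features$component_ids)
  ids <- truth$features$component_ids
  n_pairs <- choose(n, 2)
  n_sys <- ceiling(config$observed_system_fraction * n_pairs)
  .assert(n_sys >= 1L, "observed_system_fraction draws zero systems")
  pair_idx <- which(upper.tri(diag(n)), arr.ind = TRUE)

  ip <- .features_internal(truth$features)
  with_seed(config$seed + 1L, {
    chosen <- sample.int(n_pairs, n_sys)
    a <- pair_idx[chosen, 1L]; b <- pair_idx[chosen, 2L]
    m <- config$records_per_system
    N_rec <- n_sys * m
    sys_rec <- rep(seq_len(n_sys), each = m)
    # measured species: uniformly the first or second of the pair
    meas_first <- stats::runif(N_rec) < 0.5
    ia <- ifelse(meas_first, a[sys_rec], b[sys_rec])
    ib <- ifelse(meas_first, b[sys_rec], a[sys_rec])
    is_inf <- stats::runif(N_rec) < config$infinite_dilution_fraction
    x_i <- ifelse(is_inf, 0,
                  stats::runif(N_rec, config$x_range[1], config$x_range[2]))
    T_K <- stats::runif(N_rec, config$T_range[1], config$T_range[2])

    rqa <- list(r = truth$geometries$r[ia], q = truth$geometries$q[ia])
    rqb <- list(r = truth$geometries$r[ib], q = truth$geometries$q[ib])
    P <- tcrossprod(ip$theta, ip$beta)
    Usym <- P + t(P)
    lg <- .binary_lngamma_grad(rqa$r, rqa$q, rqb$r, rqb$q, x_i, T_K,
                               ip$ulike[ia], ip$ulike[ib],
                               Usym[cbind(ia, ib)], grad = FALSE)$value
    noise <- if (config$noise_scale == 0) 0
    else if (config$noise_family == "gaussian")
      stats::rnorm(N_rec, 0, config$noise_scale)
    else stats::rcauchy(N_rec, 0, config$noise_scale)
    observation_dataset(data.frame(
      id_i = ids[ia], id_j = ids[ib], T_K = T_K, x_i = x_i,
      ln_gamma = lg + noise,
      record_type = ifelse(is_inf, "infinite_dilution", "finite"),
      stringsAsFactors = FALSE))
  })
}

#' Generate a plausible Antoine table for a synthetic roster
#'
#' Draws A ~ U(5.8, 7.2), B ~ U(1200, 2400), C ~ U(-80, -30) per component
#' and keeps only draws whose normal boiling point (p_s = 101.325 kPa)
#' falls within 250-550 K, resampling otherwise (at most 1000 times per
#' component). The validity range is the boiling point +/- 120 K.
#'
#' @param truth a `synthetic_truth` (supplies the component ids).
#' @param seed integer RNG seed.
#' @return An [antoine_table()].
#' @export
generate_antoine <- function(truth, seed) {
  ids <- truth$features$component_ids
  with_seed(seed, {
    draw_one <- function(id) {
      for (k in seq_len(1000L)) {
        A <- stats::runif(1, 5.8, 7.2)
        B <- stats::runif(1, 1200, 2400)
        C <- stats::runif(1, -80, -30)
        Tb <- B / (A - log10(101.325)) - C
        if (Tb >= 250 && Tb <= 550) {
          return(c(A = A, B = B, C = C, T_min = Tb - 120, T_max = Tb + 120))
        }
      }
      stop("could not draw plausible Antoine coefficients after 1000 rejections",
           call. = FALSE)
    }
    mat <- t(vapply(ids, draw_one, numeric(5)))
    antoine_table(ids, mat[, "A"], mat[, "B"], mat[, "C"],
                  mat[, "T_min"], mat[, "T_max"])
  })
}

#' Write a complete small fixture directory
#'
#' Single entry point emitting every table dialect consumed by the other
#' modules: observations, component geometries, Antoine parameters, the
#' generating latent features, the full true interaction set, and a
#' flat key-value truth manifest.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly; files `observations.tsv`,
#'   `geometry.tsv`, `antoine.tsv`, `true_features.tsv`,
#'   `true_interactions.tsv`, `truth_manifest.txt`.
#' @export
make_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(config)
  obs <- generate_observations(truth)
  ant <- generate_antoine(truth, config$seed + 2L)
  write_observations(obs, file.path(dir, "observations.tsv"))
  write_geometry(truth$geometries, file.path(dir, "geometry.tsv"))
  write_antoine(ant, file.path(dir, "antoine.tsv"))
  write_features(truth$features, file.path(dir, "true_features.tsv"))
  write_interactions(truth$full_U, file.path(dir, "true_interactions.tsv"))
  n <- config$N_components
  manifest <- c(
    N_components = n,
    K_true = config$K_true,
    possible_binary_systems = format(choose(n, 2), scientific = FALSE),
    observed_systems = length(unique(obs$records$system_key)),
    n_records = nrow(obs$records),
    noise_family = config$noise_family,
    noise_scale = config$noise_scale,
    seed = config$seed)
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(dir, "truth_manifest.txt"))
  invisible(dir)
}
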