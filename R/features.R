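#' Latent component features
#'
#' Per-component latent feature vectors theta_i, beta_i (shared dimension K)
#' plus the like pair-interaction energies U_ii. Unlike pair energies are
#' reconstructed from the features as
#'
#'   U_ij = theta_i . beta_j + theta_j . beta_i      (i != j)
#'
#' which is symmetric under i <-> j by construction. Features are
#' unconstrained; only the reconstructed energies U are identifiable (the
#' parameterization carries a GL(K) gauge freedom: (theta M, beta (M^-1)^T)
#' reconstructs the same U for any invertible M).
#'
#' @param component_ids character vector, length N.
#' @param theta,beta N x K numeric matrices of latent features.
#' @param like_energies length-N numeric vector of U_ii, J/mol.
#' @return A `latent_features` object.
#' @export
latent_features <- function(component_ids, theta, beta, like_energies) {
  component_ids <- as.character(component_ids)
  n <- length(component_ids)
  .assert(!anyDuplicated(component_ids), "duplicate component ids")
  theta <- as.matrix(theta); beta <- as.matrix(beta)
  .assert(nrow(theta) == n && nrow(beta) == n, "theta/beta must have one row per component")
  .assert(ncol(theta) == ncol(beta) && ncol(theta) >= 1L,
          "theta and beta must share a latent dimension K >= 1")
  .assert(length(like_energies) == n, "like_energies must have one entry per component")
  .assert(all(is.finite(theta)) && all(is.finite(beta)) && all(is.finite(like_energies)),
          "all features and like energies must be finite")
  rownames(theta) <- rownames(beta) <- component_ids
  structure(list(component_ids = component_ids, theta = theta, beta = beta,
                 K = ncol(theta), like_energies = as.numeric(like_energies)),
            class = "latent_features")
}

#' @export
print.latent_features <- function(x, ...) {
  cat(sprintf("Latent features: N = %d components, K = %d\n",
              length(x$component_ids), x$K))
  invisible(x)
}

#' Predict one unlike pair-interaction energy from latent features
#'
#' @param features a [latent_features()] object.
#' @param id_i,id_j distinct component identifiers.
#' @return U_ij = theta_i . beta_j + theta_j . beta_i, in J/mol.
#' @export
predict_pair_energy <- function(features, id_i, id_j) {
  .assert(inherits(features, "latent_features"), "features must be latent_features")
  if (identical(as.character(id_i), as.character(id_j))) {
    stop("i = j: like energies are parameters, see features$like_energies",
         call. = FALSE)
  }
  idx <- .match_ids(c(id_i, id_j), features$component_ids)
  sum(features$theta[idx[1], ] * features$beta[idx[2], ]) +
    sum(features$theta[idx[2], ] * features$beta[idx[1], ])
}

#' Assemble a complete symmetric interaction set from latent features
#'
#' Builds the full pair-energy matrix for a component subset: diagonal from
#' the like energies, off-diagonal from the latent-feature reconstruction.
#' This is the matrix-completion promise: it succeeds for every pair of
#' known components, including pairs never observed together.
#'
#' @param features a [latent_features()] object.
#' @param subset component ids to include (default: the full roster).
#' @return A [symmetric_interactions()] set.
#' @export
assemble_interactions <- function(features, subset = features$component_ids) {
  subset <- as.character(subset)
  .assert(length(subset) >= 2L, "need at least 2 components")
  idx <- .match_ids(subset, features$component_ids)
  th <- features$theta[idx, , drop = FALSE]
  be <- features$beta[idx, , drop = FALSE]
  P <- tcrossprod(th, be)
  U <- P + t(P)
  diag(U) <- features$like_energies[idx]
  U <- (U + t(U)) / 2  # enforce bitwise symmetry against rounding asymmetry
  symmetric_interactions(subset, U)
}

#' Parameter counts of the two UNIQUAC parameterizations
#'
#' Number of fitted interaction parameters when modeling a set of observed
#' binary systems: the conventional asymmetric parameterization uses two dU
#' parameters per system (2 S); the symmetric one uses one U_ij per system
#' plus one like energy per component (S + N).
#'
#' @param N_components number of components, >= 0.
#' @param N_observed_systems number of observed binary systems, >= 0.
#' @param mode `"symmetric"` or `"asymmetric"`.
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(1146, 12199, "asymmetric")  # 24398
#' count_parameters(1146, 12199, "symmetric")   # 13345
count_parameters <- function(N_components, N_observed_systems,
                             mode = c("symmetric", "asymmetric")) {
  mode <- match.arg(mode)
  .assert(N_components >= 0 && N_observed_systems >= 0, "counts must be >= 0")
  if (mode == "asymmetric") 2L * as.integer(N_observed_systems)
  else as.integer(N_observed_systems) + as.integer(N_components)
}

#' Read or write a latent feature store
#'
#' Tab-delimited text, one row per component with columns `component_id`,
#' `U_ii` (J/mol), `theta_1..theta_K`, `beta_1..beta_K`; K is inferred from
#' the header on read.
#'
#' @param features a [latent_features()] object (for writing).
#' @param path file path.
#' @return `read_features` returns a `latent_features` object;
#'   `write_features` returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  K <- features$K
  d <- data.frame(component_id = features$component_ids,
                  U_ii = features$like_energies, stringsAsFactors = FALSE)
  th <- features$theta; colnames(th) <- paste0("theta_", seq_len(K))
  be <- features$beta; colnames(be) <- paste0("beta_", seq_len(K))
  utils::write.table(cbind(d, th, be), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  th_cols <- grep("^theta_[0-9]+$", names(d), value = TRUE)
  be_cols <- grep("^beta_[0-9]+$", names(d), value = TRUE)
  .assert(length(th_cols) >= 1L && length(th_cols) == length(be_cols),
          "feature store needs matching theta_k / beta_k columns")
  th_cols <- th_cols[order(as.integer(sub("theta_", "", th_cols)))]
  be_cols <- be_cols[order(as.integer(sub("beta_", "", be_cols)))]
  latent_features(d$component_id,
                  as.matrix(d[, th_cols, drop = FALSE]),
                  as.matrix(d[, be_cols, drop = FALSE]),
                  d$U_ii)
}

#' Export a pair-energy table
#'
#' Writes predicted unlike pair energies for the requested pairs (default:
#' all pairs of the roster) as tab-delimited text with columns `id_i`,
#' `id_j`, `U_mean`, `U_sd`. For a point-estimate fit the `U_sd` column is
#' blank; for a variational fit it holds the posterior standard deviation
#' obtained by sampling the variational posterior.
#'
#' @param fit a [latent_features()] object or an `mcm_fit` (see [fit_map()],
#'   [fit_vi()]).
#' @param path output path.
#' @param pairs optional 2-column character matrix/data.frame of pairs.
#' @param n_draws posterior draws for the sd column (variational fits).
#' @return `path`, invisibly.
#' @export
write_pair_energies <- function(fit, path, pairs = NULL, n_draws = 1000L) {
  feats <- if (inherits(fit, "mcm_fit")) fit$features else fit
  .assert(inherits(feats, "latent_features"), "fit must carry latent features")
  ids <- feats$component_ids
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
    pairs <- cbind(ids[idx[, 1L]], ids[idx[, 2L]])
  } else {
    pairs <- as.matrix(pairs)
  }
  mean_sd <- pair_energy_summary(fit, pairs[, 1L], pairs[, 2L], n_draws = n_draws)
  d <- data.frame(id_i = pairs[, 1L], id_j = pairs[, 2L],
                  U_mean = mean_sd$mean, U_sd = mean_sd$sd,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
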