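#' Symmetric pair-interaction energy set
#'
#' Container for the lattice-model pair-interaction energies of a component
#' roster: like energies U_ii on the diagonal and unlike energies U_ij = U_ji
#' off it, all in J/mol. Physical symmetry U_ij = U_ji is an invariant of the
#' type: the constructor rejects any matrix that is not exactly symmetric.
#'
#' @param component_ids character vector naming rows/columns of `U`.
#' @param U square numeric matrix of energies (J/mol), exactly symmetric.
#' @return A `symmetric_interactions` object.
#' @export
symmetric_interactions <- function(component_ids, U) {
  component_ids <- as.character(component_ids)
  n <- length(component_ids)
  .assert(!anyDuplicated(component_ids), "duplicate component ids")
  .assert(is.matrix(U) && nrow(U) == n && ncol(U) == n,
          "U must be a square matrix matching component_ids")
  .assert(all(is.finite(U)), "all energies must be finite")
  .assert(identical(U, t(U)), "U must be exactly symmetric (U_ij = U_ji)")
  dimnames(U) <- list(component_ids, component_ids)
  structure(list(component_ids = component_ids, U = U),
            class = "symmetric_interactions")
}

#' Asymmetric interaction-parameter set (conventional UNIQUAC)
#'
#' Container for the conventional UNIQUAC parameterization, which fits two
#' independent parameters per unordered pair: dU_ij = U_ij - U_jj and
#' dU_ji = U_ij - U_ii (J/mol). No symmetry is required; the diagonal is 0
#' by definition.
#'
#' @param component_ids character vector naming rows/columns of `delta`.
#' @param delta square numeric matrix with `delta[i, j]` = dU_ij (J/mol) and
#'   zero diagonal.
#' @return An `asymmetric_interactions` object.
#' @export
asymmetric_interactions <- function(component_ids, delta) {
  component_ids <- as.character(component_ids)
  n <- length(component_ids)
  .assert(!anyDuplicated(component_ids), "duplicate component ids")
  .assert(is.matrix(delta) && nrow(delta) == n && ncol(delta) == n,
          "delta must be a square matrix matching component_ids")
  .assert(all(is.finite(delta)), "all entries must be finite")
  .assert(all(diag(delta) == 0), "diagonal of delta must be zero")
  dimnames(delta) <- list(component_ids, component_ids)
  structure(list(component_ids = component_ids, delta = delta),
            class = "asymmetric_interactions")
}

#' @export
print.symmetric_interactions <- function(x, ...) {
  cat(sprintf("Symmetric pair-interaction set: %d components, %d unlike pairs (J/mol)\n",
              length(x$component_ids), choose(length(x$component_ids), 2)))
  invisible(x)
}

#' @export
print.asymmetric_interactions <- function(x, ...) {
  cat(sprintf("Asymmetric dU parameter set: %d components (J/mol)\n",
              length(x$component_ids)))
  invisible(x)
}

# matrix of energy differences D[i, j] = U_ij - U_jj (or stored dU), J/mol,
# restricted and ordered to `ids`
.delta_matrix <- function(interactions, ids) {
  idx <- .match_ids(ids, interactions$component_ids, "interaction")
  if (inherits(interactions, "symmetric_interactions")) {
    U <- interactions$U[idx, idx, drop = FALSE]
    sweep(U, 2L, diag(U), "-")
  } else if (inherits(interactions, "asymmetric_interactions")) {
    interactions$delta[idx, idx, drop = FALSE]
  } else {
    stop("interactions must be a symmetric_interactions or asymmetric_interactions object",
         call. = FALSE)
  }
}

#' Boltzmann factor matrix tau
#'
#' Evaluates the UNIQUAC Boltzmann factors tau_ij = exp(-(U_ij - U_jj)/(R T))
#' (equivalently exp(-dU_ij/(R T)) under the conventional asymmetric
#' parameterization). The diagonal is exactly 1. Exponents are clipped at
#' +/- 500 with a warning (see [tau_clip_count()]).
#'
#' @param interactions a [symmetric_interactions()] or
#'   [asymmetric_interactions()] set.
#' @param T temperature in K, > 0.
#' @param component_ids optional subset/ordering of components; defaults to
#'   the set's full roster.
#' @return Square matrix tau with positive entries and unit diagonal.
#' @export
tau_matrix <- function(interactions, T, component_ids = NULL) {
  .assert(is.numeric(T) && length(T) == 1L && is.finite(T) && T > 0,
          "T must be a single finite temperature > 0 (K)")
  ids <- if (is.null(component_ids)) interactions$component_ids else as.character(component_ids)
  D <- .delta_matrix(interactions, ids)
  tau <- exp(.clip_exponent(-D / (.R_GAS * T), warn = TRUE))
  diag(tau) <- 1
  dimnames(tau) <- list(ids, ids)
  tau
}

#' Convert symmetric energies to conventional dU parameters
#'
#' For every ordered pair (i, j) computes dU_ij = U_ij - U_jj. The two
#' parameters per unordered pair obey the identity
#' dU_ij - dU_ji = U_ii - U_jj exactly; independently fitted dU tables
#' generally violate it (see [check_delta_consistency()]).
#'
#' @param interactions a [symmetric_interactions()] set.
#' @return An [asymmetric_interactions()] set.
#' @export
delta_from_symmetric <- function(interactions) {
  .assert(inherits(interactions, "symmetric_interactions"),
          "interactions must be a symmetric_interactions object")
  D <- sweep(interactions$U, 2L, diag(interactions$U), "-")
  diag(D) <- 0
  asymmetric_interactions(interactions$component_ids, D)
}

#' Can a dU table be explained by symmetric pair energies?
#'
#' Tests whether an asymmetric dU parameter set is the image of some
#' symmetric energy set, i.e. whether values {U_ii, U_ij} exist with
#' dU_ij = U_ij - U_jj and dU_ji = U_ij - U_ii for every pair. The
#' overdetermined linear system is solved in least squares (the global
#' additive gauge is fixed by zeroing aliased coefficients); the set is
#' consistent iff the maximum absolute equation residual is below `tol`.
#' With fewer than 3 components (or missing pairs) the system is
#' underdetermined and reported as trivially consistent.
#'
#' @param asym an [asymmetric_interactions()] set.
#' @param tol residual tolerance in J/mol (default 1e-6).
#' @return A list with `consistent` (logical), `best_fit_U` (a
#'   [symmetric_interactions()] least-squares reconstruction), `residuals`
#'   (named numeric vector, one per equation), `max_abs_residual`, and
#'   `note`.
#' @export
check_delta_consistency <- function(asym, tol = 1e-6) {
  .assert(inherits(asym, "asymmetric_interactions"),
          "asym must be an asymmetric_interactions object")
  ids <- asym$component_ids
  n <- length(ids)
  pairs <- which(upper.tri(asym$delta), arr.ind = TRUE)
  p <- nrow(pairs)
  underdetermined <- n < 3L || p < choose(n, 2)

  # unknowns: U_11..U_nn then one U_ij per unordered pair
  n_unknown <- n + p
  A <- matrix(0, 2L * p, n_unknown)
  y <- numeric(2L * p)
  eq_names <- character(2L * p)
  for (k in seq_len(p)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    # dU_ij = U_ij - U_jj
    A[2L * k - 1L, n + k] <- 1; A[2L * k - 1L, j] <- -1
    y[2L * k - 1L] <- asym$delta[i, j]
    eq_names[2L * k - 1L] <- sprintf("dU[%s,%s]", ids[i], ids[j])
    # dU_ji = U_ij - U_ii
    A[2L * k, n + k] <- 1; A[2L * k, i] <- -1
    y[2L * k] <- asym$delta[j, i]
    eq_names[2L * k] <- sprintf("dU[%s,%s]", ids[j], ids[i])
  }
  fit <- stats::lm.fit(A, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # fix the additive gauge of the rank-1 null space
  resid <- y - as.vector(A %*% coefs)
  names(resid) <- eq_names

  U <- diag(coefs[seq_len(n)], n)
  for (k in seq_len(p)) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    U[i, j] <- U[j, i] <- coefs[n + k]
  }
  max_r <- if (length(resid)) max(abs(resid)) else 0
  consistent <- underdetermined || max_r < tol
  list(consistent = consistent,
       best_fit_U = symmetric_interactions(ids, U),
       residuals = resid,
       max_abs_residual = max_r,
       note = if (underdetermined)
         "underdetermined (fewer than 3 components or missing pairs): trivially consistent"
       else NA_character_)
}

#' Read or write a symmetric interaction table
#'
#' Tab-delimited text with columns `id_i`, `id_j`, `U_ij` (J/mol), one row
#' per pair with i <= j, including the diagonal (like energies). On read the
#' full symmetric set is reconstructed; conflicting duplicate rows are an
#' error, missing pairs are an error.
#'
#' @param path file path.
#' @param interactions a [symmetric_interactions()] set (for writing).
#' @return `read_interactions` returns a `symmetric_interactions` set;
#'   `write_interactions` returns `path` invisibly.
#' @export
write_interactions <- function(interactions, path) {
  ids <- interactions$component_ids
  n <- length(ids)
  keep <- which(upper.tri(interactions$U, diag = TRUE), arr.ind = TRUE)
  d <- data.frame(id_i = ids[keep[, 1L]], id_j = ids[keep[, 2L]],
                  U_ij = interactions$U[keep], stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .assert(all(c("id_i", "id_j", "U_ij") %in% names(d)),
          "interaction table needs columns id_i, id_j, U_ij")
  key <- system_key(d$id_i, d$id_j)
  key[d$id_i == d$id_j] <- paste0(d$id_i[d$id_i == d$id_j], "|diag")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    vals <- split(d$U_ij, key)
    bad <- vapply(vals[dup], function(v) max(v) - min(v) > 0, logical(1))
    if (any(bad)) stop("conflicting duplicate interaction rows", call. = FALSE)
    d <- d[!duplicated(key), ]
  }
  ids <- sort(unique(c(d$id_i, d$id_j)))
  n <- length(ids)
  U <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ii <- match(d$id_i, ids); jj <- match(d$id_j, ids)
  U[cbind(ii, jj)] <- d$U_ij
  U[cbind(jj, ii)] <- d$U_ij
  .assert(!anyNA(U), "interaction table is missing pairs or diagonal entries")
  symmetric_interactions(ids, U)
}
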