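#' Model constants
#'
#' Fixed physical constants of the lattice model: the molar gas constant
#' `R` (J/(mol K)) and the lattice coordination number `z`. Both are fixed
#' package-wide; `z = 10` is the canonical UNIQUAC choice and is not a user
#' knob. All interaction energies in exported interfaces are in J/mol.
#'
#' @return A list with elements `R` (8.314462618 J/(mol K)) and `z` (10).
#' @export
#' @examples
#' uniquac_constants()
uniquac_constants <- function() {
  list(R = 8.314462618, z = 10)
}

.R_GAS <- 8.314462618
.Z_COORD <- 10

# clip bound for tau exponents; guards exp() overflow during optimizer excursions
.TAU_EXP_CLIP <- 500

# package-internal mutable state: tau clipping event counter
.mcm_state <- new.env(parent = emptyenv())
.mcm_state$tau_clip_count <- 0L

#' Count of tau-exponent clipping events
#'
#' The Boltzmann factors tau_ij = exp(-(U_ij - U_jj)/(R T)) are computed with
#' the exponent clipped to +/- 500 so that extreme parameter values met during
#' optimization cannot overflow. Every clipped entry increments a
#' package-level counter; this pair of helpers reads and resets it, and the
#' command-line pipeline reports it in run logs.
#'
#' @return `tau_clip_count()` returns the integer number of clipped entries
#'   since the last reset; `reset_tau_clip_count()` resets it (invisibly).
#' @export
tau_clip_count <- function() .mcm_state$tau_clip_count

#' @rdname tau_clip_count
#' @export
reset_tau_clip_count <- function() {
  .mcm_state$tau_clip_count <- 0L
  invisible(NULL)
}

# clip exponents, count events; `warn` controls user-facing notification
.clip_exponent <- function(e, warn = FALSE) {
  n_clip <- sum(e > .TAU_EXP_CLIP | e < -.TAU_EXP_CLIP)
  if (n_clip > 0L) {
    .mcm_state$tau_clip_count <- .mcm_state$tau_clip_count + as.integer(n_clip)
    if (warn) {
      warning(sprintf("tau exponent clipped at +/-%d for %d entr%s",
                      .TAU_EXP_CLIP, n_clip, if (n_clip == 1L) "y" else "ies"),
              call. = FALSE)
    }
  }
  pmin(pmax(e, -.TAU_EXP_CLIP), .TAU_EXP_CLIP)
}
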