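# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package take a mandatory seed and go through this helper, so nothing
# perturbs (or depends on) global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Canonical unordered label for a binary system, e.g. "C002|C017".
system_key <- function(id_i, id_j) {
  ifelse(as.character(id_i) < as.character(id_j),
         paste(id_i, id_j, sep = "|"),
         paste(id_j, id_i, sep = "|"))
}

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

# index positions of `ids` inside `roster`, erroring on unknowns
.match_ids <- function(ids, roster, what = "component") {
  idx <- match(as.character(ids), as.character(roster))
  if (anyNA(idx)) {
    stop(sprintf("unknown %s id(s): %s (trained roster has %d components)",
                 what, paste(unique(ids[is.na(idx)]), collapse = ", "),
                 length(roster)),
         call. = FALSE)
  }
  idx
}
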