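#' Activity-coefficient observation dataset
#'
#' A collection of ln gamma measurements in binary systems. Each record
#' holds the measured species `id_i`, its partner `id_j`, temperature `T_K`,
#' liquid mole fraction `x_i` of the measured species, the observed
#' `ln_gamma`, and a `record_type`: `"finite"` for a finite-composition
#' point (x_i in (0, 1)) or `"infinite_dilution"` for a ln gamma-infinity
#' record, which carries `x_i = 0` by convention. Records are grouped into
#' binary systems by the canonical unordered pair label `system_key`;
#' train/validation/test splitting is always by system, never by record,
#' so held-out systems are truly unseen.
#'
#' @param records data frame with columns `id_i`, `id_j`, `T_K`, `x_i`,
#'   `ln_gamma`, `record_type`.
#' @param split optional named character vector mapping every `system_key`
#'   to `"train"`, `"validation"` or `"test"`.
#' @return A `gamma_dataset` object (list with `records`, `split`).
#' @export
observation_dataset <- function(records, split = NULL) {
  req <- c("id_i", "id_j", "T_K", "x_i", "ln_gamma", "record_type")
  .assert(all(req %in% names(records)), paste("records need columns:", paste(req, collapse = ", ")))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$id_i <- as.character(records$id_i)
  records$id_j <- as.character(records$id_j)
  .assert(all(records$id_i != records$id_j), "records must reference two distinct components")
  .assert(all(is.finite(records$T_K)) && all(records$T_K > 0), "all T_K must be > 0")
  .assert(all(is.finite(records$ln_gamma)), "all ln_gamma must be finite")
  .assert(all(records$record_type %in% c("finite", "infinite_dilution")),
          "record_type must be 'finite' or 'infinite_dilution'")
  .assert(all(records$x_i >= 0 & records$x_i < 1), "x_i must lie in [0, 1)")
  .assert(all((records$record_type == "infinite_dilution") == (records$x_i == 0)),
          "record_type is 'infinite_dilution' iff x_i = 0")
  records$system_key <- system_key(records$id_i, records$id_j)
  if (!is.null(split)) {
    keys <- unique(records$system_key)
    .assert(all(keys %in% names(split)), "every system_key needs a split label")
    .assert(all(split %in% c("train", "validation", "test")),
            "split labels must be train/validation/test")
  }
  structure(list(records = records, split = split), class = "gamma_dataset")
}

#' @export
print.gamma_dataset <- function(x, ...) {
  n_sys <- length(unique(x$records$system_key))
  cat(sprintf("Activity-coefficient dataset: %d records, %d systems, %d components\n",
              nrow(x$records), n_sys,
              length(unique(c(x$records$id_i, x$records$id_j)))))
  if (!is.null(x$split)) {
    tab <- table(x$split[unique(x$records$system_key)])
    cat("  split (systems):", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a dataset by binary system
#'
#' Randomly partitions the observed systems (component pairs) into train,
#' validation and test sets; every record inherits the label of its system.
#' Partition sizes are floor(f_k * S); leftover systems are assigned in
#' order train, validation, test. Deterministic given `seed`.
#'
#' @param dataset a [observation_dataset()].
#' @param fractions length-3 numeric summing to 1 (train, validation, test).
#' @param seed integer RNG seed (mandatory).
#' @return The dataset with its `split` field populated.
#' @export
split_by_system <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed) {
  .assert(inherits(dataset, "gamma_dataset"), "dataset must be a gamma_dataset")
  .assert(length(fractions) == 3L && abs(sum(fractions) - 1) < 1e-9,
          "fractions must be length 3 and sum to 1")
  keys <- sort(unique(dataset$records$system_key))
  S <- length(keys)
  .assert(S >= sum(fractions > 0) && S >= 3L, "need at least 3 systems to split")
  sizes <- floor(fractions * S)
  rem <- S - sum(sizes)
  k <- 1L
  while (rem > 0L) {           # remainder goes train-first
    sizes[k] <- sizes[k] + 1L
    k <- if (k == 3L) 1L else k + 1L
    rem <- rem - 1L
  }
  perm <- with_seed(seed, sample.int(S))
  lab <- rep(c("train", "validation", "test"), times = sizes)
  split <- stats::setNames(lab, keys[perm])
  dataset$split <- split[keys]          # stable key order
  names(dataset$split) <- keys
  dataset
}

# records of one split (or all, if split_name is NULL)
.split_records <- function(dataset, split_name = NULL) {
  if (is.null(split_name)) return(dataset$records)
  .assert(!is.null(dataset$split), "dataset has no split labels; run split_by_system()")
  dataset$records[dataset$split[dataset$records$system_key] == split_name, , drop = FALSE]
}

#' Read or write an observation table
#'
#' Tab-delimited text with columns `id_i`, `id_j`, `T_K`, `x_i`, `ln_gamma`,
#' `record_type`; infinite-dilution rows carry `x_i = 0`.
#'
#' @param path file path.
#' @param dataset a [observation_dataset()] (for writing).
#' @return `read_observations` returns a `gamma_dataset` (without split
#'   labels); `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  observation_dataset(d)
}

#' @rdname read_observations
#' @export
write_observations <- function(dataset, path) {
  cols <- c("id_i", "id_j", "T_K", "x_i", "ln_gamma", "record_type")
  utils::write.table(dataset$records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
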