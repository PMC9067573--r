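#' Pure-component UNIQUAC geometry table
#'
#' Constructs the table of van der Waals geometric pure-component parameters:
#' the relative molecular volume `r` and surface area `q` of each component.
#' These enter the combinatorial (size/shape) part of the UNIQUAC activity
#' coefficient and are tabulated pure-component properties, not fitted here.
#'
#' @param component_id character vector of unique component identifiers.
#' @param r numeric vector of volume parameters, dimensionless, > 0.
#' @param q numeric vector of surface parameters, dimensionless, > 0.
#' @param name optional display names (defaults to the ids).
#' @return A `component_geometry` data frame with columns `component_id`,
#'   `name`, `r`, `q`.
#' @export
#' @examples
#' component_geometry(c("water", "ethanol"), r = c(0.92, 2.11), q = c(1.40, 1.97))
component_geometry <- function(component_id, r, q, name = component_id) {
  component_id <- as.character(component_id)
  .assert(!anyDuplicated(component_id), "duplicate component ids")
  .assert(length(r) == length(component_id) && length(q) == length(component_id),
          "component_id, r and q must have equal length")
  .assert(all(is.finite(r)) && all(r > 0), "all r must be finite and > 0")
  .assert(all(is.finite(q)) && all(q > 0), "all q must be finite and > 0")
  out <- data.frame(component_id = component_id, name = as.character(name),
                    r = as.numeric(r), q = as.numeric(q),
                    stringsAsFactors = FALSE)
  class(out) <- c("component_geometry", "data.frame")
  out
}

# r and q vectors for `ids`, in order, from a geometry table
.geom_rq <- function(geometries, ids) {
  idx <- .match_ids(ids, geometries$component_id)
  list(r = geometries$r[idx], q = geometries$q[idx])
}

#' Read or write a component geometry table
#'
#' Tab-delimited UTF-8 text with a header row and columns `component_id`,
#' `name`, `r`, `q`.
#'
#' @param path file path.
#' @param geometries a [component_geometry()] table (for writing).
#' @return `read_geometry` returns a `component_geometry` table;
#'   `write_geometry` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .assert(all(c("component_id", "r", "q") %in% names(d)),
          "geometry table needs columns component_id, r, q")
  if (is.null(d$name)) d$name <- d$component_id
  component_geometry(d$component_id, d$r, d$q, name = d$name)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometries, path) {
  utils::write.table(as.data.frame(geometries)[, c("component_id", "name", "r", "q")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
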