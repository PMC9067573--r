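#' Antoine vapor-pressure parameter table
#'
#' Antoine coefficients in the log10 / kPa / K dialect:
#' log10(p_s / kPa) = A - B / ((T / K) + C), valid on \[T_min, T_max\].
#' Converters for other dialects (e.g. mmHg / Celsius) are deliberately not
#' provided; the table file header declares the dialect.
#'
#' @param component_id character vector of component ids.
#' @param A,B,C Antoine coefficients (numeric vectors).
#' @param T_min,T_max validity range, K, with T_min < T_max.
#' @return An `antoine_table` data frame.
#' @export
antoine_table <- function(component_id, A, B, C, T_min, T_max) {
  component_id <- as.character(component_id)
  .assert(!anyDuplicated(component_id), "duplicate component ids")
  .assert(all(T_min < T_max), "T_min must be < T_max")
  out <- data.frame(component_id = component_id, A = A, B = B, C = C,
                    T_min_K = T_min, T_max_K = T_max, stringsAsFactors = FALSE)
  class(out) <- c("antoine_table", "data.frame")
  out
}

.antoine_row <- function(antoine, id) {
  idx <- .match_ids(id, antoine$component_id, "Antoine")
  antoine[idx, , drop = FALSE]
}

#' Saturation vapor pressure from Antoine coefficients
#'
#' p_s = 10^(A - B / (T + C)) in kPa. Temperatures outside the tabulated
#' validity range are allowed but trigger a warning (extrapolation).
#'
#' @param antoine an [antoine_table()] (one or more rows).
#' @param id component id (a single one, or a vector matching `T`).
#' @param T temperature(s), K.
#' @return Vapor pressure(s), kPa.
#' @export
vapor_pressure <- function(antoine, id, T) {
  row <- .antoine_row(antoine, id)
  .assert(all(T + row$C > 0), "T + C must be > 0 for the Antoine form")
  out_of_range <- T < row$T_min_K | T > row$T_max_K
  if (any(out_of_range)) {
    warning(sprintf("Antoine extrapolation outside validity range for %s",
                    paste(unique(row$component_id[out_of_range]), collapse = ", ")),
            call. = FALSE)
  }
  10^(row$A - row$B / (T + row$C))
}

# boiling temperature of one component at pressure P (kPa): closed-form
# inversion of the (monotone) Antoine equation
.antoine_invert <- function(antoine, id, P) {
  row <- .antoine_row(antoine, id)
  row$B / (row$A - log10(P)) - row$C
}

# deterministic safeguarded root solve on [lo, hi]: coarse bracket scan,
# bisection to `tol` K, one secant polish
.solve_T <- function(f, lo = 150, hi = 700, tol = 1e-8, n_scan = 60L) {
  Ts <- seq(lo, hi, length.out = n_scan)
  fs <- vapply(Ts, f, numeric(1))
  ok <- which(is.finite(fs))
  .assert(length(ok) >= 2L, "root function not finite on the temperature bracket")
  sgn <- sign(fs[ok])
  ch <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  .assert(length(ch) >= 1L,
          sprintf("no bracket for the equilibrium temperature in [%g, %g] K", lo, hi))
  a <- Ts[ok[ch[1L]]]; b <- Ts[ok[ch[1L] + 1L]]
  fa <- fs[ok[ch[1L]]]; fb <- fs[ok[ch[1L] + 1L]]
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- f(m)
    if (!is.finite(fm)) {
      stop(sprintf("equilibrium function failed during bisection at T = %.3f K", m),
           call. = FALSE)
    }
    if (fm == 0) return(m)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
  }
  # one secant polish
  if (fb != fa) {
    Tsec <- b - fb * (b - a) / (fb - fa)
    if (is.finite(Tsec) && Tsec > lo && Tsec < hi) return(Tsec)
  }
  (a + b) / 2
}

# gamma provider: accepts latent_features, mcm_fit, or an interaction set,
# and returns list(interactions, geometries-resolved) restricted to ids
.resolve_model <- function(model, ids) {
  if (inherits(model, "mcm_fit")) {
    assemble_interactions(model$features, ids)
  } else if (inherits(model, "latent_features")) {
    assemble_interactions(model, ids)
  } else if (inherits(model, "symmetric_interactions") ||
             inherits(model, "asymmetric_interactions")) {
    model
  } else {
    stop("model must be an mcm_fit, latent_features, or interaction set", call. = FALSE)
  }
}

# activity coefficients at (ids, x, T); handles components with x = 0 by
# evaluating on the active sub-mixture (their gamma is not needed)
.gamma_vec <- function(geometries, interactions, ids, x, T) {
  act <- which(x > 0)
  g <- rep(NA_real_, length(ids))
  if (length(act) == 1L) {
    g[act] <- 0
  } else {
    g[act] <- ln_gamma(geometries, interactions,
                       mixture_state(ids[act], x[act] / sum(x[act]), T))
  }
  exp(g)
}

#' Bubble-point temperature and vapor composition
#'
#' Solves the extended Raoult's law sum_i x_i gamma_i(T, x) p_i^s(T) = P
#' for T at fixed liquid composition x and pressure P (ideal vapor phase;
#' all liquid non-ideality in gamma), then returns the equilibrium vapor
#' composition y_i = x_i gamma_i p_i^s / P. Components with x_i = 0 are
#' dropped from the liquid; a pure liquid reduces to Antoine inversion.
#' Root solving is a deterministic bracket scan on \[T_lo, T_hi\] followed
#' by bisection to 1e-8 K and one secant polish.
#'
#' @param P pressure, kPa.
#' @param x liquid mole fractions (simplex; zeros allowed).
#' @param component_ids component ids matching `x`.
#' @param geometries a [component_geometry()] table.
#' @param model an `mcm_fit`, [latent_features()], or interaction set.
#' @param antoine an [antoine_table()].
#' @param T_lo,T_hi search bracket, K.
#' @return List with `T` (K), `y` (vapor mole fractions, named), `P`.
#' @export
bubble_point_T <- function(P, x, component_ids, geometries, model, antoine,
                           T_lo = 150, T_hi = 700) {
  .assert(P > 0, "P must be > 0")
  .assert(abs(sum(x) - 1) < 1e-10 && all(x >= 0), "x must lie on the simplex")
  ids <- as.character(component_ids)
  act <- which(x > 0)
  if (length(act) == 1L) {
    T_b <- .antoine_invert(antoine, ids[act], P)
    y <- numeric(length(ids)); y[act] <- 1
    names(y) <- ids
    return(list(T = T_b, y = y, P = P))
  }
  interactions <- .resolve_model(model, ids[act])
  f <- function(T) {
    gam <- .gamma_vec(geometries, interactions, ids, x, T)
    ps <- vapply(act, function(k)
      suppressWarnings(vapor_pressure(antoine, ids[k], T)), numeric(1))
    sum(x[act] * gam[act] * ps) - P
  }
  T_b <- .solve_T(f, T_lo, T_hi)
  gam <- .gamma_vec(geometries, interactions, ids, x, T_b)
  ps <- vapply(act, function(k)
    suppressWarnings(vapor_pressure(antoine, ids[k], T_b)), numeric(1))
  y <- numeric(length(ids))
  y[act] <- x[act] * gam[act] * ps / P
  y <- y / sum(y)   # residual root tolerance; sum is 1 within 1e-8 already
  names(y) <- ids
  list(T = T_b, y = y, P = P)
}

#' Dew-point temperature and liquid composition
#'
#' Solves sum_i y_i P / (gamma_i(T, x) p_i^s(T)) = 1 jointly with
#' x_i = y_i P / (gamma_i p_i^s), by a fixed-point iteration on x nested in
#' the temperature root solve. Pure vapor reduces to Antoine inversion.
#'
#' @inheritParams bubble_point_T
#' @param y vapor mole fractions (simplex).
#' @param max_inner maximum fixed-point cycles per temperature.
#' @return List with `T` (K), `x` (liquid mole fractions, named), `P`.
#' @export
dew_point_T <- function(P, y, component_ids, geometries, model, antoine,
                        T_lo = 150, T_hi = 700, max_inner = 500L) {
  .assert(P > 0, "P must be > 0")
  .assert(abs(sum(y) - 1) < 1e-10 && all(y >= 0), "y must lie on the simplex")
  ids <- as.character(component_ids)
  act <- which(y > 0)
  if (length(act) == 1L) {
    T_d <- .antoine_invert(antoine, ids[act], P)
    x <- numeric(length(ids)); x[act] <- 1
    names(x) <- ids
    return(list(T = T_d, x = x, P = P))
  }
  interactions <- .resolve_model(model, ids[act])
  inner <- function(T, strict = TRUE) {
    ps <- vapply(act, function(k)
      suppressWarnings(vapor_pressure(antoine, ids[k], T)), numeric(1))
    # Wegstein-accelerated successive substitution on the liquid composition
    step <- function(x) {
      gam <- .gamma_vec(geometries, interactions, ids, x, T)
      raw <- y[act] * P / (gam[act] * ps)
      x_new <- numeric(length(ids))
      x_new[act] <- raw / sum(raw)
      list(x = x_new, sum_raw = sum(raw))
    }
    x <- y
    st <- step(x)
    x_prev <- x; f_prev <- st$x
    x <- st$x
    for (it in seq_len(max_inner)) {
      st <- step(x)
      fx <- st$x
      if (max(abs(fx - x)) < 1e-12) {
        return(list(x = fx, sum_raw = st$sum_raw, converged = TRUE))
      }
      dx <- x - x_prev
      s <- ifelse(abs(dx) > 1e-300, (fx - f_prev) / dx, 0)
      q <- pmin(pmax(s / (s - 1), -5), 0.5)   # Wegstein weights, bounded
      x_prev <- x; f_prev <- fx
      x_acc <- q * x + (1 - q) * fx
      x_acc[act] <- pmax(x_acc[act], 1e-12)
      x_acc[act] <- x_acc[act] / sum(x_acc[act])
      x <- x_acc
    }
    # far from the dew temperature the composition loop may genuinely fail;
    # during root bracketing that is tolerated, at the solution it is not
    if (strict) {
      stop(sprintf("dew-point inner iteration did not converge at T = %.3f K; last x = %s",
                   T, paste(signif(x[act], 6), collapse = ", ")), call. = FALSE)
    }
    list(x = x, sum_raw = NA_real_, converged = FALSE)
  }
  f <- function(T) inner(T, strict = FALSE)$sum_raw - 1
  T_d <- .solve_T(f, T_lo, T_hi)
  res <- inner(T_d)
  x <- res$x
  names(x) <- ids
  list(T = T_d, x = x, P = P)
}

#' Isobaric binary T-x-y phase diagram
#'
#' Evaluates bubble points over a uniform liquid-composition grid and dew
#' points over the same grid of vapor compositions, at fixed pressure.
#' Grid endpoints are the pure-component boiling temperatures (Antoine
#' inversion). Grid points where the solver fails are omitted with a
#' message.
#'
#' @inheritParams bubble_point_T
#' @param n_grid number of grid points including endpoints.
#' @return Data frame with columns `P_kPa`, `x1`, `T_bubble_K`,
#'   `y1_at_bubble`, `T_dew_K` (dew interpreted at vapor fraction `x1`).
#' @export
isobaric_diagram <- function(P, component_ids, geometries, model, antoine,
                             n_grid = 101L) {
  ids <- as.character(component_ids)
  .assert(length(ids) == 2L, "isobaric_diagram is for binary systems")
  grid <- seq(0, 1, length.out = n_grid)
  out <- data.frame(P_kPa = P, x1 = grid, T_bubble_K = NA_real_,
                    y1_at_bubble = NA_real_, T_dew_K = NA_real_)
  for (k in seq_along(grid)) {
    g <- grid[k]
    bub <- tryCatch(bubble_point_T(P, c(g, 1 - g), ids, geometries, model, antoine),
                    error = function(e) {
                      message(sprintf("bubble point failed at x1 = %.3f: %s", g,
                                      conditionMessage(e))); NULL })
    if (!is.null(bub)) {
      out$T_bubble_K[k] <- bub$T
      out$y1_at_bubble[k] <- bub$y[1L]
    }
    dew <- tryCatch(dew_point_T(P, c(g, 1 - g), ids, geometries, model, antoine),
                    error = function(e) {
                      message(sprintf("dew point failed at y1 = %.3f: %s", g,
                                      conditionMessage(e))); NULL })
    if (!is.null(dew)) out$T_dew_K[k] <- dew$T
  }
  out
}

#' Locate a binary azeotrope
#'
#' Scans the interior liquid-composition grid for a sign change of
#' y1(x1) - x1 along the bubble curve and refines it by bisection. At a
#' reported azeotrope |y1 - x1| < 1e-8.
#'
#' @inheritParams bubble_point_T
#' @param n_grid interior scan resolution.
#' @return List with `exists` (logical) and, when found, `x1` and `T` (K).
#' @export
find_azeotrope <- function(P, component_ids, geometries, model, antoine,
                           n_grid = 101L) {
  ids <- as.character(component_ids)
  .assert(length(ids) == 2L, "find_azeotrope is for binary systems")
  h <- function(x1) {
    bub <- bubble_point_T(P, c(x1, 1 - x1), ids, geometries, model, antoine)
    bub$y[1L] - x1
  }
  xs <- seq(0.005, 0.995, length.out = n_grid)
  hs <- vapply(xs, h, numeric(1))
  ch <- which(hs[-1] * hs[-length(hs)] < 0)
  if (!length(ch)) return(list(exists = FALSE, x1 = NA_real_, T = NA_real_))
  a <- xs[ch[1L]]; b <- xs[ch[1L] + 1L]
  fa <- hs[ch[1L]]
  while (b - a > 1e-12) {
    m <- (a + b) / 2
    fm <- h(m)
    if (abs(fm) < 1e-10) { a <- b <- m; break }
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
  }
  x1 <- (a + b) / 2
  bub <- bubble_point_T(P, c(x1, 1 - x1), ids, geometries, model, antoine)
  list(exists = TRUE, x1 = x1, T = bub$T)
}

#' Ternary vapor-composition prediction
#'
#' Given pressure and a ternary liquid composition, predicts the
#' equilibrium temperature and vapor composition (the three-component
#' bubble point under the extended Raoult's law). Compositions on an edge
#' of the simplex reduce exactly to the corresponding binary bubble point.
#'
#' @inheritParams bubble_point_T
#' @param x ternary liquid composition (3-vector on the simplex).
#' @return List with `P`, `T` (K), `x`, and predicted `y` (3-vector).
#' @export
predict_ternary_vapor <- function(P, x, component_ids, geometries, model, antoine) {
  .assert(length(x) == 3L && length(component_ids) == 3L,
          "predict_ternary_vapor is for ternary systems")
  bub <- bubble_point_T(P, x, component_ids, geometries, model, antoine)
  list(P = P, T = bub$T, x = stats::setNames(x, component_ids), y = bub$y)
}

#' Read or write an Antoine parameter table
#'
#' Tab-delimited text with a mandatory leading comment line declaring the
#' log10 / kPa / K dialect, then a header and columns `component_id`, `A`,
#' `B`, `C`, `T_min_K`, `T_max_K`.
#'
#' @param path file path.
#' @param antoine an [antoine_table()] (for writing).
#' @return `read_antoine` returns an `antoine_table`; `write_antoine`
#'   returns `path` invisibly.
#' @export
write_antoine <- function(antoine, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# Antoine dialect: log10(p_s/kPa) = A - B/((T/K) + C)", con)
  utils::write.table(as.data.frame(antoine), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_antoine
#' @export
read_antoine <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         encoding = "UTF-8")
  .assert(all(c("component_id", "A", "B", "C", "T_min_K", "T_max_K") %in% names(d)),
          "Antoine table needs columns component_id, A, B, C, T_min_K, T_max_K")
  antoine_table(d$component_id, d$A, d$B, d$C, d$T_min_K, d$T_max_K)
}

#' Export a binary isobaric diagram as delimited text
#'
#' @param diagram output of [isobaric_diagram()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  utils::write.table(diagram, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
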