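#' Mean-field ODE integration of a reaction network
#'
#' Integrates the deterministic counterpart of a network: the right-hand
#' side is the stoichiometry-weighted sum of the propensities evaluated at
#' the continuous state, so SSA ensemble means can be validated against the
#' very same rate laws. For input-driven networks the input species is
#' prescribed by the closed-form trace [eval_input()] (its derivative is
#' never integrated), exactly as the model defines it.
#'
#' Defaults are oracle-grade (`rtol = 1e-8`, `atol = 1e-10`, stiff-capable
#' `lsoda`); the systems are small so this costs nothing.
#'
#' @param network a `reaction_network`.
#' @param spec driving [input_spec()] (defaults to the network's own).
#' @param t_end horizon in minutes.
#' @param times output times; default `0..t_end` by 1 min.
#' @param rtol,atol integrator tolerances.
#' @return An `ode_solution`: list with `times`, `values` (time x species
#'   matrix, input column replaced by the exact trace) and the tolerances.
#' @export
ode_integrate <- function(network, spec = network$input_spec, t_end = 200,
                          times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(times)) times <- seq(0, t_end, by = 1)
  driven <- network$input_species
  if (!is.null(driven) && is.null(spec)) {
    stop("network is input-driven; an input_spec is required", call. = FALSE)
  }
  S <- stoichiometry(network, spec)
  rhs <- make_rhs(network, spec, S)
  y0 <- as.numeric(network$initial_state)
  names(y0) <- network$species
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  vals <- sol[, network$species, drop = FALSE]
  if (!is.null(driven)) vals[, driven] <- eval_input(spec, sol[, "time"])
  if (min(vals) < -1e-6) {
    warning("negative state beyond tolerance in ODE solution", call. = FALSE)
  }
  structure(list(times = sol[, "time"], values = vals, network = network$name,
                 rtol = rtol, atol = atol),
            class = "ode_solution")
}

make_rhs <- function(network, spec, S) {
  driven <- network$input_species
  function(t, y, parms) {
    x <- y
    if (!is.null(driven)) x[driven] <- eval_input(spec, t)
    p <- propensities(network, x, t, spec)
    dx <- as.numeric(crossprod(S, p))
    names(dx) <- network$species
    if (!is.null(driven)) dx[driven] <- 0
    list(dx)
  }
}

#' @export
print.ode_solution <- function(x, ...) {
  cat(sprintf("<ode_solution %s> %d times x %d species\n",
              x$network, length(x$times), ncol(x$values)))
  invisible(x)
}

#' Export an ODE solution as CSV
#'
#' @param sol an `ode_solution`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_ode_csv <- function(sol, path) {
  utils::write.csv(data.frame(time_min = sol$times, sol$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Long-time fixed point of the mean-field equations
#'
#' Integrates to `t_probe` and `2 t_probe` (with the input at its plateau
#' beyond the transient), flags species that are still drifting as divergent
#' (the decoding-section phosphatase DUSP has production but no decay, so it
#' grows without bound -- this is reported, not treated as an error), and
#' polishes the remaining coordinates with damped Newton iterations on the
#' right-hand side using a finite-difference Jacobian.
#'
#' @param network a `reaction_network`.
#' @param spec driving [input_spec()] where required.
#' @param t_probe probe horizon in minutes.
#' @return Named numeric vector of steady-state levels; divergent species are
#'   `NA` and named in the `divergent` attribute.
#' @export
steady_state <- function(network, spec = network$input_spec, t_probe = 2000) {
  sol <- ode_integrate(network, spec, t_end = 2 * t_probe,
                       times = c(0, t_probe, 2 * t_probe))
  x1 <- sol$values[2, ]; x2 <- sol$values[3, ]
  drift <- abs(x2 - x1) / pmax(abs(x2), 1)
  divergent <- drift > 1e-3 & abs(x2) > abs(x1)
  driven <- network$input_species
  t_inf <- 1e8  # exp(-t/T) underflows to 0: input exactly at its plateau
  S <- stoichiometry(network, spec)
  free <- setdiff(network$species[!divergent], driven)
  x <- x2
  if (!is.null(driven)) x[driven] <- eval_input(spec, t_inf)
  rhs_free <- function(xf) {
    x[free] <- xf
    p <- propensities(network, x, t_inf, spec)
    as.numeric(crossprod(S, p))[match(free, network$species)]
  }
  if (!any(divergent) && length(free)) {
    xf <- x[free]
    for (it in 1:50) {
      f <- rhs_free(xf)
      if (max(abs(f)) < 1e-10 * max(1, max(abs(xf)))) break
      J <- num_jacobian(rhs_free, xf)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {                       # damp to keep the state non-negative
        cand <- xf - lambda * step
        if (all(cand > -1e-9) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      xf <- pmax(cand, 0)
    }
    x[free] <- xf
  }
  out <- x
  out[divergent] <- NA_real_
  attr(out, "divergent") <- network$species[divergent]
  out
}

num_jacobian <- function(f, x, h = NULL) {
  n <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-6
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  J
}
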