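#' Pathway input specification
#'
#' The decoding section is driven by a prescribed transient of cytoplasmic
#' doubly phosphorylated ERK,
#' \deqn{ppERK_{cyt}(t) = L [ k_2 (e^{-t/T_2} - 1) - k_1 (e^{-t/T_1} - 1) ],}
#' the difference of two first-order relaxations. `k1`, `k2` (molecules/min)
#' set the amplitudes of the two exponential branches, `T1`, `T2` (min) their
#' time constants, and `L` (dimensionless) scales the whole trace; `L` is the
#' experimental dial for input amplitude. Non-negativity of the trace requires
#' `k1 > k2 > 0` and is enforced here.
#'
#' The same specification also defines the stochastic version of the input:
#' the positive and negative parts of the derivative of the trace become the
#' production and degradation hazards of a time-inhomogeneous birth/death
#' pair, see [input_hazards()].
#'
#' @param k1,k2 amplitude rates (molecules/min); `k1 > k2 > 0`.
#' @param T1,T2 time constants (min), positive.
#' @param L dimensionless scale factor, positive.
#' @param label identifier, one of the reference inputs `"I1"`, `"I2"`,
#'   `"I3"` or `"custom"`.
#' @return An object of class `input_spec`.
#' @seealso [standard_inputs()], [eval_input()], [input_hazards()]
#' @export
input_spec <- function(k1, k2, T1, T2, L = 100, label = "custom") {
  vals <- c(k1 = k1, k2 = k2, T1 = T1, T2 = T2, L = L)
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("input_spec parameters must be finite numbers", call. = FALSE)
  }
  if (!(k1 > k2 && k2 > 0)) {
    stop("input requires k1 > k2 > 0 so that the trace stays non-negative",
         call. = FALSE)
  }
  if (T1 <= 0 || T2 <= 0) stop("time constants T1, T2 must be positive", call. = FALSE)
  if (L <= 0) stop("scale factor L must be positive", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, T1 = T1, T2 = T2, L = L,
                 label = as.character(label)),
            class = "input_spec")
}

#' @export
print.input_spec <- function(x, ...) {
  cat(sprintf("<input_spec %s> k1=%g k2=%g T1=%g T2=%g L=%g (limit %.4g)\n",
              x$label, x$k1, x$k2, x$T1, x$T2, x$L, x$L * (x$k1 - x$k2)))
  invisible(x)
}

#' Evaluate the deterministic input trace
#'
#' Closed form of the input level at time `t` (min). The trace starts at 0,
#' rises on the fast time scale and saturates at `L * (k1 - k2)`.
#'
#' @param spec an [input_spec()].
#' @param t time(s) in minutes, non-negative; vectorized.
#' @return Input level (molecule-count scale), same length as `t`.
#' @export
eval_input <- function(spec, t) {
  stopifnot(inherits(spec, "input_spec"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  spec$L * (spec$k2 * (exp(-t / spec$T2) - 1) - spec$k1 * (exp(-t / spec$T1) - 1))
}

#' Stochastic input hazards
#'
#' Production and degradation event rates of the stochastic input process at
#' time `t`: the positive and negative parts of the time derivative of the
#' deterministic trace,
#' `production = k1 L / T1 * exp(-t/T1)` and
#' `degradation = k2 L / T2 * exp(-t/T2)`. Both decay monotonically. During
#' simulation the degradation hazard is additionally gated to 0 whenever the
#' input count is 0, so counts can never go negative (the ungated hazard does
#' not depend on the state).
#'
#' @inheritParams eval_input
#' @return A list with numeric components `production` and `degradation`
#'   (events/min), each the same length as `t`.
#' @export
input_hazards <- function(spec, t) {
  stopifnot(inherits(spec, "input_spec"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  list(production  = spec$k1 * spec$L / spec$T1 * exp(-t / spec$T1),
       degradation = spec$k2 * spec$L / spec$T2 * exp(-t / spec$T2))
}

#' Reference input parameter sets
#'
#' The three phenomenological input traces used throughout: `I1` and `I3`
#' relax slowly, `I2` is the fast, high-plateau reference condition. Their
#' saturation levels `L*(k1-k2)` at `L = 100` are 22.0, 28.1 and 15.6
#' molecules respectively.
#'
#' @param L scale factor applied to all three specs.
#' @return Named list of three [input_spec()] objects `I1`, `I2`, `I3`.
#' @export
standard_inputs <- function(L = 100) {
  list(I1 = input_spec(2.19,  1.97,  3.16, 8.68, L, "I1"),
       I2 = input_spec(1.23,  0.949, 1.0,  3.69, L, "I2"),
       I3 = input_spec(0.257, 0.101, 9.68, 6.3,  L, "I3"))
}

#' Rescale an input specification
#'
#' @param spec an [input_spec()].
#' @param L new scale factor.
#' @return The spec with `L` replaced (shape parameters untouched).
#' @export
with_L <- function(spec, L) {
  stopifnot(inherits(spec, "input_spec"))
  input_spec(spec$k1, spec$k2, spec$T1, spec$T2, L, spec$label)
}

#' Input-amplitude sweep
#'
#' The default sweep, `10, 20, ..., 120` (12 levels), is the set of input
#' amplitudes over which channels are estimated; each level is one input
#' symbol of the discrete channel.
#'
#' @param lo,hi,step sweep bounds and increment, all positive, `hi >= lo`.
#' @return Ordered numeric vector of L values.
#' @export
l_sweep <- function(lo = 10, hi = 120, step = 10) {
  if (lo <= 0 || step <= 0 || hi < lo) {
    stop("need lo > 0, step > 0 and hi >= lo", call. = FALSE)
  }
  s <- seq(lo, hi, by = step)
  if (!length(s)) stop("empty L sweep", call. = FALSE)
  s
}

#' Export an input trace as CSV
#'
#' Two-column table `(time_min, level)` of the deterministic trace.
#'
#' @param spec an [input_spec()].
#' @param path file to write.
#' @param times sample times in minutes.
#' @return `path`, invisibly.
#' @export
write_input_csv <- function(spec, path, times = seq(0, 200, by = 1)) {
  utils::write.csv(data.frame(time_min = times, level = eval_input(spec, times)),
                   path, row.names = FALSE)
  invisible(path)
}
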