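#' Discrete channel
#'
#' Conditional response distribution `P(R = r_i | S = s_j)` of one molecular
#' readout at one time point, over a shared response partition: rows are
#' input levels (the L values), columns are response bins.
#'
#' @param cond numeric matrix, inputs x bins; rows must be probability
#'   vectors (renormalized, then checked to 1e-12).
#' @param input_labels labels of the input levels.
#' @param bin_edges response-bin edges (length `ncol(cond) + 1`), or `NULL`
#'   for abstract channels.
#' @param species,time optional provenance.
#' @return An object of class `discrete_channel`.
#' @export
discrete_channel <- function(cond, input_labels = rownames(cond),
                             bin_edges = NULL, species = NA_character_,
                             time = NA_real_) {
  cond <- as.matrix(cond)
  if (any(cond < 0)) stop("conditional probabilities must be >= 0", call. = FALSE)
  rs <- rowSums(cond)
  if (any(rs <= 0)) stop("every channel row needs positive mass", call. = FALSE)
  cond <- cond / rs
  stopifnot(all(abs(rowSums(cond) - 1) < 1e-12))
  if (is.null(input_labels)) input_labels <- as.character(seq_len(nrow(cond)))
  rownames(cond) <- input_labels
  structure(list(cond = cond, input_labels = input_labels,
                 bin_edges = bin_edges, species = species, time = time),
            class = "discrete_channel")
}

#' @export
print.discrete_channel <- function(x, ...) {
  cat(sprintf("<discrete_channel> %d inputs x %d bins%s\n",
              nrow(x$cond), ncol(x$cond),
              if (!is.na(x$species)) sprintf(" (%s @ t=%g)", x$species, x$time) else ""))
  invisible(x)
}

#' Estimate a channel from per-input count samples
#'
#' Workhorse shared by [estimate_channel()] and the bootstrap helpers: the
#' pooled min-max range of the samples is split into `bins` equal-width
#' cells (shared support is what makes the channel well defined) and each
#' input's samples are histogrammed and normalized. If all observations are
#' identical the channel degenerates to a single bin, which is valid and
#' carries zero information.
#'
#' @param counts_by_input list of numeric vectors, one per input level.
#' @param bins number of equal-width bins.
#' @param input_labels labels; default names of the list.
#' @param species,time optional provenance.
#' @return A `discrete_channel`.
#' @export
channel_from_counts <- function(counts_by_input, bins = 64,
                                input_labels = names(counts_by_input),
                                species = NA_character_, time = NA_real_) {
  stopifnot(length(counts_by_input) >= 1, bins >= 1)
  if (any(!vapply(counts_by_input, length, 1L))) {
    stop("empty sample set for at least one input", call. = FALSE)
  }
  lo <- min(vapply(counts_by_input, min, 1))
  hi <- max(vapply(counts_by_input, max, 1))
  if (hi <= lo) {  # degenerate pooled range: single-bin channel
    cond <- matrix(1, nrow = length(counts_by_input), ncol = 1)
    return(discrete_channel(cond, input_labels, c(lo - 0.5, lo + 0.5),
                            species, time))
  }
  edges <- seq(lo, hi, length.out = bins + 1)
  cond <- t(vapply(counts_by_input, function(x) {
    i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(i, nbins = bins) / length(x)
  }, numeric(bins)))
  discrete_channel(cond, input_labels, edges, species, time)
}

#' Estimate the response channel at one time point
#'
#' Builds the discrete channel between the input level and the count of one
#' species at time `t` from per-input trajectory ensembles (all sharing the
#' sample grid).
#'
#' @param ensembles list of `trajectory_ensemble`, one per input level (>= 2).
#' @param species species name.
#' @param t time on the shared sample grid.
#' @param bins number of equal-width response bins.
#' @return A `discrete_channel` with provenance filled in.
#' @export
estimate_channel <- function(ensembles, species, t, bins = 64) {
  stopifnot(length(ensembles) >= 2)
  grid <- ensembles[[1]]$sample_times
  for (e in ensembles) {
    stopifnot(inherits(e, "trajectory_ensemble"),
              isTRUE(all.equal(e$sample_times, grid)))
  }
  ti <- time_index(ensembles[[1]], t)
  counts <- lapply(ensembles, function(e) e$counts[, ti, species])
  labels <- names(ensembles)
  if (is.null(labels)) {
    labels <- vapply(ensembles, function(e) {
      L <- e$condition$input$L
      if (is.null(L)) NA_character_ else as.character(L)
    }, "")
    if (anyNA(labels)) labels <- as.character(seq_along(ensembles))
  }
  channel_from_counts(counts, bins, labels, species, t)
}

#' Mutual information of a discrete channel (bits)
#'
#' `I(R;S) = sum_{j,i} p_S(j) P(r_i|s_j) log2( P(r_i|s_j) / p_R(r_i) )`
#' with `p_R` the response mixture; `0 log 0 = 0`.
#'
#' @param p_s input distribution over the channel's rows.
#' @param channel a `discrete_channel`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(p_s, channel) {
  W <- channel$cond
  if (length(p_s) != nrow(W)) stop("p_s does not match channel inputs", call. = FALSE)
  if (any(p_s < 0) || abs(sum(p_s) - 1) > 1e-9) {
    stop("p_s must be a probability distribution", call. = FALSE)
  }
  p_r <- as.numeric(crossprod(W, p_s))
  terms <- W * log2(sweep(W, 2, p_r, "/"))
  terms[W == 0] <- 0
  sum(p_s * rowSums(terms))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Channel capacity via the Arimoto-Blahut algorithm
#'
#' Alternating maximization from the uniform input distribution: given the
#' current `p`, compute the per-input divergences
#' `D_j = sum_r P(r|s_j) log2(P(r|s_j) / p_R(r))` and reweight
#' `p_j <- p_j 2^{D_j}` (normalized). `sum_j p_j D_j` and `max_j D_j` are
#' the standard lower and upper capacity bounds; iteration stops when their
#' gap drops below `tol_bits`.
#'
#' @param channel a `discrete_channel`.
#' @param tol_bits convergence tolerance on the capacity bounds gap (bits).
#' @param max_iter iteration cap; on hitting it the result is flagged
#'   `converged = FALSE` and carries the residual gap.
#' @return A `capacity_result`: `cc_bits`, the maximizing distribution
#'   `p_star`, `iterations`, `gap`, `converged`.
#' @export
arimoto_blahut <- function(channel, tol_bits = 1e-6, max_iter = 10000) {
  stopifnot(inherits(channel, "discrete_channel"), tol_bits > 0)
  W <- channel$cond
  W <- W[, colSums(W) > 0, drop = FALSE]  # unreachable responses carry nothing
  m <- nrow(W)
  p <- rep(1 / m, m)
  logW <- W
  pos <- W > 0
  logW[pos] <- log2(W[pos])
  row_wlogw <- rowSums(W * logW)  # sum_r P(r|s) log2 P(r|s), fixed across iterations
  iter <- 0L; gap <- Inf; cc <- 0
  repeat {
    iter <- iter + 1L
    p_r <- pmax(as.numeric(crossprod(W, p)), 1e-300)
    D <- row_wlogw - as.numeric(W %*% log2(p_r))
    cc <- sum(p * D)
    gap <- max(D) - cc
    if (gap < tol_bits || iter >= max_iter) break
    p <- p * 2^(D - max(D))
    p <- p / sum(p)
  }
  structure(list(cc_bits = max(cc, 0), p_star = p, iterations = iter,
                 gap = gap, converged = gap < tol_bits),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> %.6f bits (%d iterations, gap %.2e%s)\n",
              x$cc_bits, x$iterations, x$gap,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Channel-capacity time series
#'
#' Applies [estimate_channel()] + [arimoto_blahut()] at every requested
#' sample time; the typical trace of a transient readout has a rise phase, a
#' maximum and a decay.
#'
#' @inheritParams estimate_channel
#' @param times times to evaluate; default the full shared grid.
#' @param tol_bits Arimoto-Blahut tolerance.
#' @return `data.frame(time, cc, gap, iterations)`.
#' @export
cc_timeseries <- function(ensembles, species, bins = 64, tol_bits = 1e-6,
                          times = NULL) {
  if (is.null(times)) times <- ensembles[[1]]$sample_times
  res <- lapply(times, function(t) {
    ch <- estimate_channel(ensembles, species, t, bins)
    ab <- arimoto_blahut(ch, tol_bits)
    data.frame(time = t, cc = ab$cc_bits, gap = ab$gap,
               iterations = ab$iterations)
  })
  do.call(rbind, res)
}

# joint channel of several readouts under conditional independence, with
# all-zero response columns pruned (the support actually realized is tiny
# compared with the full bin product)
joint_channel <- function(channels) {
  stopifnot(length(channels) >= 1)
  labels <- channels[[1]]$input_labels
  for (ch in channels) {
    if (!identical(ch$input_labels, labels)) {
      stop("channels must share input labels", call. = FALSE)
    }
  }
  cells <- prod(vapply(channels, function(ch) ncol(ch$cond), 1))
  if (cells > 5e6) {
    stop("joint response support too large (", cells,
         " cells); use coarser binning", call. = FALSE)
  }
  W <- channels[[1]]$cond
  for (ch in channels[-1]) {
    V <- ch$cond
    W <- do.call(rbind, lapply(seq_len(nrow(W)), function(j)
      as.vector(outer(V[j, ], W[j, ]))))
    keep <- colSums(W) > 0
    W <- W[, keep, drop = FALSE]
  }
  discrete_channel(W, labels)
}

#' Multivariate mutual information of a gene set (bits)
#'
#' `I(R_1, ..., R_n; S)` of several readouts jointly against the input,
#' computed by direct summation under conditional independence,
#' `P(r_1..r_n | s) = prod_i P(r_i | s)` -- the non-redundant information
#' carried by the set. By default `p_s` is the capacity-achieving
#' distribution of the joint (factorized) channel, obtained by running
#' Arimoto-Blahut on it, so the reported MMI is the set's capacity; any
#' explicit `p_s` (e.g. a single gene's maximizer, or uniform) can be
#' supplied instead.
#'
#' With a single channel this reduces exactly to [mutual_information()].
#'
#' @param channels list of `discrete_channel` sharing input labels.
#' @param p_s input distribution, or `NULL` for the joint-channel maximizer.
#' @param tol_bits Arimoto-Blahut tolerance used when `p_s` is `NULL`.
#' @return MMI in bits.
#' @export
mmi <- function(channels, p_s = NULL, tol_bits = 1e-6) {
  if (inherits(channels, "discrete_channel")) channels <- list(channels)
  J <- joint_channel(channels)
  if (is.null(p_s)) p_s <- arimoto_blahut(J, tol_bits)$p_star
  mutual_information(p_s, J)
}

#' Coefficient of variation of a readout
#'
#' Across-realization standard deviation divided by the mean at a fixed
#' time: the standard dimensionless noise measure for molecular counts.
#'
#' @param ens a `trajectory_ensemble`.
#' @param species species name.
#' @param t time on the sample grid.
#' @return SD/mean; `NA` when the mean is zero (undefined).
#' @export
coefficient_of_variation <- function(ens, species, t) {
  x <- ens$counts[, time_index(ens, t), species]
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Export a channel as CSV with a JSON sidecar
#'
#' The matrix goes to `path` (rows = inputs); bin edges and labels go to
#' `<path>.json`.
#'
#' @param channel a `discrete_channel`.
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(channel, path) {
  utils::write.csv(channel$cond, path, row.names = TRUE)
  jsonlite::write_json(list(input_labels = channel$input_labels,
                            bin_edges = channel$bin_edges,
                            species = channel$species, time = channel$time),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
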