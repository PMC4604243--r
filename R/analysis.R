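#' Binned population firing rate
#'
#' rate(bin) = spike count in bin / (n_cells x bin width), averaged over
#' trials when a list of spike tables is supplied. The default 100 ms bin
#' matches the analysis convention of the experiments.
#'
#' @param spikes data.frame (cell, time_ms) or a list of them (one per
#'   trial).
#' @param population cell ids of the population (non-empty).
#' @param t_total_ms total duration (ms).
#' @param bin_ms bin width (ms).
#' @return list of class `rate_trace` with bin_edges (ms), rate (Hz),
#'   n_cells, n_trials.
#' @export
binned_rate <- function(spikes, population, t_total_ms, bin_ms = 100) {
  if (length(population) == 0) stop("empty population")
  trials <- if (is.data.frame(spikes)) list(spikes) else spikes
  edges <- seq(0, t_total_ms, by = bin_ms)
  if (edges[length(edges)] < t_total_ms) edges <- c(edges, t_total_ms)
  counts <- numeric(length(edges) - 1)
  for (tr in trials) {
    sel <- tr$time_ms[tr$cell %in% population]
    sel <- sel[sel > 0 & sel <= t_total_ms]
    if (length(sel)) {
      bin <- findInterval(sel, edges, left.open = TRUE)
      counts <- counts + tabulate(bin, nbins = length(counts))
    }
  }
  widths_s <- diff(edges) / 1000
  rate <- counts / (length(population) * widths_s * length(trials))
  structure(list(bin_edges = edges, rate = rate,
                 n_cells = length(population), n_trials = length(trials)),
            class = "rate_trace")
}

#' Center-minus-surround rate difference
#'
#' Bin-wise difference between two rate traces on identical bin edges
#' (the saliency statistic: positive means the center site fires above
#' the surround site).
#'
#' @param rate1,rate2 `rate_trace` objects with matching bins.
#' @return list of class `delta_trace` with bin_edges and delta (Hz).
#' @export
delta_trace <- function(rate1, rate2) {
  if (!isTRUE(all.equal(rate1$bin_edges, rate2$bin_edges)))
    stop("mismatched binning")
  structure(list(bin_edges = rate1$bin_edges,
                 delta = rate1$rate - rate2$rate), class = "delta_trace")
}

#' Mean of a rate trace over a time window
#'
#' Averages over bins fully inside [from_ms, to_ms].
#'
#' @param trace a `rate_trace` or `delta_trace`.
#' @param from_ms,to_ms window (ms).
#' @return mean rate (Hz).
#' @export
window_mean <- function(trace, from_ms, to_ms) {
  e <- trace$bin_edges
  inside <- e[-length(e)] >= from_ms & e[-1] <= to_ms
  if (!any(inside)) stop("no bins fully inside the window")
  vals <- if (inherits(trace, "delta_trace")) trace$delta else trace$rate
  mean(vals[inside])
}

#' Size-tuning summary
#'
#' Builds the response-vs-stimulus-size curve (mean PC rate of the
#' recorded minicolumn over the stimulus window) for the control condition
#' and, optionally, the disinhibited (VIP-driven) condition, plus their
#' difference.
#'
#' @param sizes number of driven minicolumns per point (>= 2; >= 3 for a
#'   meaningful tuning shape).
#' @param control responses without VIP drive (Hz), same length as sizes.
#' @param disinhibited optional responses with VIP drive (Hz).
#' @param normalize divide each curve by its own peak.
#' @return data.frame with size, control, optionally disinhibited and
#'   difference (disinhibited - control, computed before normalisation).
#' @export
size_tuning <- function(sizes, control, disinhibited = NULL,
                        normalize = TRUE) {
  if (length(sizes) < 2) stop("need at least 2 stimulus sizes")
  stopifnot(length(control) == length(sizes))
  out <- data.frame(size = sizes, control = control)
  if (!is.null(disinhibited)) {
    stopifnot(length(disinhibited) == length(sizes))
    out$disinhibited <- disinhibited
    out$difference <- disinhibited - control
  }
  if (normalize) {
    out$control <- out$control / max(out$control)
    if (!is.null(disinhibited))
      out$disinhibited <- out$disinhibited / max(disinhibited)
  }
  out[order(out$size), , drop = FALSE]
}
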