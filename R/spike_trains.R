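#' Generate correlated Poisson spike trains (mother/child)
#'
#' A mother Poisson train of rate `rate` is thinned once with transfer
#' probability `p = correlation`; the surviving mother spikes are common
#' to all children, and each child additionally receives an independent
#' Poisson train of rate `(1 - p) * rate`. Every child then has
#' expected rate `rate`, and the expected pairwise spike-count
#' correlation between children equals `correlation` (the common
#' component contributes `p * rate` of shared variance out of `rate`).
#' At `p = 1` all children equal the mother; at `p = 0` they are
#' independent.
#'
#' @param n_trains number of child trains.
#' @param rate target rate of each child, Hz.
#' @param correlation pairwise correlation `c = p` in `[0, 1]`.
#' @param duration train length, s.
#' @param seed integer seed.
#' @return A list of class `spike_trains`: numeric vectors of spike
#'   times (s), sorted, with `duration` and the generating parameters as
#'   attributes.
#' @export
correlated_spike_trains <- function(n_trains, rate, correlation, duration,
                                    seed = 1L) {
  if (correlation < 0 || correlation > 1) stop("correlation must be in [0, 1]")
  stopifnot(rate > 0, duration > 0, n_trains >= 1)
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  p <- correlation
  n_mother <- stats::rpois(1, rate * duration)
  mother <- sort(stats::runif(n_mother, 0, duration))
  common <- mother[stats::runif(n_mother) < p]
  trains <- lapply(seq_len(n_trains), function(i) {
    k <- stats::rpois(1, (1 - p) * rate * duration)
    sort(c(common, stats::runif(k, 0, duration)))
  })
  structure(trains, class = "spike_trains", duration = duration,
            rate = rate, correlation = correlation)
}

#' Mean pairwise spike-count correlation of a train set
#'
#' Pearson correlation of spike counts in fixed bins, averaged over all
#' distinct train pairs. The 25 ms default bin is the package's declared
#' estimator scale.
#'
#' @param trains a list of spike-time vectors (s).
#' @param duration total duration, s (defaults to the `duration`
#'   attribute).
#' @param bin bin width, s.
#' @return Mean pairwise Pearson correlation (scalar).
#' @export
spike_train_correlation <- function(trains, duration = NULL, bin = 0.025) {
  duration <- duration %||% attr(trains, "duration")
  if (is.null(duration)) stop("duration must be supplied")
  edges <- seq(0, duration, by = bin)
  nb <- length(edges) - 1L
  counts <- vapply(trains, function(tt) {
    tabulate(findInterval(tt, edges, rightmost.closed = TRUE), nbins = nb)
  }, numeric(nb))
  cm <- suppressWarnings(stats::cor(counts))
  mean(cm[upper.tri(cm)], na.rm = TRUE)
}

#' Mean firing rate of each train
#'
#' @param trains list of spike-time vectors.
#' @param duration duration, s.
#' @return Numeric vector of rates, Hz.
#' @export
spike_train_rates <- function(trains, duration = NULL) {
  duration <- duration %||% attr(trains, "duration")
  vapply(trains, length, numeric(1)) / duration
}

#' Write spike trains as a two-column TSV (train id, spike time s)
#'
#' @param trains list of spike-time vectors.
#' @param path output path.
#' @export
write_spike_trains <- function(trains, path) {
  df <- data.frame(
    train = rep(seq_along(trains), vapply(trains, length, integer(1))),
    time = unlist(trains))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
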