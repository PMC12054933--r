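#' Instantaneous firing rates on a window grid
#'
#' Counts spikes of each neuron in consecutive windows of length
#' `window` and divides by the window length: `nu_j(t) = n_j(t) / T` for
#' the interval `[t, t + T]`. The reference window is `T = 0.05` s.
#'
#' @param raster a data frame with columns `time` and `neuron`, or a
#'   `qif_sim` object.
#' @param N number of neurons.
#' @param window window length `T` in seconds.
#' @param t_start,t_end analysis interval; defaults to `[0, max spike time]`.
#' @return an object of class `rate_series`: list with `time` (window
#'   start times), `rates` (`N x n_windows` matrix, Hz) and `window`.
#' @export
instantaneous_rate <- function(raster, N, window = 0.05, t_start = 0,
                               t_end = NULL) {
  raster <- as_raster(raster)
  if (is.null(t_end))
    t_end <- if (nrow(raster) > 0) max(raster$time) else t_start + window
  n_win <- max(1L, floor((t_end - t_start) / window))
  starts <- t_start + (seq_len(n_win) - 1) * window
  keep <- raster$time >= t_start & raster$time < t_start + n_win * window
  win <- floor((raster$time[keep] - t_start) / window) + 1L
  idx <- (win - 1L) * N + raster$neuron[keep]
  counts <- tabulate(idx, nbins = N * n_win)
  structure(list(time = starts,
                 rates = matrix(counts / window, nrow = N, ncol = n_win),
                 window = window), class = "rate_series")
}

#' Mean instantaneous rate of a population
#'
#' @param rates a `rate_series` from [instantaneous_rate()].
#' @param neurons indices of the population (default all).
#' @return numeric vector of population-mean rates (Hz) per window.
#' @export
population_rate <- function(rates, neurons = NULL) {
  m <- rates$rates
  if (!is.null(neurons)) m <- m[neurons, , drop = FALSE]
  colMeans(m)
}

#' Coefficient of variation of interspike intervals
#'
#' `CV_j = sd(ISI_j) / mean(ISI_j)` per neuron. Perfectly periodic firing
#' gives 0 and a Poisson process 1. Neurons with fewer than `min_isi`
#' interspike intervals are flagged undefined (`NA`), which by default
#' excludes the near-degenerate estimates produced by very few spikes.
#'
#' @inheritParams instantaneous_rate
#' @param min_isi minimum number of ISIs required (default 10).
#' @return numeric vector of length `N`, `NA` where undefined.
#' @export
coefficient_of_variation <- function(raster, N, min_isi = 10) {
  raster <- as_raster(raster)
  out <- rep(NA_real_, N)
  sp <- split(raster$time, factor(raster$neuron, levels = seq_len(N)))
  for (j in seq_len(N)) {
    isi <- diff(sort(sp[[j]]))
    if (length(isi) >= max(min_isi, 2))
      out[j] <- sd(isi) / mean(isi)
  }
  out
}

#' Interpolated spike phases
#'
#' Associates a continuous phase to each neuron's spike train by linear
#' interpolation between consecutive spikes:
#' `theta_j(t) = 2*pi*(t - t_n)/(t_{n+1} - t_n)` for
#' `t_n <= t <= t_{n+1}`. The phase is undefined before a neuron's first
#' and after its last spike; such entries are `NA` and are excluded from
#' the order parameter rather than frozen, to avoid spurious coherence
#' from silent neurons.
#'
#' @inheritParams instantaneous_rate
#' @param times evaluation time points.
#' @return an `N x length(times)` matrix of phases in `[0, 2*pi]`, `NA`
#'   where undefined.
#' @export
spike_phases <- function(raster, N, times) {
  raster <- as_raster(raster)
  theta <- matrix(NA_real_, N, length(times))
  sp <- split(raster$time, factor(raster$neuron, levels = seq_len(N)))
  for (j in seq_len(N)) {
    s <- sort(sp[[j]])
    if (length(s) < 2) next
    idx <- findInterval(times, s)
    ok <- idx >= 1L & idx < length(s)
    ii <- idx[ok]
    theta[j, ok] <- 2 * pi * (times[ok] - s[ii]) / (s[ii + 1] - s[ii])
    theta[j, times == s[length(s)]] <- 2 * pi  # inclusive right endpoint
  }
  theta
}

#' Kuramoto order parameter from spike phases
#'
#' `Z(t) = R(t) exp(i Phi(t))` is the mean of the unit phasors
#' `exp(i theta_j(t))` over the neurons with a defined phase at `t`.
#' `R = 1` indicates full synchrony; an asynchronous network of `N`
#' neurons fluctuates around `1/sqrt(N)`.
#'
#' @param phases phase matrix from [spike_phases()] (neurons x times).
#' @param times optional time vector to attach to the output.
#' @return data frame with columns `time` (if given), `R`, `Phi` and `n`
#'   (number of neurons with defined phase).
#' @export
kuramoto <- function(phases, times = NULL) {
  z_re <- cos(phases); z_im <- sin(phases)
  n <- colSums(!is.na(phases))
  re <- colSums(z_re, na.rm = TRUE); im <- colSums(z_im, na.rm = TRUE)
  R <- ifelse(n > 0, sqrt(re^2 + im^2) / n, NA_real_)
  out <- data.frame(R = R, Phi = atan2(im, re), n = n)
  if (!is.null(times)) out <- cbind(data.frame(time = times), out)
  out
}

#' Kuramoto order-parameter time series of a spike raster
#'
#' Convenience wrapper chaining [spike_phases()] and [kuramoto()] on a
#' regular time grid, optionally restricted to a subset of neurons.
#'
#' @inheritParams instantaneous_rate
#' @param dt grid spacing (s).
#' @param neurons optional neuron subset.
#' @return data frame with `time`, `R`, `Phi`, `n`.
#' @export
kuramoto_series <- function(raster, N, dt = 0.02, t_start = 0, t_end = NULL,
                            neurons = NULL) {
  raster <- as_raster(raster)
  if (is.null(t_end))
    t_end <- if (nrow(raster) > 0) max(raster$time) else t_start + dt
  if (!is.null(neurons)) {
    neurons <- sort(unique(neurons))
    raster <- raster[raster$neuron %in% neurons, , drop = FALSE]
    raster$neuron <- match(raster$neuron, neurons)
    N <- length(neurons)
  }
  times <- seq(t_start, t_end, by = dt)
  kuramoto(spike_phases(raster, N, times), times)
}

#' Mean weight-change rate between snapshots
#'
#' `K(t) = sum_{i != j} (w_ij(t + dt) - w_ij(t)) / dt / (N (N - 1))`,
#' positive for net potentiation. The reference snapshot spacing is
#' 0.1 s.
#'
#' @param snapshots list of `N x N` weight matrices.
#' @param times snapshot times; defaults to spacing `dt_pair`.
#' @param dt_pair spacing (s) used when `times` is missing.
#' @return data frame with `time` (of the first snapshot of each pair)
#'   and `K`.
#' @export
weight_change_rate <- function(snapshots, times = NULL, dt_pair = 0.1) {
  n <- length(snapshots)
  if (n < 2) stop("need at least two snapshots")
  if (is.null(times)) times <- (seq_len(n) - 1) * dt_pair
  N <- nrow(snapshots[[1]])
  K <- vapply(seq_len(n - 1), function(k) {
    d <- snapshots[[k + 1]] - snapshots[[k]]
    diag(d) <- 0
    sum(d) / (times[k + 1] - times[k]) / (N * (N - 1))
  }, numeric(1))
  data.frame(time = times[-n], K = K)
}

#' Detect spontaneous recall events
#'
#' Slides a window of length `window` (reference: 0.2 s) over the raster
#' and computes, for each memory module, the fraction of its exclusive
#' excitatory neurons that spike within the window. A window is a recall
#' candidate for module `m` when that fraction exceeds
#' `participation_threshold` while all other modules stay at or below it;
#' windows where two or more modules exceed the threshold are flagged
#' `"joint"`. Overlapping candidate windows with the same label are
#' merged into one event.
#'
#' @inheritParams instantaneous_rate
#' @param assignment a [population_assignment()] object (its hub set, if
#'   any, is treated as an additional detection set).
#' @param window window length (s).
#' @param step window slide (s); default `window / 4`.
#' @param participation_threshold minimum spiking fraction (default 0.5).
#' @return data frame with columns `start`, `end`, `label` (module id as
#'   character, `"hubs"`, or `"joint"`) and `peak_fraction`.
#' @export
detect_recalls <- function(raster, assignment, window = 0.2, step = NULL,
                           participation_threshold = 0.5, t_start = 0,
                           t_end = NULL) {
  raster <- as_raster(raster)
  if (is.null(step)) step <- window / 4
  if (is.null(t_end))
    t_end <- if (nrow(raster) > 0) max(raster$time) else t_start + window
  sets <- detection_sets(assignment)
  starts <- seq(t_start, max(t_start, t_end - window), by = step)
  ord <- order(raster$time)
  rt <- raster$time[ord]; rn <- raster$neuron[ord]
  lo <- findInterval(starts, rt, left.open = TRUE) + 1L
  hi <- findInterval(starts + window, rt)

  frac <- matrix(0, length(starts), length(sets))
  for (k in seq_along(starts)) {
    if (lo[k] > hi[k]) next
    ids <- unique(rn[lo[k]:hi[k]])
    for (s in seq_along(sets))
      frac[k, s] <- sum(sets[[s]] %in% ids) / length(sets[[s]])
  }

  above <- frac > participation_threshold
  n_above <- rowSums(above)
  label <- rep(NA_character_, length(starts))
  label[n_above == 1] <- names(sets)[apply(above[n_above == 1, , drop = FALSE],
                                           1, which)]
  label[n_above > 1] <- "joint"

  events <- list()
  k <- 1L
  while (k <= length(starts)) {
    if (is.na(label[k])) { k <- k + 1L; next }
    j <- k
    while (j < length(starts) && !is.na(label[j + 1L]) &&
           label[j + 1L] == label[k] &&
           starts[j + 1L] <= starts[j] + window) j <- j + 1L
    events[[length(events) + 1L]] <- data.frame(
      start = starts[k], end = starts[j] + window, label = label[k],
      peak_fraction = max(frac[k:j, , drop = FALSE]))
    k <- j + 1L
  }
  if (length(events) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), peak_fraction = numeric(0)))
  do.call(rbind, events)
}

#' Classify the stability of a stored-memory configuration
#'
#' A configuration is stable when (i) the network displays asynchronous
#' irregular firing -- the time-median of the Kuramoto order parameter
#' stays below `r_ceiling` and the population-mean rate below
#' `rate_ceiling` -- and (ii) every memory module exhibits at least one
#' independent spontaneous recall over the observation horizon. It is
#' unstable as soon as one module shows no recall, or the asynchrony
#' check fails.
#'
#' @inheritParams detect_recalls
#' @param recalls optional precomputed [detect_recalls()] result.
#' @param r_ceiling asynchrony ceiling on the median order parameter
#'   (default 0.5).
#' @param rate_ceiling ceiling on the population-mean rate in Hz
#'   (default 20).
#' @param r_dt grid spacing for the order-parameter series.
#' @return a list of class `stability_verdict`: `stable`,
#'   `recall_counts` (per module), `median_R`, `mean_rate`,
#'   `asynchronous`, and the thresholds used.
#' @export
classify_stability <- function(raster, assignment, recalls = NULL,
                               window = 0.2, participation_threshold = 0.5,
                               r_ceiling = 0.5, rate_ceiling = 20,
                               r_dt = 0.02, t_start = 0, t_end = NULL) {
  raster <- as_raster(raster)
  if (is.null(t_end))
    t_end <- if (nrow(raster) > 0) max(raster$time) else t_start + 1
  if (is.null(recalls))
    recalls <- detect_recalls(raster, assignment, window = window,
                              participation_threshold = participation_threshold,
                              t_start = t_start, t_end = t_end)
  modules <- as.character(seq_len(assignment$M))
  counts <- vapply(modules, function(m) sum(recalls$label == m), integer(1))
  ks <- kuramoto_series(raster, assignment$N, dt = r_dt, t_start = t_start,
                        t_end = t_end)
  med_R <- median(ks$R, na.rm = TRUE)
  mean_rate <- nrow(raster[raster$time >= t_start & raster$time <= t_end, ]) /
    assignment$N / (t_end - t_start)
  asyn <- isTRUE(med_R < r_ceiling) && mean_rate < rate_ceiling
  structure(list(stable = asyn && all(counts >= 1L), recall_counts = counts,
                 median_R = med_R, mean_rate = mean_rate,
                 asynchronous = asyn, r_ceiling = r_ceiling,
                 rate_ceiling = rate_ceiling,
                 participation_threshold = participation_threshold),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("Stability verdict: %s\n",
              if (x$stable) "STABLE" else "unstable"))
  cat(sprintf("  median R = %.3f (< %.2f: %s), mean rate = %.2f Hz (< %g)\n",
              x$median_R, x$r_ceiling, x$asynchronous, x$mean_rate,
              x$rate_ceiling))
  cat("  recalls per module:", paste(x$recall_counts, collapse = " "), "\n")
  invisible(x)
}

#' Intra- and inter-module block means of the weight matrix
#'
#' Mean synaptic weight split by pre-synaptic class (excitatory `E`,
#' Hebbian inhibitory `H`, anti-Hebbian inhibitory `A`), post-synaptic
#' type (`E` or `I`) and whether pre and post belong to the same module.
#' Neurons outside every module (untrained, or hub neurons belonging to
#' more than one module) are excluded.
#'
#' @param weights `N x N` weight matrix.
#' @param class_of per-neuron synapse classes (`"e"`, `"hi"`, `"ai"`).
#' @param module integer module id per neuron (`NA` = unassigned), e.g.
#'   from [module_vector()].
#' @return data frame with columns `pre`, `post`, `intra`, `inter`.
#' @export
module_weight_stats <- function(weights, class_of, module) {
  N <- nrow(weights)
  stopifnot(length(class_of) == N, length(module) == N)
  pre_class <- c(e = "E", hi = "H", ai = "A")[class_of]
  post_class <- ifelse(class_of == "e", "E", "I")
  assigned <- !is.na(module)
  out <- expand.grid(pre = c("E", "H", "A"), post = c("E", "I"),
                     stringsAsFactors = FALSE)
  out$intra <- NA_real_; out$inter <- NA_real_
  same <- outer(module, module, "==")
  off <- !diag(TRUE, N)
  both <- outer(assigned, assigned, "&") & off
  for (r in seq_len(nrow(out))) {
    sel <- outer(post_class == out$post[r], pre_class == out$pre[r], "&") & both
    if (any(sel & same)) out$intra[r] <- mean(weights[sel & same])
    if (any(sel & !same)) out$inter[r] <- mean(weights[sel & !same])
  }
  out
}

#' Estimate the forgetting time of a single recall event
#'
#' Under uncorrelated background firing the forgetting offset `f` makes
#' excitatory synapses drift slowly towards depression; spontaneous
#' recalls counteract this drift with short potentiation boosts. The
#' forgetting time is the duration of asynchronous background firing
#' needed to erase the mean weight reinforcement contributed by one
#' recall:
#' `t_forget = boost / |drift|`.
#'
#' Both quantities are measured with a two-neuron simulation oracle on an
#' excitatory synapse held at the mid-range weight `w0` (where the tanh
#' soft bounds are inactive). The drift is the mean weight change per
#' second for a pre/post pair firing as independent Poisson processes at
#' `background_rate`, with every spike triggering a last-spike STDP
#' update. The boost is the mean total weight change produced by one
#' recall volley, modelled on the transient-synchrony events of the
#' resting network: each neuron emits `volley_spikes` near-coincident
#' spikes at the elevated within-event rate `volley_rate`, with uniform
#' jitter of `jitter` seconds between pre and post, so that last-spike
#' pairings fall inside the volley.
#'
#' @param stdp an [stdp_params()] object (its `e` kernel is used).
#' @param background_rate background firing rate (Hz), reference 2 Hz.
#' @param w0 weight at which the drift and boost are evaluated.
#' @param drift_time simulated background duration (s).
#' @param n_recalls number of simulated recall volleys averaged.
#' @param volley_spikes spikes per neuron within one recall volley.
#' @param volley_rate within-volley firing rate (Hz).
#' @param jitter spike-time jitter within the volley (s).
#' @param seed optional seed.
#' @return a list of class `forgetting_estimate`: `time` (s; `Inf` when
#'   there is no net depression), `boost`, `drift_rate`.
#' @export
forgetting_time_estimate <- function(stdp = stdp_params(M = 2),
                                     background_rate = 2, w0 = 0.5,
                                     drift_time = 400, n_recalls = 400,
                                     volley_spikes = 2, volley_rate = 15,
                                     jitter = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dw_at <- function(dt_diff) weight_update(w0, dt_diff, "e", stdp) - w0

  # background drift: independent Poisson pre/post, last-spike pairing,
  # weight held at w0 so the rate is not distorted by the soft bounds
  t_pre <- cumsum(rexp(ceiling(background_rate * drift_time * 2),
                       background_rate))
  t_post <- cumsum(rexp(ceiling(background_rate * drift_time * 2),
                        background_rate))
  t_pre <- t_pre[t_pre <= drift_time]
  t_post <- t_post[t_post <= drift_time]
  ev <- rbind(data.frame(t = t_pre, who = "pre"),
              data.frame(t = t_post, who = "post"))
  ev <- ev[order(ev$t), ]
  last_pre <- NA_real_; last_post <- NA_real_; acc <- 0
  for (k in seq_len(nrow(ev))) {
    if (ev$who[k] == "pre") {
      if (!is.na(last_post)) acc <- acc + dw_at(last_post - ev$t[k])
      last_pre <- ev$t[k]
    } else {
      if (!is.na(last_pre)) acc <- acc + dw_at(ev$t[k] - last_pre)
      last_post <- ev$t[k]
    }
  }
  drift_rate <- acc / drift_time

  # recall boost: short volley at the elevated within-event rate
  gap <- 1 / volley_rate
  boosts <- vapply(seq_len(n_recalls), function(r) {
    pre <- (seq_len(volley_spikes) - 1) * gap + runif(volley_spikes, 0, jitter)
    post <- (seq_len(volley_spikes) - 1) * gap + runif(volley_spikes, 0, jitter)
    ev <- rbind(data.frame(t = pre, who = "pre"),
                data.frame(t = post, who = "post"))
    ev <- ev[order(ev$t), ]
    lp <- NA_real_; lq <- NA_real_; b <- 0
    for (k in seq_len(nrow(ev))) {
      if (ev$who[k] == "pre") {
        if (!is.na(lq)) b <- b + dw_at(lq - ev$t[k])
        lp <- ev$t[k]
      } else {
        if (!is.na(lp)) b <- b + dw_at(ev$t[k] - lp)
        lq <- ev$t[k]
      }
    }
    b
  }, numeric(1))
  boost <- mean(boosts)

  time <- if (drift_rate >= 0) Inf else boost / abs(drift_rate)
  structure(list(time = time, boost = boost, drift_rate = drift_rate,
                 background_rate = background_rate, w0 = w0),
            class = "forgetting_estimate")
}

#' @export
print.forgetting_estimate <- function(x, ...) {
  cat(sprintf(paste0("Forgetting-time estimate: %.2f s ",
                     "(boost %.4g, drift %.4g /s at %g Hz background)\n"),
              x$time, x$boost, x$drift_rate, x$background_rate))
  invisible(x)
}

as_raster <- function(x) {
  if (inherits(x, "qif_sim")) return(x$raster)
  if (is.matrix(x)) x <- data.frame(time = x[, 1], neuron = as.integer(x[, 2]))
  if (!all(c("time", "neuron") %in% names(x)))
    stop("raster needs columns 'time' and 'neuron'")
  x
}
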