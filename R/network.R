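#' Firing rate of an uncoupled, noise-free QIF neuron
#'
#' In the absence of coupling and noise, a QIF neuron with positive total
#' drive `eta + I` is an oscillator with period `pi * tau_m / sqrt(eta + I)`,
#' hence rate `sqrt(eta + I) / (pi * tau_m)`. For `eta + I <= 0` the neuron
#' is excitable and does not fire.
#'
#' @param eta excitability (vectorised).
#' @param I DC current.
#' @param tau_m membrane time constant (s).
#' @return firing rate(s) in Hz.
#' @examples
#' free_firing_rate((pi * 0.02)^2)        # 1 Hz
#' free_firing_rate(0, (50 * pi * 0.02)^2) # 50 Hz
#' @export
free_firing_rate <- function(eta, I = 0, tau_m = 0.02) {
  drive <- eta + I
  ifelse(drive > 0, sqrt(pmax(drive, 0)) / (pi * tau_m), 0)
}

#' Initialise network state and weights
#'
#' Draws per-neuron excitabilities `eta ~ N(0, eta_sd^2)`, initialises the
#' membrane potentials near rest (uniform in `[Vr, 0]`), builds the
#' connectivity mask if a sparse network was requested, and assembles the
#' initial weight matrix. With `weights = "small-random"` excitatory
#' synapses start uniform in `[0, 0.1]` and inhibitory ones in
#' `[-0.1, 0]`; `"zero"` starts from an empty matrix; alternatively an
#' explicit `N x N` matrix can be supplied (validated against the class
#' bounds and the mask).
#'
#' Draw order under one seed: excitabilities, initial potentials,
#' connectivity mask, initial weights.
#'
#' @param params a [network_params()] object.
#' @param weights `"small-random"`, `"zero"`, or an `N x N` numeric matrix.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return a list of class `qif_state` with elements `eta`, `V`,
#'   `weights`, `mask` (or `NULL`), `class_of` and `params`.
#' @export
init_network <- function(params, weights = c("small-random", "zero"),
                         seed = NULL) {
  if (!inherits(params, "qif_params")) stop("params must be a qif_params object")
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  cls <- neuron_classes(params)
  eta <- rnorm(N, 0, params$eta_sd)
  V <- runif(N, params$Vr, 0)
  mask <- NULL
  if (!is.null(params$connectivity)) {
    mask <- matrix(runif(N * N) < params$connectivity, N, N)
    diag(mask) <- FALSE
  }
  if (is.character(weights)) {
    weights <- match.arg(weights)
    w <- matrix(0, N, N)
    if (weights == "small-random") {
      exc <- cls == "e"
      w[, exc] <- runif(N * sum(exc), 0, 0.05)
      w[, !exc] <- runif(N * sum(!exc), -0.05, 0)
    }
  } else {
    w <- validate_weights(weights, params, mask)
  }
  diag(w) <- 0
  if (!is.null(mask)) w[!mask] <- 0
  structure(list(eta = eta, V = V, weights = w, mask = mask,
                 class_of = cls, params = params), class = "qif_state")
}

validate_weights <- function(w, params, mask = NULL) {
  N <- params$N
  if (!is.matrix(w) || nrow(w) != N || ncol(w) != N)
    stop("weight matrix must be ", N, " x ", N)
  cls <- neuron_classes(params)
  exc <- cls == "e"
  if (any(w[, exc] < 0 | w[, exc] > 1))
    stop("excitatory (pre-synaptic) weights must lie in [0, 1]")
  if (any(w[, !exc] < -1 | w[, !exc] > 0))
    stop("inhibitory (pre-synaptic) weights must lie in [-1, 0]")
  w
}

#' Recording options for [run_simulation()]
#'
#' @param snapshot_times times (s) at which to store full copies of the
#'   weight matrix; the final matrix is always returned.
#' @param k_dt cadence (s) for the mean weight-change rate series `K(t)`
#'   (0 = off). The reference value is 0.1 s.
#' @param stats_dt cadence (s) for intra-/inter-module block-mean weight
#'   series (0 = off); requires `stats_module`.
#' @param stats_module integer module id per neuron (`NA` = unassigned),
#'   used by the block-mean recorder.
#' @param drive_neurons neuron indices whose synaptic drive variables are
#'   recorded.
#' @param drive_dt cadence (s) for drive recording.
#' @return a list of recorder settings.
#' @export
record_options <- function(snapshot_times = numeric(0), k_dt = 0,
                           stats_dt = 0, stats_module = NULL,
                           drive_neurons = integer(0), drive_dt = 0) {
  list(snapshot_times = sort(snapshot_times), k_dt = k_dt,
       stats_dt = stats_dt, stats_module = stats_module,
       drive_neurons = drive_neurons, drive_dt = drive_dt)
}

#' Run the spiking-network simulation
#'
#' Integrates the coupled stochastic QIF equations with an Euler scheme of
#' step `dt`: non-refractory neurons advance by
#' `dV = dt/tau_m * (V^2 + eta + ge*Se + ghi*Shi + gai*Sai + I + xi)`,
#' where the three synaptic drives decay exponentially with their time
#' constants and jump by `w[i,j]/N_q` whenever pre-synaptic neuron `j` of
#' class `q` fires. A neuron crossing the threshold `Vp` emits a spike at
#' the corrected time `t + tau_m/V`, is reset to `Vr` and held there for
#' `refractory_scale * tau_m / V` seconds. If plasticity is on, every
#' spike triggers soft-bounded STDP updates of its incident synapses
#' under last-spike pairing (see [weight_update()]); plasticity is active
#' throughout the run, including rest and stimulation epochs.
#'
#' @param state a `qif_state` from [init_network()].
#' @param protocol optional stimulation protocol from
#'   [build_stimulus_schedule()]; `NULL` simulates rest.
#' @param duration simulated time (s).
#' @param plasticity logical; freeze the weights if `FALSE`.
#' @param stdp an [stdp_params()] object.
#' @param seed optional integer seed for the noise stream; `NULL`
#'   continues the current stream.
#' @param record a [record_options()] list.
#' @return an object of class `qif_sim`: list with `raster` (data frame
#'   `time`, `neuron`), `weights` (final matrix), `state` (updated
#'   `qif_state`), `snapshots` + `snapshot_times`, `K` (data frame), a
#'   block-stats data frame `stats`, recorded `drives`, and the inputs
#'   used.
#' @export
run_simulation <- function(state, protocol = NULL, duration,
                           plasticity = TRUE, stdp = stdp_params(),
                           seed = NULL, record = record_options()) {
  if (!inherits(state, "qif_state")) stop("state must come from init_network()")
  if (duration <= 0) stop("duration must be positive")
  params <- state$params
  if (!is.null(seed)) set.seed(seed)

  if (is.null(protocol)) {
    epochs <- matrix(numeric(0), 0, 3)
    targets <- list()
  } else {
    if (!inherits(protocol, "qif_protocol"))
      stop("protocol must come from build_stimulus_schedule()")
    if (nrow(protocol$epochs) > 0 &&
        max(protocol$epochs$t_off) > duration + 1e-9)
      stop("protocol extends past the simulation duration")
    epochs <- as.matrix(protocol$epochs[, c("t_on", "t_off", "amplitude")])
    targets <- lapply(protocol$targets, function(x) as.integer(x) - 1L)
  }

  stats_module <- record$stats_module
  if (is.null(stats_module)) stats_module <- integer(0)
  else {
    stats_module <- as.integer(stats_module)
    stats_module[is.na(stats_module)] <- -1L
  }
  rec <- list(snapshot_times = record$snapshot_times, k_dt = record$k_dt,
              stats_dt = record$stats_dt, stats_module = stats_module,
              drive_neurons = as.integer(record$drive_neurons) - 1L,
              drive_dt = record$drive_dt)
  if (rec$stats_dt > 0 && length(rec$stats_module) != params$N)
    stop("stats_dt recording needs stats_module of length N")

  cpars <- list(tau_m = params$tau_m, dt = params$dt, tau_de = params$tau_de,
                tau_di = params$tau_di, ge = params$ge, ghi = params$ghi,
                gai = params$gai, Vp = params$Vp, Vr = params$Vr,
                noise_sigma = params$noise_sigma,
                noise_mode = params$noise_mode,
                refractory_scale = params$refractory_scale)

  out <- run_network_cpp(state$weights, class_codes(params), state$eta,
                         state$V, cpars, unclass(stdp), plasticity, epochs,
                         targets, duration, state$mask, rec)

  raster <- data.frame(time = out$raster[, 1], neuron = as.integer(out$raster[, 2]))
  new_state <- state
  new_state$weights <- out$weights
  new_state$V <- out$V

  stats <- NULL
  if (record$stats_dt > 0) {
    stats <- as.data.frame(out$stats)
    names(stats) <- c("time_s", stats_column_names())
  }
  K <- if (record$k_dt > 0)
    data.frame(time_s = out$k_times, K = out$k_values) else NULL
  drives <- NULL
  if (length(record$drive_neurons) > 0 && record$drive_dt > 0) {
    drives <- as.data.frame(out$drives)
    names(drives) <- c("time_s", as.vector(t(outer(
      record$drive_neurons, c("Se", "Shi", "Sai"),
      function(n, s) paste0(s, "_", n)))))
  }

  structure(list(raster = raster, weights = out$weights, state = new_state,
                 snapshots = out$snapshots,
                 snapshot_times = out$snapshot_times, K = K, stats = stats,
                 drives = drives, duration = duration, params = params,
                 stdp = stdp, protocol = protocol,
                 last_spike = out$last_spike),
            class = "qif_sim")
}

stats_column_names <- function() {
  pre <- c("E", "H", "A")
  cols <- character(0)
  for (q in pre)
    for (post in c("E", "I"))
      for (scope in c("intra", "inter"))
        cols <- c(cols, paste0(q, post, "_", scope))
  cols
}

#' @export
print.qif_sim <- function(x, ...) {
  cat(sprintf("QIF simulation: %.3g s, N = %d, %d spikes (%.2f Hz/neuron)\n",
              x$duration, x$params$N, nrow(x$raster),
              nrow(x$raster) / x$params$N / x$duration))
  invisible(x)
}
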