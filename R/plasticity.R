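#' STDP kernel for excitatory synapses (asymmetric Hebbian)
#'
#' Plasticity value as a function of the spike-timing difference
#' `dt = t_post - t_pre`. Causal pairs (`dt > 0`) are potentiated and
#' anti-causal pairs depressed:
#' \deqn{\Lambda_e(\Delta t) = A_+ e^{-\Delta t/\tau_+} -
#'       A_- e^{-4\Delta t/\tau_+} - f \quad (\Delta t \ge 0)}
#' \deqn{\Lambda_e(\Delta t) = A_+ e^{4\Delta t/\tau_-} -
#'       A_- e^{\Delta t/\tau_-} - f \quad (\Delta t < 0)}
#' The constant `f` is a forgetting offset: for widely separated spikes
#' the kernel tends to `-f`, giving a slow depression of unused synapses.
#' The function is continuous at `dt = 0`.
#'
#' @param dt_diff spike-timing difference(s) in seconds, `t_post - t_pre`.
#' @param params kernel parameter list (element `e` of [stdp_params()]).
#' @return plasticity value(s), same length as `dt_diff`.
#' @examples
#' lambda_e(0)          # A_plus - A_minus - f = 2.247
#' lambda_e(c(-1, 1))   # both close to -f
#' @export
lambda_e <- function(dt_diff, params = stdp_params()$e) {
  pos <- dt_diff >= 0
  out <- numeric(length(dt_diff))
  out[pos] <- params$A_plus * exp(-dt_diff[pos] / params$tau_plus) -
    params$A_minus * exp(-4 * dt_diff[pos] / params$tau_plus)
  out[!pos] <- params$A_plus * exp(4 * dt_diff[!pos] / params$tau_minus) -
    params$A_minus * exp(dt_diff[!pos] / params$tau_minus)
  out - params$f
}

#' STDP kernel for Hebbian inhibitory synapses (symmetric, Ricker wavelet)
#'
#' Even function of the spike-timing difference:
#' \deqn{\Lambda_{hi}(\Delta t) = A\left[1 - (\Delta t/\tau)^2\right]
#'       e^{-\Delta t^2 / 2\tau^2} - f}
#' Near-coincident spikes potentiate (regardless of order), spikes
#' separated by more than `tau` depress.
#'
#' @inheritParams lambda_e
#' @param params kernel parameter list (element `hi` of [stdp_params()]).
#' @examples
#' lambda_hi(0)    # A - f = 2.9
#' lambda_hi(0.1)  # -f: the bracket vanishes at |dt| = tau
#' @export
lambda_hi <- function(dt_diff, params = stdp_params()$hi) {
  x <- dt_diff / params$tau
  params$A * (1 - x^2) * exp(-x^2 / 2) - params$f
}

#' STDP kernel for anti-Hebbian inhibitory synapses (reverse Ricker wavelet)
#'
#' The sign-reversed counterpart of [lambda_hi()]:
#' \deqn{\Lambda_{ai}(\Delta t) = -A\left[1 - (\Delta t/\tau)^2\right]
#'       e^{-\Delta t^2 / 2\tau^2} + f}
#' Coincident spikes depress while uncorrelated firing gives a small
#' constant potentiation `+f` (the rule being anti-Hebbian).
#'
#' @inheritParams lambda_e
#' @param params kernel parameter list (element `ai` of [stdp_params()]).
#' @export
lambda_ai <- function(dt_diff, params = stdp_params()$ai) {
  x <- dt_diff / params$tau
  -params$A * (1 - x^2) * exp(-x^2 / 2) + params$f
}

#' Split a plasticity value into potentiation and depression parts
#'
#' @param value plasticity kernel value(s).
#' @return a list with elements `potentiation` (`max(value, 0)`) and
#'   `depression` (`min(value, 0)`).
#' @export
split_plasticity <- function(value) {
  list(potentiation = pmax(value, 0), depression = pmin(value, 0))
}

#' Soft-bounded STDP weight update
#'
#' Applies one pairwise weight update for a spike-timing difference
#' `dt = t_post - t_pre`:
#' \deqn{w' = w + \gamma_l \Delta w, \qquad
#'   \Delta w = (-1)^{a_q}\left[\tanh(\lambda(w_l - w))\,\Lambda^{x(q)} +
#'   \tanh(\lambda(w + w_u))\,\Lambda^{y(q)}\right]}
#' For excitatory synapses (`w` in `[0,1]`) the potentiation part is
#' gated by `tanh(lambda*(1 - w))` and the depression part by
#' `tanh(lambda*w)`, so the bounds 1 and 0 saturate smoothly. For
#' inhibitory synapses (`w` in `[-1,0]`) the roles of the potentiation and
#' depression kernels are exchanged and the sign flipped, so potentiation
#' drives `w` towards -1 and depression towards 0. A safety clamp absorbs
#' floating-point overshoot of the tanh bound.
#'
#' @param w current weight(s), inside the class bounds.
#' @param dt_diff spike-timing difference(s), `t_post - t_pre` (s).
#' @param class synapse class of the pre-synaptic neuron: `"e"`, `"hi"` or
#'   `"ai"`.
#' @param stdp an [stdp_params()] object.
#' @return updated weight(s).
#' @examples
#' weight_update(0.5, -0.05, "e")  # depression: ~0.49456
#' weight_update(1, 0.005, "e")    # saturated at the upper bound
#' @export
weight_update <- function(w, dt_diff, class = c("e", "hi", "ai"),
                          stdp = stdp_params()) {
  class <- match.arg(class)
  kern <- switch(class, e = lambda_e(dt_diff, stdp$e),
                 hi = lambda_hi(dt_diff, stdp$hi),
                 ai = lambda_ai(dt_diff, stdp$ai))
  if (class == "e") {
    if (any(w < 0 | w > 1)) stop("excitatory weights must lie in [0, 1]")
  } else if (any(w < -1 | w > 0)) {
    stop("inhibitory weights must lie in [-1, 0]")
  }
  parts <- split_plasticity(kern)
  dw <- if (class == "e") {
    tanh(stdp$lambda * (1 - w)) * parts$potentiation +
      tanh(stdp$lambda * w) * parts$depression
  } else {
    -(tanh(stdp$lambda * (0 - w)) * parts$depression +
        tanh(stdp$lambda * (w + 1)) * parts$potentiation)
  }
  out <- w + stdp$gamma_l * dw
  if (class == "e") pmin(pmax(out, 0), 1) else pmin(pmax(out, -1), 0)
}

#' Apply on-spike plasticity for a set of spiking neurons
#'
#' Reference (pure R) implementation of the event-driven weight update
#' used inside the simulator: when a neuron spikes, every incident synapse
#' whose partner has fired at least once is updated once using last-spike
#' pairing, with the just-fired neuron's spike time set to `t`. Synapses
#' whose partner has never spiked are skipped (no defined timing
#' difference). Spiking neurons are processed in order of their spike
#' times, so coincident spikes within a volley pair with the in-volley
#' times of earlier-processed partners.
#'
#' @param ledger numeric vector of last spike times per neuron (`NA` =
#'   never fired).
#' @param weights `N x N` weight matrix, entry `[i, j]` = synapse from
#'   pre-synaptic `j` to post-synaptic `i`.
#' @param class_of character vector of per-neuron synapse classes
#'   (`"e"`, `"hi"`, `"ai"`).
#' @param spiking_neurons indices of neurons spiking now.
#' @param t spike time(s): a scalar, or one corrected time per spiking
#'   neuron.
#' @param stdp an [stdp_params()] object.
#' @param mask optional logical connectivity matrix; masked-out synapses
#'   are never updated.
#' @return a list with the updated `weights` and `ledger`.
#' @export
on_spike_plasticity <- function(ledger, weights, class_of, spiking_neurons,
                                t, stdp = stdp_params(), mask = NULL) {
  if (length(t) == 1L) t <- rep(t, length(spiking_neurons))
  ord <- order(t, spiking_neurons)
  for (k in ord) {
    s <- spiking_neurons[k]
    ts <- t[k]
    partners <- which(!is.na(ledger))
    partners <- partners[partners != s]
    for (p in partners) {
      tp <- ledger[p]
      if (is.null(mask) || mask[s, p]) {
        weights[s, p] <- weight_update(weights[s, p], ts - tp, class_of[p],
                                       stdp)
      }
      if (is.null(mask) || mask[p, s]) {
        weights[p, s] <- weight_update(weights[p, s], tp - ts, class_of[s],
                                       stdp)
      }
    }
    ledger[s] <- ts
  }
  list(weights = weights, ledger = ledger)
}
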