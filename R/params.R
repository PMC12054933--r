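#' Network parameters for the QIF simulation
#'
#' Builds the full parameter set of the spiking network: population
#' composition, membrane and synaptic time constants, coupling strengths,
#' threshold/reset values, integration step, excitability and noise scales,
#' and the stimulation current amplitude. Defaults are the reference
#' parameter table of the model: a network of `N = 100` neurons with 80
#' excitatory, 10 Hebbian-inhibitory and 10 anti-Hebbian-inhibitory
#' neurons, `tau_m = 20` ms, synaptic decays of 2 ms (excitatory) and 5 ms
#' (inhibitory), couplings `ge = 100`, `ghi = 200`, `gai = 400`, threshold
#' `Vp = 10`, reset `Vr = -10` and `dt = 1` ms.
#'
#' Excitabilities are drawn as `eta ~ N(0, (pi*tau0)^2)` (standard
#' deviation `pi*tau0`), which places the spontaneous rates of the
#' oscillatory neurons in the 0--8 Hz range with a mean around 1 Hz.
#' The per-step noise has standard deviation `4*pi*tau0` and the
#' stimulation DC current is `(50*pi*tau0)^2`, driving stimulated neurons
#' to fire near 50 Hz.
#'
#' @param N total number of neurons.
#' @param n_exc,n_hebb,n_anti numbers of excitatory, Hebbian-inhibitory and
#'   anti-Hebbian-inhibitory neurons; must sum to `N`. Neuron indices are
#'   assigned in that order (excitatory first).
#' @param tau_m membrane time constant (s).
#' @param tau0 dimensionless excitability scale (0.02).
#' @param tau_de,tau_di synaptic decay times (s) for excitatory and
#'   inhibitory drives.
#' @param ge,ghi,gai global coupling strengths for the three synapse
#'   classes.
#' @param Vp,Vr spike threshold and reset potentials.
#' @param dt Euler integration step (s).
#' @param eta_sd standard deviation of the excitability distribution.
#' @param noise_sigma standard deviation of the per-step noise term.
#' @param stim_amplitude DC current applied to stimulated neurons.
#' @param connectivity `NULL` for all-to-all coupling (no autapses), or a
#'   probability in (0,1] for a directed Erdos--Renyi connection mask.
#' @param noise_mode discretisation of the noise term `xi(t)`. `"pc"`
#'   (default) holds each draw `N(0, noise_sigma^2)` piecewise-constant
#'   over one membrane time constant, so the noise fluctuates on the
#'   timescale the membrane can follow; this reproduces the stated
#'   resting statistics (mean ~1 Hz, a few-Hz firing variability) while
#'   letting trained networks exhibit spontaneous recalls. `"step"`
#'   redraws every Euler step and applies the draw like the deterministic
#'   terms (much weaker effective noise); `"em"` treats `xi` as white
#'   noise of intensity `noise_sigma^2` with Euler--Maruyama `sqrt(dt)`
#'   scaling (much stronger; all neurons become noise-driven). See the
#'   package vignette for the calibration comparison.
#' @param refractory_scale the post-spike hold at `Vr` lasts
#'   `refractory_scale * tau_m / V_cross` seconds, where `V_cross` is the
#'   membrane value at threshold crossing. The default 2 accounts for the
#'   time to reach infinity from `Vp` plus the return from minus infinity
#'   to `Vr`.
#' @return an object of class `qif_params` (a validated list).
#' @examples
#' p <- network_params()
#' p$N
#' @export
network_params <- function(N = 100L, n_exc = 80L, n_hebb = 10L, n_anti = 10L,
                           tau_m = 0.02, tau0 = 0.02, tau_de = 0.002,
                           tau_di = 0.005, ge = 100, ghi = 200, gai = 400,
                           Vp = 10, Vr = -10, dt = 0.001,
                           eta_sd = pi * tau0,
                           noise_sigma = 4 * pi * tau0,
                           stim_amplitude = (50 * pi * tau0)^2,
                           connectivity = NULL,
                           noise_mode = c("pc", "step", "em"),
                           refractory_scale = 2) {
  noise_mode <- match.arg(noise_mode)
  N <- as.integer(N); n_exc <- as.integer(n_exc)
  n_hebb <- as.integer(n_hebb); n_anti <- as.integer(n_anti)
  if (any(c(N, n_exc, n_hebb, n_anti) < 0L))
    stop("population counts must be non-negative")
  if (n_exc + n_hebb + n_anti != N)
    stop("n_exc + n_hebb + n_anti must equal N (got ",
         n_exc + n_hebb + n_anti, " != ", N, ")")
  if (any(c(tau_m, tau_de, tau_di, dt) <= 0))
    stop("all time constants and dt must be positive")
  if (!(Vp > 0 && Vr < 0)) stop("need Vp > 0 > Vr")
  if (!is.null(connectivity) &&
      (!is.numeric(connectivity) || connectivity <= 0 || connectivity > 1))
    stop("connectivity must be NULL or a probability in (0, 1]")
  structure(list(N = N, n_exc = n_exc, n_hebb = n_hebb, n_anti = n_anti,
                 tau_m = tau_m, tau0 = tau0, tau_de = tau_de, tau_di = tau_di,
                 ge = ge, ghi = ghi, gai = gai, Vp = Vp, Vr = Vr, dt = dt,
                 eta_sd = eta_sd, noise_sigma = noise_sigma,
                 stim_amplitude = stim_amplitude, connectivity = connectivity,
                 noise_mode = noise_mode,
                 refractory_scale = refractory_scale),
            class = "qif_params")
}

#' Per-neuron synapse classes
#'
#' Synapse class is determined by the pre-synaptic neuron: `"e"`
#' (excitatory, indices `1:n_exc`), `"hi"` (Hebbian inhibitory) or `"ai"`
#' (anti-Hebbian inhibitory).
#'
#' @param params a [network_params()] object.
#' @return a character vector of length `N` with values `"e"`, `"hi"`,
#'   `"ai"`.
#' @export
neuron_classes <- function(params) {
  rep(c("e", "hi", "ai"), times = c(params$n_exc, params$n_hebb, params$n_anti))
}

class_codes <- function(params) {
  rep(0:2, times = c(params$n_exc, params$n_hebb, params$n_anti))
}

#' STDP parameter sets for the three plasticity rules
#'
#' Returns the parameters of the three spike-timing-dependent plasticity
#' kernels and of the soft-bounded weight update. Excitatory synapses
#' follow an asymmetric Hebbian kernel with amplitudes `A_plus = 5.296`,
#' `A_minus = 2.949` and time constants `tau_plus = 20` ms,
#' `tau_minus = 50` ms. Inhibitory synapses follow Ricker-wavelet
#' ("Mexican hat") kernels of amplitude `A = 3` and width `tau = 100` ms:
#' Hebbian (near-coincident spikes potentiate) or anti-Hebbian (sign
#' reversed). All three kernels carry a constant forgetting offset
#' `f = f0 / M` with `f0 = 0.2`, so that `M = 2` stored memories give the
#' reference value `f = 0.1`. The weight update uses learning rate
#' `gamma_l = 0.005` and tanh soft bounds of slope `lambda = 100`.
#'
#' @param M number of stored memories, used to scale the forgetting term.
#' @param f0 forgetting scale; `f = f0 / M`.
#' @param f optional explicit forgetting term overriding `f0 / M` (applied
#'   to all three kernels).
#' @param gamma_l learning rate.
#' @param lambda slope of the tanh soft-bound functions.
#' @return an object of class `stdp_params`: a list with elements `e`,
#'   `hi`, `ai` (kernel parameters, each with its own `f`), `gamma_l` and
#'   `lambda`.
#' @examples
#' s <- stdp_params(M = 2)
#' s$e$f # 0.1
#' @export
stdp_params <- function(M = 2, f0 = 0.2, f = NULL, gamma_l = 0.005,
                        lambda = 100) {
  if (M <= 0) stop("M must be positive")
  fv <- if (is.null(f)) f0 / M else f
  if (fv < 0) stop("forgetting term must be non-negative")
  if (gamma_l < 0) stop("gamma_l must be non-negative")
  structure(list(
    e = list(A_plus = 5.296, A_minus = 2.949, tau_plus = 0.02,
             tau_minus = 0.05, f = fv),
    hi = list(A = 3, tau = 0.1, f = fv),
    ai = list(A = 3, tau = 0.1, f = fv),
    gamma_l = gamma_l, lambda = lambda), class = "stdp_params")
}

#' @export
print.qif_params <- function(x, ...) {
  cat("QIF network parameters\n")
  cat(sprintf("  N = %d (E %d | Hebbian-I %d | anti-Hebbian-I %d)\n",
              x$N, x$n_exc, x$n_hebb, x$n_anti))
  cat(sprintf("  tau_m %.3g s, dt %.3g s, ge %.3g, ghi %.3g, gai %.3g\n",
              x$tau_m, x$dt, x$ge, x$ghi, x$gai))
  cat(sprintf("  Vp %.3g, Vr %.3g, eta_sd %.4g, noise %.4g (%s), stim %.4g\n",
              x$Vp, x$Vr, x$eta_sd, x$noise_sigma, x$noise_mode,
              x$stim_amplitude))
  cat(sprintf("  connectivity: %s\n",
              if (is.null(x$connectivity)) "all-to-all"
              else sprintf("Erdos-Renyi p = %.3g", x$connectivity)))
  invisible(x)
}
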