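#' Membrane parameters for a neuron class
#'
#' Fixed leaky integrate-and-fire presets for the two cell classes of the
#' circuit. Excitatory (pyramidal) cells: C_m = 0.5 nF, g_L = 25 nS,
#' tau_ref = 2 ms; inhibitory interneurons: C_m = 0.2 nF, g_L = 20 nS,
#' tau_ref = 1 ms. Both share V_L = -70 mV, V_th = -50 mV, V_reset = -55 mV.
#'
#' @param class `"excitatory"` or `"inhibitory"`.
#' @return Named list with fields `C_m` (nF), `g_L` (nS), `V_L`, `V_th`,
#'   `V_reset` (mV) and `tau_ref` (ms).
#' @export
neuron_params <- function(class = c("excitatory", "inhibitory")) {
  class <- match.arg(class)
  if (class == "excitatory") {
    list(C_m = 0.5, g_L = 25, V_L = -70, V_th = -50, V_reset = -55, tau_ref = 2)
  } else {
    list(C_m = 0.2, g_L = 20, V_L = -70, V_th = -50, V_reset = -55, tau_ref = 1)
  }
}

#' Synaptic parameters onto a postsynaptic cell class
#'
#' Conductances and kinetic constants of the four synaptic channels
#' (external AMPA, recurrent AMPA, NMDA, GABA). Onto excitatory cells:
#' g_ext_AMPA = 2.1, g_rec_AMPA = 0.05, g_NMDA = 0.165, g_GABA = 1.3 nS;
#' onto inhibitory cells: 1.62, 0.04, 0.13, 1.0 nS. Time constants
#' tau_AMPA = 2 ms, tau_NMDA_decay = 100 ms, tau_NMDA_rise = 2 ms,
#' tau_GABA = 5 ms; NMDA rise coupling alpha = 0.5 /ms; magnesium
#' concentration 1 mM; reversals V_E = 0 mV, V_I = -70 mV.
#'
#' @param target `"excitatory"` or `"inhibitory"` postsynaptic class.
#' @return Named list of synaptic constants.
#' @export
synapse_params <- function(target = c("excitatory", "inhibitory")) {
  target <- match.arg(target)
  g <- if (target == "excitatory") {
    c(g_ext_AMPA = 2.1, g_rec_AMPA = 0.05, g_NMDA = 0.165, g_GABA = 1.3)
  } else {
    c(g_ext_AMPA = 1.62, g_rec_AMPA = 0.04, g_NMDA = 0.13, g_GABA = 1.0)
  }
  c(as.list(g),
    list(tau_AMPA = 2, tau_NMDA_decay = 100, tau_NMDA_rise = 2, tau_GABA = 5,
         alpha = 0.5, Mg = 1, V_E = 0, V_I = -70))
}

#' Depressed synaptic weight compensating a potentiated one
#'
#' Within each selective population the recurrent weight is potentiated to
#' `w_plus` >= 1; the weight between the selective populations and from the
#' non-selective population onto them is depressed to
#' `w_minus = 1 - f (w_plus - 1) / (1 - f)` so that the total recurrent
#' excitatory drive a selective neuron receives in the spontaneous state,
#' `f w_plus + (1 - f) w_minus = 1`, does not change with `w_plus`.
#'
#' @param w_plus Potentiated weight (dimensionless, >= 1).
#' @param f Fraction of excitatory neurons in each selective population
#'   (0 < f < 0.5).
#' @return The depressed weight `w_minus` (<= 1).
#' @export
#' @examples
#' derive_w_minus(1.61, 0.15)
derive_w_minus <- function(w_plus, f = 0.15) {
  stopifnot(is.numeric(w_plus), is.numeric(f), f > 0, f < 0.5)
  if (any(w_plus < 1))
    stop("w_plus must be >= 1: the depression formula holds only in the potentiated regime")
  1 - f * (w_plus - 1) / (1 - f)
}
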