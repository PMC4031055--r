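#' Integrate-and-fire neuron and gamma-cycle parameters
#'
#' Electrophysiological constants shared by DG granule cells and CA3 pyramidal
#' cells, plus the timing of the competitive gamma cycle. Defaults follow
#' published slice measurements: 33 MOhm input resistance, 30 ms membrane time
#' constant, -50 mV firing threshold, reset to a -65 mV resting potential, a
#' -2 nA after-hyperpolarization decaying with a 7 ms time constant, and a 2 ms
#' absolute refractory period. Global feedback inhibition arrives 3.3 +/- 0.4 ms
#' after the first spike of the cycle; recurrent EPSCs are 3 ms steps released
#' with a 1 ms lag. The feedforward gain of 0.68 nA sets the network oscillation
#' near gamma (~35 Hz). Each cycle lasts 36.5 ms and is simulated with 1 ms
#' Euler steps up to the first spike and 0.1 ms steps from there to the release
#' of GABA.
#'
#' @param r_n Input resistance (MOhm).
#' @param tau_n Membrane time constant (ms).
#' @param v_thresh Firing threshold (mV).
#' @param v_rest Resting / reset potential (mV).
#' @param a_ahp After-hyperpolarization peak current (nA, negative).
#' @param tau_ahp AHP decay time constant (ms).
#' @param tau_spike Absolute refractory period (ms).
#' @param g_ff Feedforward gain (nA per unit of normalized input).
#' @param gamma_t Gamma-cycle duration (ms).
#' @param inh_delay_mean,inh_delay_sd Mean and SD (ms) of the normally
#'   distributed delay between the first spike and global inhibition onset
#'   (truncated at zero).
#' @param rec_lag Release lag of recurrent EPSCs (ms).
#' @param epsc_dur Duration of the recurrent EPSC step (ms).
#' @param dt_coarse,dt_fine Euler step sizes (ms) before the first spike and
#'   within the active window.
#' @return A `neuron_params` list.
#' @export
#' @examples
#' p <- neuron_params()
#' p$g_ff
neuron_params <- function(r_n = 33, tau_n = 30, v_thresh = -50, v_rest = -65,
                          a_ahp = -2, tau_ahp = 7, tau_spike = 2, g_ff = 0.68,
                          gamma_t = 36.5, inh_delay_mean = 3.3,
                          inh_delay_sd = 0.4, rec_lag = 1, epsc_dur = 3,
                          dt_coarse = 1, dt_fine = 0.1) {
  stopifnot(tau_n > 0, tau_ahp > 0, tau_spike > 0, gamma_t > 0,
            dt_coarse > 0, dt_fine > 0, v_thresh > v_rest, r_n > 0)
  structure(list(
    r_n = r_n, tau_n = tau_n, v_thresh = v_thresh, v_rest = v_rest,
    a_ahp = a_ahp, tau_ahp = tau_ahp, tau_spike = tau_spike, g_ff = g_ff,
    gamma_t = gamma_t, inh_delay_mean = inh_delay_mean,
    inh_delay_sd = inh_delay_sd, rec_lag = rec_lag, epsc_dur = epsc_dur,
    dt_coarse = dt_coarse, dt_fine = dt_fine
  ), class = "neuron_params")
}

#' Recurrent-collateral parameters for CA3
#'
#' Bundles the CA3 recurrent weight matrix with the recall machinery: a cell
#' whose summed recurrent drive (weighted EPSC states of its presynaptic
#' partners, self-connection excluded) exceeds `delta` times its total incoming
#' weight receives the saturating feedback current `i_rec_max`. The recall
#' threshold quoted for the best model fit is `1 - delta` = 95%, i.e.
#' `delta = 0.05`.
#'
#' @param w Square nonnegative recurrent weight matrix (cells x cells), e.g.
#'   the `w` field of a memory built with [build_memory()].
#' @param delta Recurrent excitation threshold parameter in `[0, 1]`;
#'   `delta = 1` makes the threshold unreachable (recurrence effectively off).
#' @param i_rec_max Asymptotic feedback excitatory current (nA).
#' @return A `recurrent_params` list with precomputed incoming-weight sums.
#' @export
recurrent_params <- function(w, delta = 0.05, i_rec_max = 20) {
  if (delta < 0 || delta > 1) {
    abort("`delta` must lie in [0, 1].", class = "hippomorph_argument_error")
  }
  w <- as(w, "CsparseMatrix")
  if (nrow(w) != ncol(w) || any(w@x < 0)) {
    abort("`w` must be a square nonnegative matrix.",
          class = "hippomorph_argument_error")
  }
  structure(list(
    w = w, delta = delta, i_rec_max = i_rec_max,
    incoming = Matrix::rowSums(w)
  ), class = "recurrent_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  R_n %g MOhm, tau_n %g ms, threshold %g mV, rest %g mV\n",
              x$r_n, x$tau_n, x$v_thresh, x$v_rest))
  cat(sprintf("  g_FF %g nA, gamma cycle %g ms, GABA delay %g +/- %g ms\n",
              x$g_ff, x$gamma_t, x$inh_delay_mean, x$inh_delay_sd))
  invisible(x)
}

#' @export
print.recurrent_params <- function(x, ...) {
  cat(sprintf("<recurrent_params> %d cells, delta = %g (recall threshold %g%%), I_max = %g nA\n",
              nrow(x$w), x$delta, 100 * (1 - x$delta), x$i_rec_max))
  invisible(x)
}

# Sample truncated-normal inhibition delays (>= 0).
sample_inh_delay <- function(n, params) {
  d <- rnorm(n, params$inh_delay_mean, params$inh_delay_sd)
  pmax(d, 0)
}
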