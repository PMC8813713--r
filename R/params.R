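#' Fixed network parameters of the cortical column
#'
#' Returns the full registry of fixed (non-drive) parameters of the two-layer
#' cortical-column model: reduced pyramidal and basket-cell morphologies,
#' Hodgkin-Huxley-style channel densities, synaptic kinetics, the local
#' connectivity table and global biophysical constants.  Values follow the
#' conventions of the canonical neocortical-column model distributed with the
#' HNN software (reduced Bush-Sejnowski-style pyramidal morphologies, strong
#' slow-potassium conductances, double-exponential synapses); every value can
#' be overridden through [networkConfig()].
#'
#' Geometry is in micrometres, specific capacitance in uF/cm^2, axial
#' resistivity in ohm cm, channel densities in S/cm^2, synaptic conductances
#' in uS, times in ms.
#'
#' @return A nested list with elements `cells`, `synapses`, `connectivity`,
#'   `drive_targets` and `constants`.
#' @export
defaultNetworkParams <- function() {
  list(
    cells = list(
      L2Pyr = list(
        cm = 0.6195, Ra = 200,
        sections = data.frame(
          name   = c("soma", "apical_trunk", "apical_1", "apical_tuft",
                     "apical_oblique", "basal_1", "basal_2", "basal_3"),
          L      = c(22.1, 59.5, 306, 238, 340, 85, 255, 255),
          diam   = c(23.4, 4.25, 4.08, 3.4, 3.91, 4.25, 2.72, 2.72),
          parent = c(NA, "soma", "apical_trunk", "apical_1",
                     "apical_trunk", "soma", "basal_1", "basal_1"),
          attach = c(NA, "end", "end", "end", "end", "start", "end", "end"),
          orient = c(1, 1, 1, 1, 0, -1, -sqrt(0.5), -sqrt(0.5)),
          stringsAsFactors = FALSE
        ),
        channels = list(
          soma = c(na = 0.18, kdr = 0.01, km = 5e-3, leak = 4.26e-5),
          dend = c(na = 0.15, kdr = 0.01, km = 1e-4, leak = 4.26e-5)
        ),
        el = -65
      ),
      L5Pyr = list(
        cm = 0.85, Ra = 200,
        sections = data.frame(
          name   = c("soma", "apical_trunk", "apical_1", "apical_2",
                     "apical_tuft", "apical_oblique", "basal_1", "basal_2",
                     "basal_3"),
          L      = c(39, 102, 680, 680, 425, 255, 85, 255, 255),
          diam   = c(28.9, 10.2, 7.48, 4.93, 3.4, 5.1, 6.8, 8.5, 8.5),
          parent = c(NA, "soma", "apical_trunk", "apical_1", "apical_2",
                     "apical_trunk", "soma", "basal_1", "basal_1"),
          attach = c(NA, "end", "end", "end", "end", "end", "start", "end",
                     "end"),
          orient = c(1, 1, 1, 1, 1, 0, -1, -sqrt(0.5), -sqrt(0.5)),
          stringsAsFactors = FALSE
        ),
        channels = list(
          soma = c(na = 0.16, kdr = 0.01, km = 2e-3, ca = 6e-3, kca = 1e-3,
                   cat = 2e-4, ar = 1e-6, leak = 4.26e-5),
          dend = c(na = 0.14, kdr = 0.01, km = 1e-4, ca = 6e-3, kca = 1e-3,
                   cat = 2e-4, ar = 1e-6, leak = 4.26e-5)
        ),
        el = -71,
        # h-current density grows exponentially with distance from the soma
        ar_gradient = 3e-3
      ),
      L2Basket = list(
        cm = 0.85, Ra = 200,
        sections = data.frame(
          name = "soma", L = 39, diam = 20, parent = NA, attach = NA,
          orient = 1, stringsAsFactors = FALSE
        ),
        channels = list(soma = c(na = 0.10, kdr = 0.08, km = 8e-3,
                                 leak = 1e-4)),
        el = -65
      ),
      L5Basket = list(
        cm = 0.85, Ra = 200,
        sections = data.frame(
          name = "soma", L = 39, diam = 20, parent = NA, attach = NA,
          orient = 1, stringsAsFactors = FALSE
        ),
        channels = list(soma = c(na = 0.10, kdr = 0.08, km = 7.5e-3,
                                 leak = 1e-4)),
        el = -65
      )
    ),
    # double-exponential synapse kinetics per postsynaptic cell type
    synapses = list(
      tau1 = c(ampa = 0.5, nmda = 1, gabaa = 0.5, gabab = 1),
      tau2 = c(ampa = 5, nmda = 20, gabaa = 5, gabab = 20),
      e    = c(ampa = 0, nmda = 0, gabaa = -80, gabab = -80),
      # per-cell-type kinetic deviations (slow inhibitory tail that holds
      # superficial pyramids in check between the distal and late proximal
      # drives)
      tau2_overrides = list(L2Pyr = c(gabab = 27))
    ),
    # local connectivity: weight in uS per synapse, lamtha in grid units,
    # delay in ms at zero distance
    connectivity = data.frame(
      pre   = c("L2Pyr", "L2Pyr", "L2Pyr", "L2Basket", "L2Basket", "L2Basket",
                "L2Pyr", "L2Pyr", "L2Basket", "L5Pyr", "L5Pyr", "L5Pyr",
                "L5Basket", "L5Basket", "L5Basket"),
      post  = c("L2Pyr", "L2Pyr", "L2Basket", "L2Pyr", "L2Pyr", "L2Basket",
                "L5Pyr", "L5Basket", "L5Pyr", "L5Pyr", "L5Pyr", "L5Basket",
                "L5Pyr", "L5Pyr", "L5Basket"),
      receptor = c("ampa", "nmda", "ampa", "gabaa", "gabab", "gabaa",
                   "ampa", "ampa", "gabaa", "ampa", "nmda", "ampa",
                   "gabaa", "gabab", "gabaa"),
      weight = c(5e-4, 5e-4, 5e-4, 5e-2, 5e-2, 2e-2,
                 2.5e-4, 2.5e-4, 1e-3, 5e-4, 5e-4, 5e-4,
                 2.5e-2, 1e-2, 2e-2),
      loc   = c("proximal", "proximal", "soma", "soma", "soma", "soma",
                "proximal", "soma", "distal", "proximal", "proximal", "soma",
                "soma", "soma", "soma"),
      lamtha = c(3, 3, 3, 50, 50, 20, 3, 3, 50, 3, 3, 3, 70, 70, 20),
      # inhibitory events reach their targets with a slower effective delay
      # than excitatory ones (di-synaptic relay and GABA release kinetics)
      delay = c(1, 1, 1, 3, 3, 3, 1, 1, 3, 1, 1, 1, 3, 3, 3),
      stringsAsFactors = FALSE
    ),
    drive_targets = list(
      proximal = list(
        populations = c("L2Pyr", "L5Pyr", "L2Basket", "L5Basket"),
        sections = list(
          L2Pyr = c("basal_2", "basal_3", "apical_oblique"),
          L5Pyr = c("basal_2", "basal_3", "apical_oblique"),
          L2Basket = "soma", L5Basket = "soma"
        ),
        # relay through the granular layer: small extra delay to layer V
        delay = c(L2Pyr = 0.1, L5Pyr = 1, L2Basket = 0.1, L5Basket = 1)
      ),
      distal = list(
        populations = c("L2Pyr", "L5Pyr", "L2Basket"),
        sections = list(
          L2Pyr = "apical_tuft", L5Pyr = "apical_tuft", L2Basket = "soma"
        ),
        delay = c(L2Pyr = 0.1, L5Pyr = 0.1, L2Basket = 0.1)
      )
    ),
    constants = list(
      ena = 50, ek = -77, e_h = -35, vtraub = -55, celsius = 37,
      mg = 1, cao = 2, cainf = 1e-4, taur_cad = 20,
      spike_threshold = 0
    )
  )
}

# population bookkeeping used across the package
POPULATIONS <- c("L2Pyr", "L2Basket", "L5Pyr", "L5Basket")
RECEPTORS <- c("ampa", "nmda", "gabaa", "gabab")
BASKET_POPS <- c("L2Basket", "L5Basket")
PYR_POPS <- c("L2Pyr", "L5Pyr")
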