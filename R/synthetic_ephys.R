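#' Forward-simulate dilution and bi-ionic potential records
#'
#' Generates a synthetic Ussing-style record by running the
#' Goldman-Hodgkin-Katz equation forward at 37 C with known ground-truth
#' permeabilities, adding Gaussian measurement noise to the potentials. The
#' ground truth travels with the record so downstream inversion can be
#' checked exactly.
#'
#' @param true_p_na,true_p_cl,true_p_li Ground-truth permeabilities in cm/s
#'   (> 0).
#' @param teer Corrected TEER of the simulated monolayer, Ohm cm^2.
#' @param noise_sd Gaussian noise SD on the potentials, mV.
#' @param seed Integer seed.
#' @param n_sweeps Replicate potential readings per protocol.
#' @param apical,basal_dilution,basal_biionic Bath compositions; defaults are
#'   the 140 mM NaCl Ringer, the 1:4 saline:mannitol dilution (28 mM NaCl)
#'   and the 140 mM LiCl replacement.
#' @param temperature Temperature in K.
#' @return Tibble with columns `protocol` (`"dilution"`/`"biionic"`),
#'   `sweep`, `v_mv`, `teer`; attributes `truth` (list with the generating
#'   permeabilities and ratios) and the bath compositions.
#' @export
make_ephys_record <- function(true_p_na, true_p_cl, true_p_li,
                              teer = 224, noise_sd = 0.5, seed = 1,
                              n_sweeps = 3,
                              apical = bath(na = 140, cl = 140),
                              basal_dilution = bath(na = 28, cl = 28),
                              basal_biionic = bath(li = 140, cl = 140),
                              temperature = 310.15) {
  if (any(c(true_p_na, true_p_cl, true_p_li) <= 0)) {
    abort("ground-truth permeabilities must be positive")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  v_dil <- ghk_potential(true_p_na, true_p_cl, apical, basal_dilution,
    p_li = 0, temperature = temperature
  )
  v_bi <- ghk_potential(true_p_na, true_p_cl, apical, basal_biionic,
    p_li = true_p_li, temperature = temperature
  )
  rec <- with_private_seed(seed, {
    tibble(
      protocol = rep(c("dilution", "biionic"), each = n_sweeps),
      sweep = rep(seq_len(n_sweeps), 2),
      v_mv = c(
        v_dil + rnorm(n_sweeps, sd = noise_sd),
        v_bi + rnorm(n_sweeps, sd = noise_sd)
      ),
      teer = teer
    )
  })
  structure(
    rec,
    truth = list(
      p_na = true_p_na, p_cl = true_p_cl, p_li = true_p_li,
      beta = true_p_na / true_p_cl, li_na = true_p_li / true_p_na,
      v_dilution = v_dil, v_biionic = v_bi
    ),
    apical = apical, basal_dilution = basal_dilution,
    basal_biionic = basal_biionic, temperature = temperature,
    class = c("ephys_record", class(rec))
  )
}

#' Invert a (synthetic or measured) ephys record to a permeability panel
#'
#' Averages the potential sweeps per protocol and runs
#' [solve_permeabilities()] with the record's bath compositions.
#'
#' @param record An `ephys_record` tibble (see [make_ephys_record()]).
#' @return A `permeability_result` (see [solve_permeabilities()]).
#' @export
permeabilities_from_record <- function(record) {
  v_dil <- mean(record$v_mv[record$protocol == "dilution"])
  v_bi <- mean(record$v_mv[record$protocol == "biionic"])
  solve_permeabilities(
    dilution_v = v_dil, biionic_v = v_bi, teer = record$teer[1],
    apical = attr(record, "apical"),
    basal_dilution = attr(record, "basal_dilution"),
    basal_biionic = attr(record, "basal_biionic"),
    c_nacl = attr(record, "apical")$na,
    temperature = attr(record, "temperature") %||% 310.15
  )
}

#' Simulate a Transwell tracer flux series
#'
#' Receiver amounts follow `Q(t) = P_app A C0 t` under sink conditions
#' (constant donor concentration), with multiplicative Gaussian noise.
#' The default timepoints mirror 30-min sampling over 3 h.
#'
#' @param true_papp Ground-truth apparent permeability, cm/s.
#' @param area Insert area, cm^2.
#' @param donor_conc Donor tracer concentration, ug/ml.
#' @param receiver_volume Receiver chamber volume, ml.
#' @param timepoints Sampling times in minutes, strictly increasing.
#' @param noise_frac Multiplicative noise SD as a fraction of the signal.
#' @param seed Integer seed.
#' @return Tibble (`time_min`, `amount_ug`) with attributes `truth`, `area`,
#'   `donor_conc`, `receiver_volume`.
#' @export
make_flux_series <- function(true_papp, area = 1.12, donor_conc = 200,
                             receiver_volume = 1.5,
                             timepoints = seq(0, 180, by = 30),
                             noise_frac = 0.02, seed = 1) {
  if (true_papp < 0) abort("true_papp must be non-negative")
  if (area <= 0 || donor_conc <= 0 || receiver_volume <= 0) {
    abort("area, donor_conc and receiver_volume must be positive")
  }
  if (length(timepoints) < 2) abort("need at least 2 timepoints")
  if (any(diff(timepoints) <= 0)) abort("timepoints must be strictly increasing")
  q <- true_papp * area * donor_conc * (timepoints * 60) # ug
  series <- with_private_seed(seed, {
    noisy <- q * (1 + rnorm(length(q), sd = noise_frac))
    tibble(time_min = timepoints, amount_ug = noisy)
  })
  structure(
    series,
    truth = list(p_app = true_papp), area = area, donor_conc = donor_conc,
    receiver_volume = receiver_volume,
    class = c("flux_series", class(series))
  )
}

#' @rdname make_flux_series
#' @param object A `flux_series`.
#' @param ... Unused.
#' @export
autoplot.flux_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$amount_ug)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::labs(x = "time (min)", y = "receiver amount (µg)")
}
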