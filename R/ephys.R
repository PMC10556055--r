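# Goldman-Hodgkin-Katz arithmetic for the monovalent ions modelled here
# (Na+, Cl-, Li+). Divalents and buffer species are excluded; concentrations
# stand in for activities. The ref-13 absolute-permeability step is pinned to
# the Kimizuka-Koketsu conductance form (see absolute_permeabilities).

#' Bath composition
#'
#' @param na,cl,li Ion concentrations in mM (only Na+, Cl- and Li+ enter the
#'   GHK arithmetic).
#' @param temperature Temperature in K (default 310.15, i.e. 37 C).
#' @return A one-row tibble describing the bath.
#' @export
bath <- function(na = 0, cl = 0, li = 0, temperature = 310.15) {
  if (any(c(na, cl, li) < 0)) abort("concentrations must be non-negative")
  cat_sum <- na + li
  if (cat_sum + cl > 0 && abs(cat_sum - cl) > 0.01 * max(cat_sum, cl)) {
    abort(sprintf(
      "bath is not electroneutral for the modelled ions (cations %.3g mM vs Cl- %.3g mM)",
      cat_sum, cl
    ))
  }
  tibble(na = na, cl = cl, li = li, temperature = temperature)
}

# RT/F in mV at temperature T (K)
rt_over_f_mv <- function(temperature) {
  1000 * .gas_constant * temperature / .faraday
}

#' Forward Goldman-Hodgkin-Katz potential
#'
#' Transepithelial potential (basal minus apical, mV) for given absolute or
#' relative permeabilities; only the ratios matter for the potential.
#'
#' @param p_na,p_cl,p_li Permeabilities (any common unit).
#' @param apical,basal Bath compositions from [bath()].
#' @param temperature Temperature in K.
#' @return Potential in mV.
#' @export
ghk_potential <- function(p_na, p_cl, apical, basal, p_li = 0,
                          temperature = 310.15) {
  if (any(c(p_na, p_cl, p_li) < 0)) abort("permeabilities must be non-negative")
  num <- p_na * basal$na + p_li * basal$li + p_cl * apical$cl
  den <- p_na * apical$na + p_li * apical$li + p_cl * basal$cl
  if (num <= 0 || den <= 0) abort("GHK potential undefined: zero flux terms on one side")
  rt_over_f_mv(temperature) * log(num / den)
}

#' Blank- and area-corrected transepithelial resistance
#'
#' @param r_total Measured resistance in Ohm.
#' @param r_blank Blank-filter resistance in Ohm.
#' @param area Insert area in cm^2.
#' @return TEER in Ohm cm^2.
#' @examples
#' correct_teer(300, 100, 1.12) # 224
#' @export
correct_teer <- function(r_total, r_blank, area) {
  if (any(r_blank < 0)) abort("blank resistance must be non-negative")
  if (any(area <= 0)) abort("insert area must be positive")
  if (any(r_total <= r_blank)) {
    abort("non-physical monolayer: total resistance does not exceed the blank")
  }
  (r_total - r_blank) * area
}

#' Invert a dilution potential to the permeability ratio P_Na/P_Cl
#'
#' Solves the two-ion GHK relation
#' `V = (RT/F) ln[(beta [Na]_b + [Cl]_a) / (beta [Na]_a + [Cl]_b)]`
#' for `beta = P_Na/P_Cl` in closed form. The potential must lie strictly
#' between the single-ion Nernst limits of the imposed NaCl gradient; a
#' potential at the Na+ limit returns `Inf` with a "cation-only limit"
#' warning.
#'
#' @param v_mv Measured transepithelial potential in mV.
#' @param apical,basal Bath compositions from [bath()]; the two sides must
#'   carry different NaCl concentrations.
#' @param temperature Temperature in K.
#' @param sign_convention `"basal_minus_apical"` (default) or
#'   `"apical_minus_basal"`; the latter negates `v_mv` before inversion.
#' @return The scalar permeability ratio beta.
#' @export
dilution_ratio <- function(v_mv, apical, basal, temperature = 310.15,
                           sign_convention = c("basal_minus_apical", "apical_minus_basal")) {
  sign_convention <- match.arg(sign_convention)
  if (sign_convention == "apical_minus_basal") v_mv <- -v_mv
  k <- rt_over_f_mv(temperature)
  x <- exp(v_mv / k)
  x_cl <- apical$cl / basal$cl # anion-only limit (beta -> 0)
  x_na <- basal$na / apical$na # cation-only limit (beta -> Inf)
  if (abs(log(x_na / x_cl)) < 1e-12) {
    abort("no NaCl asymmetry between sides; the dilution potential carries no information")
  }
  lo <- min(x_na, x_cl)
  hi <- max(x_na, x_cl)
  if (abs(x - x_na) < 1e-12 * x_na) {
    warn("potential at the cation-only limit; P_Na/P_Cl is unbounded")
    return(Inf)
  }
  if (x <= lo || x >= hi) {
    abort(sprintf(
      "potential %.3f mV outside the attainable interval (%.3f, %.3f) mV set by the Nernst limits",
      v_mv, k * log(lo), k * log(hi)
    ))
  }
  beta <- (x * basal$cl - apical$cl) / (basal$na - x * apical$na)
  beta
}

#' Invert a bi-ionic potential to P_Li/P_Na
#'
#' For the Li+ replacement protocol (Na-Ringer apical, Li-Ringer basal,
#' identical Cl-), solves
#' `V = (RT/F) ln[(P_Li [Li]_b + P_Cl [Cl]_a) / (P_Na [Na]_a + P_Cl [Cl]_b)]`
#' for `P_Li/P_Na` given `beta = P_Na/P_Cl`.
#'
#' @inheritParams dilution_ratio
#' @param beta The permeability ratio P_Na/P_Cl (from [dilution_ratio()]).
#' @return The scalar ratio P_Li/P_Na.
#' @export
biionic_ratio <- function(v_mv, apical, basal, beta, temperature = 310.15,
                          sign_convention = c("basal_minus_apical", "apical_minus_basal")) {
  sign_convention <- match.arg(sign_convention)
  if (sign_convention == "apical_minus_basal") v_mv <- -v_mv
  if (beta <= 0) abort("beta = P_Na/P_Cl must be positive")
  if (abs(apical$cl - basal$cl) > 1e-9 * max(apical$cl, basal$cl)) {
    abort("bi-ionic inversion requires equal Cl- on both sides")
  }
  if (basal$li <= 0) abort("basal bath carries no Li+; nothing to invert")
  k <- rt_over_f_mv(temperature)
  x <- exp(v_mv / k)
  ratio <- (x * (apical$na + basal$cl / beta) - apical$cl / beta) / basal$li
  if (ratio <= 0) {
    abort(sprintf(
      "potential %.3f mV below the attainable bound %.3f mV (P_Li/P_Na would be non-positive)",
      v_mv, k * log((apical$cl / beta) / (apical$na + basal$cl / beta))
    ))
  }
  ratio
}

#' Absolute permeabilities from conductance and the permeability ratio
#'
#' Kimizuka-Koketsu form: with monolayer conductance `G` (S cm^-2), NaCl
#' concentration `c` (converted internally to mol cm^-3) and
#' `beta = P_Na/P_Cl`,
#' `P_Na = (RT/F^2) G beta / ((1 + beta) c)` and `P_Cl = P_Na / beta`,
#' giving cm/s. `P_Na/(P_Na + P_Cl) = beta/(1+beta)` holds exactly.
#'
#' @param conductance Monolayer conductance in S cm^-2 (1/TEER).
#' @param beta Permeability ratio P_Na/P_Cl.
#' @param c_nacl Symmetric NaCl concentration in mM.
#' @param temperature Temperature in K.
#' @return One-row tibble with `p_na` and `p_cl` in cm/s.
#' @export
absolute_permeabilities <- function(conductance, beta, c_nacl,
                                    temperature = 310.15) {
  if (conductance <= 0) abort("conductance must be positive")
  if (beta <= 0 || c_nacl <= 0) abort("beta and c_nacl must be positive")
  c_mol_cm3 <- c_nacl * 1e-6 # mM -> mol/cm^3
  p_na <- (.gas_constant * temperature / .faraday^2) * conductance * beta /
    ((1 + beta) * c_mol_cm3)
  tibble(p_na = p_na, p_cl = p_na / beta)
}

#' Apparent permeability from a tracer flux series
#'
#' Fits the receiver amount Q(t) by least squares and reports
#' `P_app = (dQ/dt) / (A C0)` in cm/s, assuming sink conditions (receiver
#' concentration well below donor). A receiver concentration above 10% of
#' donor triggers a sink-condition warning; a negative fitted slope is
#' flagged but still returned.
#'
#' @param series Flux series tibble with columns `time_min` and `amount_ug`
#'   (e.g. from [make_flux_series()]); `area`, `donor_conc` and
#'   `receiver_volume` are read from attributes when not supplied.
#' @param area Insert area in cm^2.
#' @param donor_conc Donor concentration in ug/ml.
#' @param receiver_volume Receiver volume in ml (for the sink check;
#'   optional).
#' @return One-row tibble: `p_app` (cm/s), `slope_ug_per_min`, `r_squared`,
#'   `negative_flux`.
#' @export
apparent_permeability <- function(series, area = NULL, donor_conc = NULL,
                                  receiver_volume = NULL) {
  area <- area %||% attr(series, "area")
  donor_conc <- donor_conc %||% attr(series, "donor_conc")
  receiver_volume <- receiver_volume %||% attr(series, "receiver_volume")
  if (is.null(area) || is.null(donor_conc)) {
    abort("area and donor_conc must be supplied (or carried by the series)")
  }
  if (nrow(series) < 2) abort("need at least 2 timepoints")
  if (any(diff(series$time_min) <= 0)) abort("timepoints must be strictly increasing")
  if (!is.null(receiver_volume) &&
    max(series$amount_ug) / receiver_volume > 0.1 * donor_conc) {
    warn("sink condition violated: receiver concentration exceeds 10% of donor")
  }
  fit <- lm(amount_ug ~ time_min, data = series)
  slope <- unname(coef(fit)[2]) # ug/min
  ss_tot <- sum((series$amount_ug - mean(series$amount_ug))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  # ug/ml is ug/cm^3, so (ug/s) / (cm^2 * ug/cm^3) = cm/s
  p_app <- (slope / 60) / (area * donor_conc)
  if (slope < 0) warn("negative fitted flux; returning the (negative) P_app")
  tibble(
    p_app = p_app, slope_ug_per_min = slope, r_squared = r2,
    negative_flux = slope < 0
  )
}

#' Derive the full permeability panel from one monolayer's measurements
#'
#' Chains the barrier arithmetic: conductance from TEER, `beta = P_Na/P_Cl`
#' from the dilution potential, absolute `P_Na`/`P_Cl` from conductance, and
#' `P_Li` from the bi-ionic potential.
#'
#' @param dilution_v Dilution potential in mV (basal minus apical).
#' @param biionic_v Bi-ionic potential in mV.
#' @param teer Corrected TEER in Ohm cm^2.
#' @param apical,basal_dilution,basal_biionic Baths from [bath()]; defaults
#'   are the 140 mM NaCl Ringer, its 1:4 saline:mannitol dilution (28 mM
#'   NaCl) and the 140 mM LiCl replacement Ringer.
#' @param c_nacl Symmetric NaCl concentration (mM) for the conductance step.
#' @param temperature Temperature in K.
#' @return A `permeability_result`: one-row tibble with `p_na`, `p_cl`,
#'   `p_li` (cm/s), the ratios `p_na_p_cl`, `p_li_p_cl`, `p_li_p_na`, and the
#'   source quantities.
#' @export
solve_permeabilities <- function(dilution_v, biionic_v, teer,
                                 apical = bath(na = 140, cl = 140),
                                 basal_dilution = bath(na = 28, cl = 28),
                                 basal_biionic = bath(li = 140, cl = 140),
                                 c_nacl = 140, temperature = 310.15) {
  if (teer <= 0) abort("TEER must be positive")
  g <- 1 / teer
  beta <- dilution_ratio(dilution_v, apical, basal_dilution, temperature)
  abs_p <- absolute_permeabilities(g, beta, c_nacl, temperature)
  li_na <- biionic_ratio(biionic_v, apical, basal_biionic, beta, temperature)
  out <- tibble(
    p_na = abs_p$p_na, p_cl = abs_p$p_cl, p_li = li_na * abs_p$p_na,
    p_na_p_cl = beta, p_li_p_na = li_na, p_li_p_cl = li_na * beta,
    dilution_v = dilution_v, biionic_v = biionic_v, teer = teer,
    conductance = g, temperature = temperature
  )
  class(out) <- c("permeability_result", class(out))
  out
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(
    "<permeability_result: P_Na %.3g, P_Cl %.3g, P_Li %.3g cm/s; P_Na/P_Cl %.3f, P_Li/P_Na %.3f>\n",
    x$p_na, x$p_cl, x$p_li, x$p_na_p_cl, x$p_li_p_na
  ))
  invisible(x)
}

#' @rdname solve_permeabilities
#' @param x A `permeability_result`.
#' @param ... Unused.
#' @export
tidy.permeability_result <- function(x, ...) {
  tibble(
    quantity = c("P_Na", "P_Cl", "P_Li", "P_Na/P_Cl", "P_Li/P_Na", "P_Li/P_Cl"),
    value = c(x$p_na, x$p_cl, x$p_li, x$p_na_p_cl, x$p_li_p_na, x$p_li_p_cl),
    unit = c(rep("cm/s", 3), rep("", 3))
  )
}

#' @rdname solve_permeabilities
#' @export
glance.permeability_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}
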