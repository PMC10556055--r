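#' Non-bonded energy parameters
#'
#' Lennard-Jones and Coulomb parameters for the one-bead-per-residue models.
#' Defaults are MARTINI-like magnitudes: sigma 4.7 A, epsilon 2.0 kJ/mol,
#' relative dielectric 15, cutoff 12 A. All are configuration knobs; the
#' landscape shape, not its absolute scale, is what the method interprets.
#'
#' @param sigma LJ sigma, Angstrom.
#' @param epsilon LJ well depth, kJ/mol.
#' @param dielectric Relative dielectric for the Coulomb term.
#' @param cutoff Pair cutoff, Angstrom.
#' @return A named list of parameters.
#' @export
energy_params <- function(sigma = 4.7, epsilon = 2.0, dielectric = 15,
                          cutoff = 12) {
  if (sigma <= 0 || epsilon <= 0 || dielectric <= 0 || cutoff <= 0) {
    abort("all energy parameters must be positive")
  }
  list(sigma = sigma, epsilon = epsilon, dielectric = dielectric, cutoff = cutoff)
}

#' Inter-model Lennard-Jones + Coulomb interaction energy
#'
#' Sums `4 eps [(sigma/r)^12 - (sigma/r)^6]` and
#' `f q_i q_j / (eps_r r)` (f = 138.935458 kJ mol^-1 nm e^-2, r in nm for
#' the Coulomb term) over all inter-model bead pairs within the cutoff.
#' Negative totals indicate stable association. Beads flagged `cterm` are
#' excluded from energetics.
#'
#' @param model_a,model_b Placed `bead_model`s (coordinates as they stand).
#' @param params Parameters from [energy_params()].
#' @return One-row tibble: `e_lj`, `e_coul`, `e_total` (kJ/mol).
#' @export
interaction_energy <- function(model_a, model_b, params = energy_params()) {
  a <- drop_cterm(model_a)
  b <- drop_cterm(model_b)
  e <- cpp_pair_energy(
    bead_coords(a), bead_coords(b), a$charge, b$charge,
    params$sigma, params$epsilon, params$dielectric, params$cutoff
  )
  tibble(e_lj = e[1], e_coul = e[2], e_total = e[1] + e[2])
}

#' Minimal surface separation between two bead models
#'
#' @inheritParams interaction_energy
#' @return `min_ij (|r_i - r_j| - radius_i - radius_j)` in Angstrom
#'   (negative when the models overlap).
#' @export
min_surface_separation <- function(model_a, model_b) {
  cpp_min_surface_sep(
    bead_coords(model_a), bead_coords(model_b),
    model_a$radius, model_b$radius
  )
}

#' Place two membrane-aligned monomers in rotational contact
#'
#' Rotates each monomer about its own vertical axis by its theta, then
#' brings model B in along `+x` by monotone bisection until the minimal
#' inter-model surface separation equals `contact_gap` (within 0.01 A).
#'
#' @param model_a,model_b Membrane-aligned `bead_model`s.
#' @param theta1,theta2 Rotations in degrees, `[0, 360)`.
#' @param contact_gap Target surface separation, Angstrom (default 0.5).
#' @return A `pose` list: `theta1`, `theta2`, `center_distance` (the applied
#'   x-offset between the axes) and the placed models `model_a`, `model_b`.
#' @export
place_at_contact <- function(model_a, model_b, theta1, theta2,
                             contact_gap = 0.5) {
  a <- center_on_axis(model_a)
  b <- center_on_axis(model_b)
  a <- rotate_about_axis(a, theta1)
  b <- rotate_about_axis(b, theta2)
  d <- cpp_contact_offset(
    bead_coords(a), bead_coords(b), a$radius, b$radius,
    contact_gap, 0.005, 200L
  )
  b <- translate_model(b, c(d, 0, 0))
  structure(
    list(
      theta1 = theta1 %% 360, theta2 = theta2 %% 360, center_distance = d,
      model_a = a, model_b = b
    ),
    class = "pose"
  )
}

# put the model's vertical axis on the z-axis (x = y = 0 at the axis centre)
center_on_axis <- function(model) {
  cxy <- axis_center_xy(model)
  translate_model(model, c(-cxy[1], -cxy[2], 0))
}

#' Rotational cis-interaction energy landscape
#'
#' For every pair of rotations `(theta1, theta2)` on a regular grid, places
#' the two monomers in contact (see [place_at_contact()]) and evaluates the
#' non-bonded interaction energy. The result is the complete
#' `(360/increment)^2`-cell landscape whose low-energy decile defines the
#' stable cis dimer orientations.
#'
#' @param model_a,model_b Membrane-aligned `bead_model`s.
#' @param increment Grid increment in degrees; must divide 360.
#' @param params Parameters from [energy_params()].
#' @param contact_gap Surface gap used for contact placement, Angstrom.
#' @return An `energy_landscape` tibble with columns `theta1`, `theta2`,
#'   `center_distance`, `e_lj`, `e_coul`, `e_total`, and attributes
#'   `increment`, `labels`, `params`.
#' @export
compute_landscape <- function(model_a, model_b, increment = 1,
                              params = energy_params(), contact_gap = 0.5) {
  if (increment <= 0 || 360 %% increment != 0) {
    abort("increment must be a positive divisor of 360")
  }
  a <- center_on_axis(drop_cterm(model_a))
  b <- center_on_axis(drop_cterm(model_b))
  thetas <- seq(0, 360 - increment, by = increment)
  m <- cpp_landscape(
    bead_coords(a), bead_coords(b), a$charge, b$charge, a$radius, b$radius,
    thetas, thetas, contact_gap, params$sigma, params$epsilon,
    params$dielectric, params$cutoff, 0.005, 200L
  )
  grid <- tibble(
    theta1 = m[, 1], theta2 = m[, 2], center_distance = m[, 3],
    e_lj = m[, 4], e_coul = m[, 5], e_total = m[, 4] + m[, 5]
  )
  if (!all(is.finite(grid$e_total))) abort("landscape contains non-finite energies")
  structure(
    grid,
    increment = increment,
    labels = c(
      attr(model_a, "label") %||% "A",
      attr(model_b, "label") %||% "B"
    ),
    params = params, contact_gap = contact_gap,
    class = c("energy_landscape", class(grid))
  )
}

#' Extract the stable (low-energy decile) states of a landscape
#'
#' Sorts the landscape ascending by total energy (ties broken by
#' `(theta1, theta2)` lexicographic order) and keeps the lowest
#' `floor(percentile/100 * n_cells)` states, so the count is integer-exact:
#' 12,960 states for the default 10th percentile on a 1-degree grid.
#'
#' @param landscape An `energy_landscape`.
#' @param percentile Percentile in (0, 100]; default 10.
#' @return A `stable_states` tibble (subset of the landscape, ascending
#'   energy) with attributes `summary` (mean, sd, count, threshold) and
#'   `percentile`.
#' @export
stable_states <- function(landscape, percentile = 10) {
  if (nrow(landscape) == 0) abort("empty landscape")
  if (percentile <= 0 || percentile > 100) abort("percentile must be in (0, 100]")
  n_keep <- floor(percentile / 100 * nrow(landscape))
  if (n_keep < 1) abort("percentile keeps no states on this grid")
  ord <- order(landscape$e_total, landscape$theta1, landscape$theta2)
  out <- landscape[ord[seq_len(n_keep)], , drop = FALSE]
  smry <- tibble(
    mean = mean(out$e_total), sd = sd(out$e_total), count = n_keep,
    threshold = out$e_total[n_keep]
  )
  structure(
    as_tibble(out),
    summary = smry, percentile = percentile,
    class = c("stable_states", class(tibble()))
  )
}

#' Statistics over the pore-forming rotational window
#'
#' Pore-forming claudin dimers sit near the 270-degree/270-degree rotational
#' orientation; this reports energy statistics over all cells whose two
#' angles both fall in the window around `center`. The default window is
#' half-open, `[center - halfwidth, center + halfwidth)`, giving 20 values
#' per axis at 1-degree increment and hence 400 member cells; set
#' `closed = TRUE` for the closed 21-value (441-cell) variant.
#'
#' @param landscape An `energy_landscape`.
#' @param center Window centre in degrees (default 270).
#' @param halfwidth Half-width in degrees (default 10; must be < 180).
#' @param closed Use the closed window including both endpoints.
#' @return A `window_stats` list: `$summary` (one-row tibble: center,
#'   halfwidth, n_cells, mean, sd) and `$members` (the member cells).
#' @export
window_stats <- function(landscape, center = 270, halfwidth = 10,
                         closed = FALSE) {
  if (halfwidth >= 180) abort("halfwidth must be below 180 degrees")
  in_window <- function(theta) {
    d <- (theta - (center - halfwidth)) %% 360
    if (closed) d <= 2 * halfwidth else d < 2 * halfwidth
  }
  members <- landscape[in_window(landscape$theta1) & in_window(landscape$theta2), ,
    drop = FALSE
  ]
  smry <- tibble(
    center = center, halfwidth = halfwidth, n_cells = nrow(members),
    mean = mean(members$e_total), sd = sd(members$e_total)
  )
  structure(
    list(summary = smry, members = as_tibble(members)),
    class = "window_stats"
  )
}

#' @export
print.window_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<window_stats: %d cells at %g° ± %g°; mean %.3f, sd %.3f kJ/mol>\n",
    s$n_cells, s$center, s$halfwidth, s$mean, s$sd
  ))
  invisible(x)
}

#' @rdname compute_landscape
#' @param x,object An `energy_landscape`.
#' @param ... Unused.
#' @export
glance.energy_landscape <- function(x, ...) {
  i <- which.min(x$e_total)
  tibble(
    n_cells = nrow(x), increment = attr(x, "increment"),
    min_energy = x$e_total[i], min_theta1 = x$theta1[i],
    min_theta2 = x$theta2[i], mean_energy = mean(x$e_total),
    sd_energy = sd(x$e_total)
  )
}

#' @rdname compute_landscape
#' @export
autoplot.energy_landscape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$theta1, .data$theta2, fill = .data$e_total)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E (kJ/mol)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = expression(theta[1] ~ (degree)), y = expression(theta[2] ~ (degree)),
      title = paste(attr(object, "labels"), collapse = " / ")
    )
}

#' @rdname stable_states
#' @param x A `stable_states` object.
#' @param ... Unused.
#' @export
glance.stable_states <- function(x, ...) {
  cbind(attr(x, "summary"), tibble(percentile = attr(x, "percentile")))
}

#' Write a landscape as a dense CSV energy matrix
#'
#' Rows are `theta1`, columns `theta2`, both labelled in degrees; cell
#' values are total energies in kJ/mol.
#'
#' @param landscape An `energy_landscape`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_landscape_csv <- function(landscape, path) {
  wide <- tidyr::pivot_wider(
    landscape[, c("theta1", "theta2", "e_total")],
    names_from = "theta2", values_from = "e_total"
  )
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
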