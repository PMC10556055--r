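#' Build a cis dimer from a stable rotational state
#'
#' Freezes two membrane-aligned monomers in the relative pose of a chosen
#' rotational state (typically a low-decile landscape cell) into a single
#' rigid unit. Chains are remapped to A/B and a `monomer` column records the
#' grouping.
#'
#' @param model_a,model_b Membrane-aligned `bead_model`s.
#' @param theta1,theta2 Rotational state in degrees.
#' @param contact_gap Surface gap for contact placement, Angstrom.
#' @param label Composition label; defaults to `"labelA/labelB"`.
#' @return A `cis_dimer` (a `bead_model` with a `monomer` column).
#' @export
cis_dimer <- function(model_a, model_b, theta1, theta2, contact_gap = 0.5,
                      label = NULL) {
  pose <- place_at_contact(model_a, model_b, theta1, theta2, contact_gap)
  a <- pose$model_a
  b <- pose$model_b
  a$chain_id <- "A"
  b$chain_id <- "B"
  a$monomer <- "A"
  b$monomer <- "B"
  out <- dplyr::bind_rows(as_tibble(a), as_tibble(b))
  structure(
    out,
    label = label %||% paste(
      attr(model_a, "label") %||% "A",
      attr(model_b, "label") %||% "B",
      sep = "/"
    ),
    principal_axis = c(0, 0, 1),
    thetas = c(pose$theta1, pose$theta2),
    class = c("cis_dimer", "bead_model", class(tibble()))
  )
}

#' Assemble two cis dimers into a trans tetramer
#'
#' Places the second dimer head-on above the first: it is rotated 180
#' degrees about an in-membrane axis so the extracellular segments of the
#' two dimers face each other across the paracellular gap, laterally centred
#' on the first dimer, and lowered until the minimal inter-dimer surface
#' separation equals `gap`. Each dimer moves only rigidly, so the internal
#' geometry of both cis units is preserved exactly.
#'
#' @param dimer_bottom,dimer_top `cis_dimer`s (or any `bead_model`s) with
#'   extracellular segments pointing `+z`.
#' @param gap Target minimal surface separation between the dimers,
#'   Angstrom (default 2).
#' @param params Energy parameters used for the stored interface energy.
#' @return A `trans_tetramer`: a bead tibble with columns `dimer`
#'   (`"bottom"`/`"top"`) and chains A-D, attributes `gap`, `trans_mode`
#'   (`homotypic` when both dimers share a composition label) and `energies`.
#' @export
build_tetramer <- function(dimer_bottom, dimer_top, gap = 2,
                           params = energy_params()) {
  if (gap < 0) abort("gap must be non-negative")
  bottom <- as_tibble(dimer_bottom)
  top <- flip_head_on(dimer_top)
  # lateral centring
  shift_xy <- c(
    mean(bottom$x) - mean(top$x),
    mean(bottom$y) - mean(top$y)
  )
  top <- translate_model(top, c(shift_xy, 0))
  # start with the top dimer's lowest surface at the bottom dimer's highest
  s0 <- (max(bottom$z + bottom$radius) + gap + 1) - min(top$z - top$radius)
  top <- translate_model(top, c(0, 0, s0))
  sep_at <- function(dz) {
    cpp_min_surface_sep(
      cbind(bottom$x, bottom$y, bottom$z),
      cbind(top$x, top$y, top$z + dz),
      bottom$radius, top$radius
    )
  }
  lo <- 0
  while (sep_at(lo) > gap) lo <- lo - max(1, abs(lo))
  hi <- 0
  while (sep_at(hi) < gap) hi <- hi + 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sep_at(mid) < gap) lo <- mid else hi <- mid
  }
  top <- translate_model(top, c(0, 0, hi))
  if (min_surface_separation(bottom, top) < 0) {
    abort("steric overlap between dimers at the requested gap; increase the gap")
  }
  bottom$dimer <- "bottom"
  top$dimer <- "top"
  chain_map <- c(A = "C", B = "D")
  top$chain_id <- unname(chain_map[top$chain_id])
  top$chain_id[is.na(top$chain_id)] <- "C"
  out <- dplyr::bind_rows(bottom, as_tibble(top))
  lb <- attr(dimer_bottom, "label") %||% "bottom"
  lt <- attr(dimer_top, "label") %||% "top"
  tet <- structure(
    out,
    label = paste(lb, lt, sep = " x "),
    principal_axis = c(0, 0, 1),
    gap = gap,
    trans_mode = if (identical(lb, lt)) "homotypic" else "heterotypic",
    params = params,
    class = c("trans_tetramer", "bead_model", class(tibble()))
  )
  attr(tet, "energies") <- trans_interface_energy(tet, params)
  tet
}

#' Trans interface energy of an assembled tetramer
#'
#' Non-bonded energy summed only over bead pairs with one bead in each cis
#' dimer group, decomposed into Lennard-Jones and Coulomb components.
#'
#' @param tetramer A `trans_tetramer`.
#' @param params Parameters from [energy_params()].
#' @return One-row tibble: `e_lj`, `e_coul`, `e_total` (kJ/mol).
#' @export
trans_interface_energy <- function(tetramer, params = energy_params()) {
  bottom <- tetramer[tetramer$dimer == "bottom", , drop = FALSE]
  top <- tetramer[tetramer$dimer == "top", , drop = FALSE]
  interaction_energy(bottom, top, params)
}

#' Locally refine a tetramer's rigid placement
#'
#' Minimises the trans interface energy over four rigid degrees of freedom
#' of the top dimer (vertical gap, x/y lateral shift, twist about z) with
#' Nelder-Mead from the symmetric start; poses that overlap or leave the
#' search box are rejected by penalty. The dimer-internal geometry is
#' untouched and the returned energy never exceeds the input energy.
#'
#' @param tetramer A `trans_tetramer`.
#' @param params Parameters from [energy_params()].
#' @param max_dz,max_lateral,max_twist Symmetric search bounds: vertical and
#'   lateral shifts in Angstrom, twist in degrees.
#' @param maxit Nelder-Mead iteration cap.
#' @return The refined `trans_tetramer`; attribute `refinement` records the
#'   start/end energies and the optimal shifts.
#' @export
refine_tetramer <- function(tetramer, params = energy_params(), max_dz = 2,
                            max_lateral = 3, max_twist = 15, maxit = 500) {
  bottom <- tetramer[tetramer$dimer == "bottom", , drop = FALSE]
  top0 <- tetramer[tetramer$dimer == "top", , drop = FALSE]
  ctr <- colMeans(cbind(top0$x, top0$y, top0$z))
  move_top <- function(par) {
    m <- apply_rigid(top0, rot = rot_z(par[4]), center = ctr)
    translate_model(m, c(par[2], par[3], par[1]))
  }
  bounds <- c(max_dz, max_lateral, max_lateral, max_twist)
  objective <- function(par) {
    if (any(abs(par) > bounds)) {
      return(1e6 + sum(pmax(abs(par) - bounds, 0)))
    }
    m <- move_top(par)
    sep <- min_surface_separation(bottom, m)
    if (sep < 0) {
      return(1e6 - sep)
    }
    interaction_energy(bottom, m, params)$e_total
  }
  e_start <- objective(c(0, 0, 0, 0))
  if (e_start >= 1e6) abort("start pose infeasible within the search bounds")
  # repeated Nelder-Mead restarts from the running best until converged:
  # a single pass can stall on a shrunken simplex, a fresh simplex at the
  # same point is a cheap deterministic escape
  par <- c(0, 0, 0, 0)
  e_best <- e_start
  for (round in 1:10) {
    fit <- optim(par, objective,
      method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-10)
    )
    if (fit$value < e_best - 1e-8) {
      par <- fit$par
      e_best <- fit$value
    } else {
      break
    }
  }
  if (e_best > e_start) par <- c(0, 0, 0, 0)
  top <- move_top(par)
  out <- dplyr::bind_rows(as_tibble(bottom), as_tibble(top))
  attrs <- attributes(tetramer)
  for (nm in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, nm) <- attrs[[nm]]
  }
  class(out) <- class(tetramer)
  attr(out, "energies") <- trans_interface_energy(out, params)
  attr(out, "refinement") <- tibble(
    e_start = e_start, e_end = attr(out, "energies")$e_total,
    dz = par[1], dx = par[2], dy = par[3], twist = par[4]
  )
  out
}

#' @rdname build_tetramer
#' @param x A `trans_tetramer`.
#' @param ... Unused.
#' @export
glance.trans_tetramer <- function(x, ...) {
  e <- attr(x, "energies")
  tibble(
    label = attr(x, "label"), trans_mode = attr(x, "trans_mode"),
    gap = attr(x, "gap"), n_beads = nrow(x),
    e_lj = e$e_lj, e_coul = e$e_coul, e_total = e$e_total
  )
}

#' Write a tetramer as a multi-chain pseudo-atom PDB
#'
#' @param tetramer A `trans_tetramer` (chains A-D).
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_tetramer <- function(tetramer, path) {
  write_structure(tetramer, path)
}
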