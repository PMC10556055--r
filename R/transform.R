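# rigid-motion helpers ------------------------------------------------------

# apply a 3x3 rotation about `center`, then translate by `shift`
apply_rigid <- function(model, rot = diag(3), center = c(0, 0, 0), shift = c(0, 0, 0)) {
  xyz <- sweep(bead_coords(model), 2, center)
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, center + shift, FUN = "+")
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

rot_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
    nrow = 3, byrow = TRUE
  )
}

rot_x <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
    nrow = 3, byrow = TRUE
  )
}

translate_model <- function(model, shift) apply_rigid(model, shift = shift)

# rotate about the model's own vertical axis (through its axis centre)
rotate_about_axis <- function(model, theta_deg) {
  cxy <- axis_center_xy(model)
  apply_rigid(model, rot = rot_z(theta_deg), center = c(cxy, 0))
}

#' Truncate the cytosolic C-terminal tail
#'
#' Claudin C-terminal tails are disordered and cytosolic; they are removed
#' before any geometry or energetics. Beads with `residue_index` greater than
#' `boundary` are dropped.
#'
#' @param model A `bead_model`.
#' @param boundary Last residue index to keep (1-based, as in PDB).
#' @return The truncated `bead_model`.
#' @export
truncate_cterm <- function(model, boundary) {
  rng <- range(model$residue_index)
  if (boundary < rng[1] || boundary > rng[2]) {
    abort(sprintf(
      "boundary %d outside chain range [%d, %d]", boundary, rng[1], rng[2]
    ))
  }
  model[model$residue_index <= boundary, , drop = FALSE]
}

#' Align a bead model to the membrane frame
#'
#' Finds the principal (largest-variance) axis of the transmembrane beads
#' (all beads when no TM segments are annotated), maps it onto `+z`, and
#' moves the TM centroid to the origin. The transform is rigid: all pairwise
#' distances are preserved. When ECS segments are annotated the sign of the
#' axis is chosen so the extracellular side points to `+z`.
#'
#' @param model A `bead_model` with at least 4 beads spanning more than 1 A.
#' @return The aligned `bead_model`.
#' @export
align_to_membrane_frame <- function(model) {
  if (nrow(model) < 4) abort("need at least 4 beads to define a membrane frame")
  tm <- !is.na(model$segment) & grepl("^TM", model$segment)
  ref <- if (any(tm)) model[tm, ] else model
  xyz <- bead_coords(ref)
  if (max(apply(xyz, 2, function(v) diff(range(v)))) <= 1) {
    abort("bead cloud spans less than 1 angstrom; cannot orient")
  }
  ctr <- colMeans(xyz)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)
  if (ev$values[2] < 1e-8) abort("degenerate (collinear) bead cloud; cannot orient")
  # rows e1,e2,e3 with the principal axis last -> maps it to +z
  basis <- rbind(ev$vectors[, 2], ev$vectors[, 3], ev$vectors[, 1])
  if (det(basis) < 0) basis[1, ] <- -basis[1, ]
  out <- apply_rigid(model, rot = basis, center = ctr, shift = -ctr)
  ecs <- !is.na(out$segment) & grepl("^ECS", out$segment)
  flip <- if (any(ecs)) mean(out$z[ecs]) < 0 else sum(out$z^3) < 0
  if (flip) out <- apply_rigid(out, rot = rot_x(180))
  attr(out, "principal_axis") <- c(0, 0, 1)
  out
}

#' Flip a model head-on across the paracellular gap
#'
#' Rotates the model 180 degrees about an in-membrane (x) axis through its
#' centroid, so the extracellular segments that pointed `+z` point `-z`. The
#' operation is an involution (applying it twice restores the input).
#'
#' @param model A `bead_model` (typically a cis dimer).
#' @return The flipped `bead_model`.
#' @export
flip_head_on <- function(model) {
  ctr <- colMeans(bead_coords(model))
  apply_rigid(model, rot = rot_x(180), center = ctr)
}
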