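# run code with a private RNG stream, leaving the session RNG untouched
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a claudin-like toy monomer
#'
#' Builds a four-helix bead-column bundle spanning a membrane slab plus two
#' extracellular arcs, mimicking the claudin fold: four transmembrane
#' segments (TM1-TM4) and two extracellular segments, with ECS1 longer than
#' ECS2. Formal charges can be planted at chosen positions on the arcs;
#' charged beads are named LYS (+1) or ASP (-1) so that charge classification
#' is consistent with real structures. A small seeded coordinate jitter makes
#' the rotational energy landscape non-degenerate; the same seed always
#' reproduces bit-identical coordinates.
#'
#' @param n_tm_residues_per_helix Beads per transmembrane column (default 12).
#' @param ecl_charges Optional data frame with columns `segment` (`"ECS1"` or
#'   `"ECS2"`), `offset` (1-based position along the arc) and `charge`
#'   (+1 or -1).
#' @param seed Integer seed controlling the jitter.
#' @param n_ecs1,n_ecs2 Arc lengths in beads; `n_ecs1` must exceed `n_ecs2`.
#' @param jitter_sd Coordinate jitter SD in Angstrom.
#' @param label Model label.
#' @return A [bead_model()] with segments annotated, TM centroid near the
#'   origin and membrane normal `+z`; attribute `membrane` holds the slab
#'   z-bounds.
#' @export
make_toy_monomer <- function(n_tm_residues_per_helix = 12, ecl_charges = NULL,
                             seed = 1, n_ecs1 = 12, n_ecs2 = 6,
                             jitter_sd = 0.15, label = "TOY") {
  n_tm <- n_tm_residues_per_helix
  if (n_tm < 2 || n_ecs1 < 2 || n_ecs2 < 2) abort("segment bead counts must be at least 2")
  if (n_ecs1 <= n_ecs2) abort("ECS1 must be longer than ECS2")
  rise <- 1.4
  z_top <- (n_tm - 1) * rise
  col_xy <- list(
    TM1 = c(3.5, 3.5), TM2 = c(-3.5, 3.5),
    TM3 = c(-3.5, -3.5), TM4 = c(3.5, -3.5)
  )
  helix <- function(seg, up) {
    zs <- seq(0, z_top, length.out = n_tm)
    if (!up) zs <- rev(zs)
    tibble(
      segment = seg, x = col_xy[[seg]][1], y = col_xy[[seg]][2], z = zs,
      residue_name = "LEU"
    )
  }
  arc <- function(seg, n, radius, a0, a1, z_base) {
    ang <- seq(a0, a1, length.out = n) * pi / 180
    tibble(
      segment = seg, x = radius * cos(ang), y = radius * sin(ang),
      z = z_base + 0.8 * sin(seq(0, pi, length.out = n)),
      residue_name = "GLY"
    )
  }
  parts <- dplyr::bind_rows(
    helix("TM1", TRUE),
    arc("ECS1", n_ecs1, 5.0, 0, 240, z_top + 3.0),
    helix("TM2", FALSE),
    helix("TM3", TRUE),
    arc("ECS2", n_ecs2, 4.2, 255, 345, z_top + 2.2),
    helix("TM4", FALSE)
  )
  if (!is.null(ecl_charges)) {
    ecl_charges <- as.data.frame(ecl_charges)
    for (i in seq_len(nrow(ecl_charges))) {
      seg <- ecl_charges$segment[i]
      off <- ecl_charges$offset[i]
      q <- ecl_charges$charge[i]
      if (!seg %in% c("ECS1", "ECS2")) {
        abort(paste0("charge placement outside the extracellular arcs: ", seg))
      }
      idx <- which(parts$segment == seg)
      if (off < 1 || off > length(idx)) {
        abort(sprintf("offset %d outside %s (1..%d)", off, seg, length(idx)))
      }
      if (!q %in% c(-1, 1)) abort("planted charges must be +1 or -1")
      parts$residue_name[idx[off]] <- if (q > 0) "LYS" else "ASP"
    }
  }
  parts <- with_private_seed(seed, {
    n <- nrow(parts)
    parts$x <- parts$x + rnorm(n, sd = jitter_sd)
    parts$y <- parts$y + rnorm(n, sd = jitter_sd)
    parts$z <- parts$z + rnorm(n, sd = jitter_sd)
    parts
  })
  parts$residue_index <- seq_len(nrow(parts))
  parts$chain_id <- "A"
  parts$radius <- .default_bead_radius
  m <- bead_model(parts, label = label)
  attr(m, "membrane") <- c(z_min = 0, z_max = z_top)
  m
}

#' Generate a ring-stack structure with analytically known pore radii
#'
#' Places beads on circles centred on the z-axis, one ring per entry of
#' `ring_radii`, spaced `z_spacing` apart. This is the analytic oracle for
#' the pore profiler: on the axis, the clearance at height z is exactly
#' `min_k sqrt(r_k^2 + (z - z_k)^2) - bead_radius`, and the axis is the
#' in-plane maximiser, so the true maximal probe radius at each ring plane is
#' known in closed form (it reduces to `ring_radius - bead_radius` whenever
#' the slice's own ring governs). Walls whose inter-bead gap exceeds the bead
#' diameter are flagged leaky: a probe can escape sideways, so the recorded
#' truth no longer bounds the profiler.
#'
#' @param ring_radii Numeric vector of ring radii (Angstrom, >= 0).
#' @param beads_per_ring Beads per ring (>= 6).
#' @param bead_radius Bead radius in Angstrom.
#' @param z_spacing Vertical distance between rings.
#' @param label Model label.
#' @return A [bead_model()]; attribute `ring_spec` stores the ring geometry
#'   and attribute `ground_truth` a tibble with the analytic clearance per
#'   ring plane (`z`, `clearance`, `blocked`, `leaky`).
#' @export
make_ring_stack <- function(ring_radii, beads_per_ring = 24, bead_radius = 2,
                            z_spacing = 1.5, label = "RING") {
  if (any(ring_radii < 0)) abort("ring radii must be non-negative")
  if (beads_per_ring < 6) abort("need at least 6 beads per ring")
  if (bead_radius <= 0 || z_spacing <= 0) abort("bead_radius and z_spacing must be positive")
  nr <- length(ring_radii)
  zs <- (seq_len(nr) - 1) * z_spacing
  ang <- 2 * pi * (seq_len(beads_per_ring) - 1) / beads_per_ring
  beads <- dplyr::bind_rows(lapply(seq_len(nr), function(k) {
    tibble(
      x = ring_radii[k] * cos(ang), y = ring_radii[k] * sin(ang), z = zs[k],
      residue_name = "GLY", segment = "loop"
    )
  }))
  beads$residue_index <- seq_len(nrow(beads))
  beads$chain_id <- "A"
  beads$radius <- bead_radius
  spec <- tibble(z = zs, ring_radius = ring_radii, n = beads_per_ring)
  leaky <- 2 * ring_radii * sin(pi / beads_per_ring) > 2 * bead_radius
  truth <- tibble(
    z = zs,
    clearance = vapply(zs, function(z0) {
      min(sqrt(ring_radii^2 + (z0 - zs)^2)) - bead_radius
    }, numeric(1)),
    blocked = NA, leaky = leaky
  )
  truth$blocked <- truth$clearance < 0
  if (any(leaky)) {
    warn("ring stack has leaky walls (inter-bead gap exceeds bead diameter); analytic truth flagged")
  }
  m <- bead_model(beads, label = label)
  attr(m, "ring_spec") <- spec
  attr(m, "bead_radius") <- bead_radius
  attr(m, "ground_truth") <- truth
  m
}

#' Analytic on-axis clearance of a ring stack
#'
#' @param stack A ring stack from [make_ring_stack()].
#' @param z Heights (Angstrom) at which to evaluate the clearance.
#' @return Numeric vector of clearances (may be negative when blocked).
#' @export
ring_stack_truth <- function(stack, z) {
  spec <- attr(stack, "ring_spec")
  if (is.null(spec)) abort("not a ring stack: no ring_spec attribute")
  br <- attr(stack, "bead_radius")
  vapply(z, function(z0) {
    min(sqrt(spec$ring_radius^2 + (z0 - spec$z)^2)) - br
  }, numeric(1))
}
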