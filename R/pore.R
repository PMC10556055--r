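#' Profile the paracellular pore of a structure
#'
#' Slices the structure along the membrane normal and, in each z-plane,
#' finds the in-plane point maximising the clearance
#' `c(p) = min_i (|p - b_i| - radius_i)` over all beads (HOLE-style
#' slice-chained search: each slice's maximisation is seeded from the
#' previous slice's centre, the first from the structure axis, with one
#' restart on the local slice centroid). The maximal inscribed probe radius
#' is `max(c, 0)`; the pore exists only if every slice clears
#' `probe_threshold` and the centre path stays laterally connected
#' (successive centres within `2 z_step`). Broken or blocked channels are
#' reported with minimum diameter 0 rather than omitted.
#'
#' @param structure A `bead_model` or `trans_tetramer`.
#' @param z_range Length-2 numeric: z-interval to profile (Angstrom);
#'   defaults to the structure's z-extent. Must intersect the structure.
#' @param z_step Slice spacing, Angstrom (default 0.5).
#' @param probe_threshold Minimum probe radius for an open pore, Angstrom
#'   (default 0.9).
#' @return A `pore_profile` tibble (`z`, `cx`, `cy`, `probe_radius`,
#'   `diameter`) with attributes `min_diameter`, `pore_exists`, `broken`,
#'   `z_step`, `probe_threshold`.
#' @export
profile_pore <- function(structure, z_range = NULL, z_step = 0.5,
                         probe_threshold = 0.9) {
  if (nrow(structure) == 0) abort("empty structure")
  if (z_step <= 0) abort("z_step must be positive")
  zext <- range(structure$z)
  z_range <- z_range %||% zext
  if (z_range[1] > z_range[2]) abort("z_range must be increasing")
  if (z_range[2] < zext[1] || z_range[1] > zext[2]) {
    abort(sprintf(
      "z_range [%g, %g] lies outside the structure extent [%g, %g]",
      z_range[1], z_range[2], zext[1], zext[2]
    ))
  }
  xyz <- bead_coords(structure)
  rad <- structure$radius
  # the centre search is confined to the structure's in-plane footprint:
  # outside it the clearance grows without bound (the probe has escaped the
  # channel), which would let the maximiser run away in open space
  xlim <- range(structure$x)
  ylim <- range(structure$y)
  clamp <- function(p) {
    c(min(max(p[1], xlim[1]), xlim[2]), min(max(p[2], ylim[1]), ylim[2]))
  }
  clearance <- function(p, z0) {
    p <- clamp(p)
    min(sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - z0)^2) - rad)
  }
  maximise <- function(seed, z0) {
    fit <- optim(clamp(seed), function(p) -clearance(p, z0),
      method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-12)
    )
    list(center = clamp(fit$par), clearance = -fit$value)
  }
  zs <- seq(z_range[1], z_range[2], by = z_step)
  axis_seed <- c(mean(structure$x), mean(structure$y))
  out <- vector("list", length(zs))
  prev <- axis_seed
  for (k in seq_along(zs)) {
    z0 <- zs[k]
    best <- maximise(prev, z0)
    near <- abs(structure$z - z0) <= max(3, 2 * z_step)
    if (any(near)) {
      local_seed <- c(mean(structure$x[near]), mean(structure$y[near]))
      alt <- maximise(local_seed, z0)
      if (alt$clearance > best$clearance) best <- alt
    }
    out[[k]] <- tibble(
      z = z0, cx = best$center[1], cy = best$center[2],
      probe_radius = max(best$clearance, 0)
    )
    prev <- best$center
  }
  prof <- dplyr::bind_rows(out)
  prof$diameter <- 2 * prof$probe_radius
  jumps <- sqrt(diff(prof$cx)^2 + diff(prof$cy)^2)
  broken <- any(jumps > 2 * z_step)
  blocked <- any(prof$probe_radius < probe_threshold)
  attr(prof, "z_step") <- z_step
  attr(prof, "probe_threshold") <- probe_threshold
  attr(prof, "min_diameter") <- if (broken) 0 else max(2 * min(prof$probe_radius), 0)
  attr(prof, "pore_exists") <- !broken && !blocked
  attr(prof, "broken") <- broken
  class(prof) <- c("pore_profile", class(prof))
  prof
}

#' Minimum pore diameter within a region
#'
#' @param profile A `pore_profile`.
#' @param region Optional length-2 z-interval restricting the search.
#' @return One-row tibble: `min_diameter` (Angstrom) and `z_at_min` (ties
#'   resolved to the smallest z).
#' @export
min_diameter_report <- function(profile, region = NULL) {
  if (nrow(profile) == 0) abort("empty profile")
  sub <- profile
  if (!is.null(region)) {
    sub <- profile[profile$z >= region[1] & profile$z <= region[2], , drop = FALSE]
    if (nrow(sub) == 0) abort("region is disjoint from the profiled samples")
  }
  i <- which(sub$diameter == min(sub$diameter))[1]
  tibble(min_diameter = sub$diameter[i], z_at_min = sub$z[i])
}

#' @rdname profile_pore
#' @param x,object A `pore_profile`.
#' @param ... Unused.
#' @export
glance.pore_profile <- function(x, ...) {
  tibble(
    n_samples = nrow(x), z_step = attr(x, "z_step"),
    min_diameter = attr(x, "min_diameter"),
    pore_exists = attr(x, "pore_exists"), broken = attr(x, "broken"),
    probe_threshold = attr(x, "probe_threshold")
  )
}

#' @rdname profile_pore
#' @export
autoplot.pore_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$diameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = 2 * attr(object, "probe_threshold"),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(x = "z (Å)", y = "pore diameter (Å)")
}
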