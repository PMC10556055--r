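#' Identify and classify pore-lining residues
#'
#' A bead lines the pore when its side-chain bead lies within `cutoff` of
#' the channel. Distance is measured to the channel *surface* by default:
#' the 3D distance to the nearest channel-centre sample minus that sample's
#' probe radius (a centreline mode, ignoring the probe radius, is
#' selectable). Members are assigned to pore regions by z-thirds of the
#' profiled interval (`mouth_bottom`, `center`, `mouth_top`), classified by
#' charge/polarity, and the net charge (sum of member formal charges) is
#' tallied overall and per region. A blocked or broken channel is refused
#' explicitly rather than reported empty.
#'
#' @param structure The profiled `bead_model` or `trans_tetramer`.
#' @param profile Its `pore_profile`; `pore_exists` must hold.
#' @param cutoff Proximity cutoff in Angstrom (default 6).
#' @param mode `"surface"` (default) or `"centerline"`.
#' @return A `pore_lining_report` list: `$members` (tibble with distance,
#'   region, charge and class per member), `$by_region` (tallies per
#'   region), `$net_charge`, `$counts` (members per class) and `$cutoff`.
#' @export
pore_lining_report <- function(structure, profile, cutoff = 6,
                               mode = c("surface", "centerline")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) abort("cutoff must be positive")
  if (!isTRUE(attr(profile, "pore_exists"))) {
    abort("no pore: the channel is blocked or broken, pore-lining residues not evaluated")
  }
  ctr <- cbind(profile$cx, profile$cy, profile$z)
  xyz <- bead_coords(structure)
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(ctr))) -
    2 * xyz %*% t(ctr) + outer(rep(1, nrow(xyz)), rowSums(ctr^2))
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  nearest <- max.col(-dmat, ties.method = "first")
  dist_center <- dmat[cbind(seq_len(nrow(xyz)), nearest)]
  dist <- if (mode == "surface") {
    dist_center - profile$probe_radius[nearest]
  } else {
    dist_center
  }
  zr <- range(profile$z)
  thirds <- zr[1] + diff(zr) * c(1, 2) / 3
  region <- dplyr::case_when(
    profile$z[nearest] < thirds[1] ~ "mouth_bottom",
    profile$z[nearest] < thirds[2] ~ "center",
    TRUE ~ "mouth_top"
  )
  keep <- dist <= cutoff
  members <- as_tibble(structure)[keep, , drop = FALSE]
  members$distance <- dist[keep]
  members$region <- region[keep]
  cls_levels <- c("positive", "negative", "polar", "apolar")
  counts <- vapply(cls_levels, function(cl) sum(members$charge_class == cl), integer(1))
  by_region <- members |>
    dplyr::count(.data$region, .data$charge_class) |>
    tidyr::pivot_wider(
      names_from = "charge_class", values_from = "n", values_fill = 0L
    )
  net_by_region <- members |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(net_charge = sum(.data$charge), .groups = "drop")
  out <- list(
    members = members,
    counts = tibble(charge_class = cls_levels, n = unname(counts)),
    by_region = dplyr::left_join(by_region, net_by_region, by = "region"),
    net_charge = sum(members$charge),
    cutoff = cutoff, mode = mode
  )
  class(out) <- "pore_lining_report"
  out
}

#' @export
print.pore_lining_report <- function(x, ...) {
  cat(sprintf(
    "<pore_lining_report: %d members within %g Å (%s), net charge %+d>\n",
    nrow(x$members), x$cutoff, x$mode, as.integer(x$net_charge)
  ))
  print(x$counts)
  invisible(x)
}

#' @rdname pore_lining_report
#' @param x A `pore_lining_report`.
#' @param ... Unused.
#' @export
tidy.pore_lining_report <- function(x, ...) x$members

#' @rdname pore_lining_report
#' @export
glance.pore_lining_report <- function(x, ...) {
  n <- setNames(x$counts$n, x$counts$charge_class)
  tibble(
    n_members = nrow(x$members), n_positive = n[["positive"]],
    n_negative = n[["negative"]], n_polar = n[["polar"]],
    n_apolar = n[["apolar"]], net_charge = x$net_charge, cutoff = x$cutoff
  )
}
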