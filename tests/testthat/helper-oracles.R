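# Independent brute-force oracles, deliberately written without reusing any
# package internals beyond plain data access.

# double-loop LJ + Coulomb over inter-model bead pairs
brute_energy <- function(model_a, model_b, sigma = 4.7, epsilon = 2.0,
                         dielectric = 15, cutoff = 12) {
  e_lj <- 0
  e_coul <- 0
  for (i in seq_len(nrow(model_a))) {
    for (j in seq_len(nrow(model_b))) {
      r <- sqrt(
        (model_a$x[i] - model_b$x[j])^2 +
          (model_a$y[i] - model_b$y[j])^2 +
          (model_a$z[i] - model_b$z[j])^2
      )
      if (r > cutoff) next
      sr6 <- (sigma / r)^6
      e_lj <- e_lj + 4 * epsilon * (sr6^2 - sr6)
      q <- model_a$charge[i] * model_b$charge[j]
      if (q != 0) e_coul <- e_coul + 138.935458 * q / (dielectric * r / 10)
    }
  }
  c(e_lj = e_lj, e_coul = e_coul, e_total = e_lj + e_coul)
}

# exhaustive in-plane grid search for the maximal probe clearance at height z0:
# full scan at 0.2 A, then an exhaustive 0.02 A scan around the coarse optimum
grid_clearance <- function(structure, z0, half_extent, coarse = 0.2, fine = 0.02) {
  clear_at <- function(px, py) {
    apply(cbind(px, py), 1, function(p) {
      min(sqrt((structure$x - p[1])^2 + (structure$y - p[2])^2 +
        (structure$z - z0)^2) - structure$radius)
    })
  }
  g <- expand.grid(
    px = seq(-half_extent, half_extent, by = coarse),
    py = seq(-half_extent, half_extent, by = coarse)
  )
  cg <- clear_at(g$px, g$py)
  best <- g[which.max(cg), ]
  f <- expand.grid(
    px = seq(best$px - 2 * coarse, best$px + 2 * coarse, by = fine),
    py = seq(best$py - 2 * coarse, best$py + 2 * coarse, by = fine)
  )
  max(clear_at(f$px, f$py))
}

# Kabsch superposition RMSD between two coordinate sets
superpose_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((yc - xc %*% t(rot))^2)))
}

pairwise_dists <- function(model) {
  as.matrix(stats::dist(cbind(model$x, model$y, model$z)))
}

# random rigid motion applied to a bead tibble (independent of the package's
# transform helpers)
random_rigid <- function(model, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0, -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% ry %*% rz
  shift <- stats::runif(3, -10, 10)
  xyz <- cbind(model$x, model$y, model$z) %*% t(rot)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

# a straight open channel with chosen residues planted on the wall: ring
# stack whose beads can be renamed, then rebuilt so charges follow the names
make_charged_channel <- function(ring_radii = rep(5, 5), beads_per_ring = 24,
                                 bead_radius = 2, z_spacing = 1.5,
                                 rename = NULL) {
  rs <- make_ring_stack(ring_radii, beads_per_ring, bead_radius, z_spacing)
  df <- tibble::as_tibble(rs)
  if (!is.null(rename)) {
    df$residue_name[rename$residue_index] <- rename$residue_name
  }
  df$charge <- NULL
  df$charge_class <- NULL
  bead_model(df, label = "channel")
}
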