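two_beads <- function(r, names = c("LYS", "ASP"), radius = 2) {
  list(
    a = bead_model(tibble::tibble(
      residue_index = 1, residue_name = names[1], chain_id = "A",
      x = 0, y = 0, z = 0, radius = radius
    ), "a"),
    b = bead_model(tibble::tibble(
      residue_index = 1, residue_name = names[2], chain_id = "B",
      x = r, y = 0, z = 0, radius = radius
    ), "b")
  )
}

test_that("energy kernel matches closed forms and the double-loop oracle", {
  # unit +1/-1 charges at 10 A with dielectric 15, LJ pushed out of range
  p <- energy_params(sigma = 1e-3)
  tb <- two_beads(10)
  e <- interaction_energy(tb$a, tb$b, p)
  expect_equal(e$e_coul, -138.935458 / (15 * 1.0), tolerance = 1e-12)
  expect_equal(round(e$e_coul, 4), -9.2624)
  # LJ root at r = sigma for neutral beads
  tb2 <- two_beads(4.7, names = c("GLY", "GLY"))
  expect_equal(interaction_energy(tb2$a, tb2$b)$e_lj, 0, tolerance = 1e-12)
  # 50-bead random pair against the brute-force pairwise oracle
  set.seed(31)
  mk <- function(offset) {
    bead_model(tibble::tibble(
      residue_index = 1:50,
      residue_name = sample(c("LYS", "ASP", "GLY", "SER"), 50, replace = TRUE),
      chain_id = "A",
      x = runif(50, 0, 12) + offset, y = runif(50, 0, 12), z = runif(50, 0, 12),
      radius = 2
    ), "rand")
  }
  ra <- mk(0)
  rb <- mk(13)
  e2 <- interaction_energy(ra, rb)
  oracle <- brute_energy(ra, rb)
  expect_equal(e2$e_lj, unname(oracle["e_lj"]), tolerance = 1e-9)
  expect_equal(e2$e_coul, unname(oracle["e_coul"]), tolerance = 1e-9)
  expect_equal(e2$e_total, e2$e_lj + e2$e_coul, tolerance = 1e-12)
  # singularity guard
  tb3 <- two_beads(0.05)
  expect_error(interaction_energy(tb3$a, tb3$b), "overlap")
  # doubling the dielectric halves the Coulomb term exactly
  e_half <- interaction_energy(ra, rb, energy_params(dielectric = 30))
  expect_equal(e_half$e_coul, e2$e_coul / 2, tolerance = 1e-12)
  expect_equal(e_half$e_lj, e2$e_lj, tolerance = 1e-12)
})

test_that("contact placement reaches the requested surface gap", {
  tb <- two_beads(0, radius = 2)
  pose <- place_at_contact(tb$a, tb$b, 0, 0, contact_gap = 0)
  expect_equal(pose$center_distance, 4, tolerance = 0.01)
  # against a 0.01 A brute-force translation scan
  m1 <- make_toy_monomer(seed = 1)
  m2 <- make_toy_monomer(seed = 2)
  pose2 <- place_at_contact(m1, m2, 40, 130, contact_gap = 0.5)
  a <- pose2$model_a
  b0 <- pose2$model_b
  b0$x <- b0$x - pose2$center_distance
  scan <- seq(5, 40, by = 0.01)
  seps <- vapply(scan, function(d) {
    bd <- b0
    bd$x <- bd$x + d
    min_surface_separation(a, bd)
  }, numeric(1))
  d_scan <- scan[which(seps >= 0.5)[1]]
  expect_lt(abs(pose2$center_distance - d_scan), 0.02)
  expect_equal(min_surface_separation(a, pose2$model_b), 0.5, tolerance = 0.011)
})

test_that("pose energy is invariant under global rigid motion", {
  m1 <- make_toy_monomer(seed = 3)
  m2 <- make_toy_monomer(seed = 4)
  pose <- place_at_contact(m1, m2, 120, 275)
  e0 <- interaction_energy(pose$model_a, pose$model_b)
  for (s in 1:3) {
    pair <- random_rigid(
      dplyr::bind_rows(
        dplyr::mutate(tibble::as_tibble(pose$model_a), part = "a"),
        dplyr::mutate(tibble::as_tibble(pose$model_b), part = "b")
      ),
      seed = s
    )
    e1 <- interaction_energy(
      pair[pair$part == "a", ], pair[pair$part == "b", ]
    )
    expect_equal(e1$e_total, e0$e_total, tolerance = 1e-9)
  }
})

test_that("landscape grids are complete, periodic and symmetry-faithful", {
  m1 <- make_toy_monomer(seed = 1)
  m2 <- make_toy_monomer(seed = 2)
  ls <- compute_landscape(m1, m2, increment = 30)
  expect_equal(nrow(ls), 144)
  expect_setequal(unique(ls$theta1), seq(0, 330, by = 30))
  expect_true(all(is.finite(ls$e_total)))
  # azimuthally symmetric models (ring symmetry = grid increment) give a
  # constant landscape
  ring <- make_ring_stack(rep(5, 3), beads_per_ring = 12, bead_radius = 2)
  lsr <- compute_landscape(ring, ring, increment = 30)
  expect_lt(diff(range(lsr$e_total)), 1e-6)
  # homodimer mirror symmetry: exchanging roles with the pair flipped maps
  # cell (t1, t2) to ((t2 + 180), (t1 + 180))
  lsh <- compute_landscape(m1, m1, increment = 45)
  key <- function(t1, t2) paste(t1 %% 360, t2 %% 360)
  e <- setNames(lsh$e_total, key(lsh$theta1, lsh$theta2))
  mirrored <- e[key(lsh$theta2 + 180, lsh$theta1 + 180)]
  expect_equal(unname(mirrored), lsh$e_total, tolerance = 1e-6)
  expect_error(compute_landscape(m1, m2, increment = 7), "divisor")
})

test_that("stable-state extraction matches the sort-and-slice oracle", {
  m1 <- make_toy_monomer(seed = 6)
  m2 <- make_toy_monomer(seed = 7)
  ls <- compute_landscape(m1, m2, increment = 36) # 10 x 10 grid
  st <- stable_states(ls, percentile = 10)
  # oracle: order all cells by energy, keep floor(0.1 * 100) = 10
  ord <- order(ls$e_total, ls$theta1, ls$theta2)
  expect_equal(nrow(st), 10)
  expect_equal(st$e_total, ls$e_total[ord][1:10])
  expect_equal(st$theta1, ls$theta1[ord][1:10])
  s <- glance(st)
  expect_equal(s$mean, mean(ls$e_total[ord][1:10]))
  # percentile 100 keeps everything
  expect_equal(nrow(stable_states(ls, 100)), nrow(ls))
  # nesting: stable(p) subset of stable(q) for p <= q
  st5 <- stable_states(ls, 5)
  expect_true(all(
    paste(st5$theta1, st5$theta2) %in% paste(st$theta1, st$theta2)
  ))
  expect_error(stable_states(ls[0, ], 10), "empty")
})

test_that("window statistics use the half-open pore-forming window", {
  m1 <- make_toy_monomer(seed = 8)
  m2 <- make_toy_monomer(seed = 9)
  ls <- compute_landscape(m1, m2, increment = 10)
  w <- window_stats(ls, center = 270, halfwidth = 10)
  # half-open [260, 280) at 10 degrees -> 2 values per axis -> 4 cells
  expect_equal(w$summary$n_cells, 4)
  expect_setequal(unique(w$members$theta1), c(260, 270))
  # closed variant includes both endpoints -> 9 cells
  wc <- window_stats(ls, center = 270, halfwidth = 10, closed = TRUE)
  expect_equal(wc$summary$n_cells, 9)
  # direct-summation oracle for the statistics
  inw <- ls$theta1 %in% c(260, 270) & ls$theta2 %in% c(260, 270)
  expect_equal(w$summary$mean, sum(ls$e_total[inw]) / 4, tolerance = 1e-12)
  expect_equal(w$summary$sd, sd(ls$e_total[inw]), tolerance = 1e-12)
  # constant landscape has zero spread
  ring <- make_ring_stack(rep(5, 3), beads_per_ring = 36, bead_radius = 2)
  lsr <- compute_landscape(ring, ring, increment = 10)
  expect_equal(window_stats(lsr)$summary$sd, 0, tolerance = 1e-7)
  expect_error(window_stats(ls, halfwidth = 180), "halfwidth")
})
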