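ringer <- bath(na = 140, cl = 140)
dilution <- bath(na = 28, cl = 28)
li_ringer <- bath(li = 140, cl = 140)

test_that("TEER correction is exact arithmetic with physical guards", {
  expect_equal(correct_teer(300, 100, 1.12), 224)
  expect_equal(correct_teer(300, 0, 1.12), 300 * 1.12)
  # inverse round trip
  teer <- correct_teer(312.7, 95.3, 1.12)
  expect_equal(teer / 1.12 + 95.3, 312.7, tolerance = 1e-12)
  expect_error(correct_teer(90, 100, 1.12), "non-physical")
  expect_error(correct_teer(300, 100, 0), "area")
})

test_that("dilution-potential inversion recovers beta across the GHK grid", {
  # zero potential on a pure NaCl dilution means no selectivity
  expect_equal(dilution_ratio(0, ringer, dilution), 1, tolerance = 1e-12)
  # forward-then-invert across beta and dilution strengths
  for (beta in c(0.1, 0.5, 1, 2, 5, 10)) {
    for (frac in c(2, 4, 5)) {
      basal <- bath(na = 140 / frac, cl = 140 / frac)
      v <- ghk_potential(beta * 1e-6, 1e-6, ringer, basal)
      expect_equal(dilution_ratio(v, ringer, basal), beta, tolerance = 1e-6)
    }
  }
  # antisymmetry: swapping sides flips the potential, not the ratio
  v <- ghk_potential(2e-6, 1e-6, ringer, dilution)
  expect_equal(ghk_potential(2e-6, 1e-6, dilution, ringer), -v, tolerance = 1e-12)
  expect_equal(dilution_ratio(-v, dilution, ringer), 2, tolerance = 1e-9)
  # sign-convention flag
  expect_equal(
    dilution_ratio(-v, ringer, dilution, sign_convention = "apical_minus_basal"),
    2,
    tolerance = 1e-9
  )
  # the cation-only Nernst limit is flagged, beyond it is an error
  k <- 1000 * 8.31446261815324 * 310.15 / 96485.33212331001
  v_na <- k * log(28 / 140)
  expect_warning(b_inf <- dilution_ratio(v_na, ringer, dilution), "cation-only")
  expect_identical(b_inf, Inf)
  expect_error(dilution_ratio(v_na - 1, ringer, dilution), "Nernst")
  expect_error(dilution_ratio(0, ringer, ringer), "asymmetry")
})

test_that("bi-ionic inversion recovers P_Li/P_Na including its limits", {
  # equal cation concentrations, symmetric Cl, zero potential -> ratio 1
  expect_equal(biionic_ratio(0, ringer, li_ringer, beta = 2), 1, tolerance = 1e-12)
  # forward-then-invert round trip
  for (li_na in c(0.5, 0.8, 1, 1.3, 2)) {
    p_na <- 2e-6
    v <- ghk_potential(p_na, 1e-6, ringer, li_ringer, p_li = li_na * p_na)
    expect_equal(biionic_ratio(v, ringer, li_ringer, beta = 2), li_na,
      tolerance = 1e-6
    )
  }
  # anion-blind limit: ratio -> exp(VF/RT) [Na]_a / [Li]_b
  k <- 1000 * 8.31446261815324 * 310.15 / 96485.33212331001
  v <- 3.7
  expect_equal(
    biionic_ratio(v, ringer, li_ringer, beta = 1e9),
    exp(v / k) * 140 / 140,
    tolerance = 1e-6
  )
  expect_error(biionic_ratio(0, ringer, dilution, beta = 2), "equal Cl")
  expect_error(biionic_ratio(-200, ringer, li_ringer, beta = 2), "bound")
})

test_that("absolute permeabilities reproduce the hand-checked unit oracle", {
  # frozen from an independent high-precision calculation:
  # G = 1/224 S/cm^2, beta = 1.5, 140 mM, 310.15 K
  p <- absolute_permeabilities(1 / 224, 1.5, 140)
  expect_equal(p$p_na, 5.29978894234812e-06, tolerance = 1e-12)
  expect_equal(p$p_cl, 3.53319262823208e-06, tolerance = 1e-12)
  # beta = 1 splits the conductance evenly
  p1 <- absolute_permeabilities(1 / 224, 1, 140)
  expect_equal(p1$p_na, p1$p_cl, tolerance = 1e-15)
  # linear in conductance
  p2 <- absolute_permeabilities(2 / 224, 1.5, 140)
  expect_equal(p2$p_na, 2 * p$p_na, tolerance = 1e-12)
  # exact fractional split for any beta
  for (beta in c(0.2, 1.7, 6)) {
    pp <- absolute_permeabilities(1 / 200, beta, 140)
    expect_equal(pp$p_na / (pp$p_na + pp$p_cl), beta / (1 + beta),
      tolerance = 1e-12
    )
  }
  expect_error(absolute_permeabilities(0, 1, 140), "positive")
})

test_that("apparent permeability recovers the generating slope", {
  fs <- make_flux_series(5e-6, noise_frac = 0, seed = 1)
  est <- apparent_permeability(fs)
  expect_equal(est$p_app, 5e-6, tolerance = 1e-9)
  # explicit linear series with known slope
  ser <- tibble::tibble(time_min = c(0, 30, 60, 90), amount_ug = c(0, 3, 6, 9))
  est2 <- apparent_permeability(ser, area = 1, donor_conc = 100)
  expect_equal(est2$p_app, (0.1 / 60) / (1 * 100), tolerance = 1e-12)
  # zero flux -> zero permeability
  zer <- tibble::tibble(time_min = c(0, 30, 60), amount_ug = c(0, 0, 0))
  expect_equal(apparent_permeability(zer, area = 1, donor_conc = 100)$p_app, 0)
  # declining signal is flagged but still returned
  neg <- tibble::tibble(time_min = c(0, 30, 60), amount_ug = c(2, 1, 0))
  expect_warning(res <- apparent_permeability(neg, area = 1, donor_conc = 100), "negative")
  expect_true(res$negative_flux)
  expect_lt(res$p_app, 0)
  expect_error(
    apparent_permeability(tibble::tibble(time_min = 0, amount_ug = 0), 1, 1),
    "at least 2"
  )
  # sink-condition warning
  big <- make_flux_series(5e-4, noise_frac = 0, seed = 1)
  expect_warning(apparent_permeability(big), "sink")
})

test_that("the full permeability panel is internally consistent", {
  rec <- make_ephys_record(2.4e-6, 1.2e-6, 2.9e-6, teer = 224, noise_sd = 0, seed = 2)
  res <- permeabilities_from_record(rec)
  truth <- attr(rec, "truth")
  expect_equal(res$p_na_p_cl, truth$beta, tolerance = 1e-6)
  expect_equal(res$p_li_p_na, truth$li_na, tolerance = 1e-6)
  # ratios consistent with components
  expect_equal(res$p_na / res$p_cl, res$p_na_p_cl, tolerance = 1e-9)
  expect_equal(res$p_li / res$p_na, res$p_li_p_na, tolerance = 1e-9)
  expect_equal(res$p_li_p_cl, res$p_li_p_na * res$p_na_p_cl, tolerance = 1e-9)
  expect_true(all(c(res$p_na, res$p_cl, res$p_li) > 0))
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_equal(td$value[td$quantity == "P_Na/P_Cl"], res$p_na_p_cl)
})
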