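test_that("partition rules hit the target volume exactly and behave as designed", {
  sh <- ellipsoid_shape(8, 2)
  rig <- rigidity_params()
  v0 <- ellipsoid_volume(sh)

  ## identity
  p <- partition_deformation(sh, rig, v0)
  expect_equal(p$dr, 0, tolerance = 1e-10)
  expect_equal(p$dz, 0, tolerance = 1e-10)

  for (rule in c("energy-min", "self-similar", "fixed-ratio:3.1")) {
    for (vt in c(0.8 * v0, v0 * 1.001, 1.3 * v0, 2 * v0)) {
      p <- partition_deformation(sh, rig, vt, rule)
      expect_equal(p$V, vt, tolerance = 1e-10)
      expect_equal(
        ellipsoid_volume(ellipsoid_shape(p$a, p$c)), vt,
        tolerance = 1e-10
      )
    }
  }

  ## self-similar: equal relative deformations by construction
  p <- partition_deformation(sh, rig, 1.5 * v0, "self-similar")
  expect_equal(p$dr / 8, p$dz / 2, tolerance = 1e-12)

  ## fixed ratio honoured
  p <- partition_deformation(sh, rig, 1.5 * v0, "fixed-ratio:3.1")
  expect_equal(p$dr / p$dz, 3.1, tolerance = 1e-9)

  expect_error(partition_deformation(sh, rig, -10), "not attainable")
  expect_error(partition_deformation(sh, rig, v0, "nonsense"), "unknown partition rule")
})

test_that("energy-min partition matches Lagrange stationarity and is minimal", {
  sh <- ellipsoid_shape(8, 2)
  rig <- rigidity_params(beta0 = 0, betaz = 0) # quadratic work
  v0 <- ellipsoid_volume(sh)

  ## small-volume-change limit: dr/dz -> c gzz0 / (a g00) = 0.198
  p <- partition_deformation(sh, rig, v0 + 0.01, "energy-min")
  expect_equal(p$dr / p$dz, 2 * 0.008 / (8 * 0.0101), tolerance = 1e-3)

  ## constrained minimality: beats the other rules' elastic work at equal volume
  work <- function(part) {
    101 * part$dr^2 + 80 * part$dz^2 / 2 # int 2 g00 r dr + int gzz0 z dz
  }
  vt <- 1.2 * v0
  w_em <- work(partition_deformation(sh, rig, vt, "energy-min"))
  expect_lt(w_em, work(partition_deformation(sh, rig, vt, "self-similar")))
  expect_lt(w_em, work(partition_deformation(sh, rig, vt, "fixed-ratio:1")))
})

test_that("isotonic start is a fixed point of the dynamics", {
  cfg <- swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = 5, Cl = 5), c(Na = 5, Cl = 5)),
    rigidity_params(),
    t_span = 100, n_out = 51
  )
  traj <- simulate_swelling(cfg)
  expect_equal(nrow(traj), 51) # not truncated: full span
  expect_equal(traj$V_um3, rep(traj$V_um3[1], 51), tolerance = 1e-10)
  expect_equal(traj$dP_os_Pa, rep(0, 51), tolerance = 1e-8)
})

test_that("solute conservation holds to 1e-6 along every trajectory", {
  for (cfg in list(
    reversible_config(30, t_span = 200, n_out = 101),
    swelling_config(
      ellipsoid_shape(8, 2),
      medium_state(c(Na = 20, Cl = 20), c(Na = 1, Cl = 1)),
      rigidity_params(), # disruption on
      t_span = 200, n_out = 101
    )
  )) {
    traj <- simulate_swelling(cfg)
    for (col in c("C_Cl_mM", "C_Na_mM")) {
      prod <- traj[[col]] * traj$V_um3
      expect_lt(max(abs(prod / prod[1] - 1)), 1e-6)
    }
  }
})

test_that("hypertonic swelling is monotone and reaches the flux-balance root", {
  cfg <- reversible_config(50, t_span = 300)
  traj <- simulate_swelling(cfg)
  expect_true(all(diff(traj$V_um3) >= -1e-9))
  expect_true(all(diff(traj$zeta) >= -1e-12))
  expect_true(all(diff(traj$xi) >= -1e-12))

  sat <- saturation_state(cfg)
  expect_true(sat$reversible)
  expect_equal(
    tail(traj$V_um3, 1), sat$V_sat_um3,
    tolerance = 1e-4
  )
  ## at the root, osmotic and stretching pressures balance
  expect_equal(sat$dP_os_Pa, sat$dP_imm_Pa, tolerance = 1e-9)
})

test_that("halving the solver tolerances moves the saturated volume by < 0.1%", {
  cfg1 <- reversible_config(40, t_span = 300, rtol = 1e-6, atol = 1e-8)
  cfg2 <- reversible_config(40, t_span = 300, rtol = 5e-7, atol = 5e-9)
  v1 <- tail(simulate_swelling(cfg1)$V_um3, 1)
  v2 <- tail(simulate_swelling(cfg2)$V_um3, 1)
  expect_lt(abs(v1 - v2) / v2, 1e-3)
})

test_that("saturation_state handles isotonic, hypotonic and irreversible regimes", {
  iso <- swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = 5, Cl = 5), c(Na = 5, Cl = 5)),
    rigidity_params()
  )
  s <- saturation_state(iso)
  expect_equal(s$V_sat_um3, ellipsoid_volume(ellipsoid_shape(8, 2)))
  expect_true(s$reversible)

  hypo <- swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = 1, Cl = 1), c(Na = 9, Cl = 9)),
    rigidity_params()
  )
  expect_error(saturation_state(hypo), "hypotonic")

  ## full disruption law at 50 mM: the osmotic drive exceeds the maximum
  ## restoring pressure -> no reversible equilibrium; the balance point sits
  ## just below the classical volume on the disrupted branch
  path <- swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = 50, Cl = 50), c(Na = 1, Cl = 1)),
    rigidity_params(), # beta as in the rigidity preset
    partition_rule = "self-similar"
  )
  s <- saturation_state(path)
  expect_false(s$reversible)
  expect_match(s$note, "no reversible equilibrium")
  v_cl <- classical_saturation_volume(path)
  expect_lt(s$V_sat_um3, v_cl)
  expect_gt(s$V_sat_um3, 0.9 * v_cl)
})

test_that("larger initial internal concentration gives larger saturated volume", {
  sw <- sweep_swelling(reversible_config(10, t_span = 300), c(10, 30, 50))
  expect_true(all(diff(sw$V_sat_um3) > 0))
  expect_true(all(diff(sw$S_sat_um2) > 0))
  expect_true(all(sw$reversible))
})

test_that("classical baseline saturates at the conservation volume, above the mechanical model", {
  cfg <- reversible_config(50, t_span = 300)
  v0 <- ellipsoid_volume(cfg$shape)

  expect_equal(classical_saturation_volume(cfg), v0 * 50 / 1)
  expect_equal(classical_saturation_volume(cfg), 26808.26, tolerance = 1e-6)

  traj <- classical_swelling(cfg)
  ## fluxes: J_in > J_out while swelling; their gap shrinks
  expect_true(all(traj$J_w_in_um3_s >= traj$J_w_out_um3_s - 1e-9))
  gap <- traj$J_w_in_um3_s - traj$J_w_out_um3_s
  expect_lt(tail(gap, 1), gap[1])

  ## the mechanical model saturates strictly below the classical volume
  v_mech <- saturation_state(cfg)$V_sat_um3
  expect_lt(v_mech, classical_saturation_volume(cfg))
  expect_lt(v_mech, 0.05 * classical_saturation_volume(cfg)) # far below, reversible regime
})

test_that("linearized closed form has the right endpoints and risetime", {
  m <- linearized_model(alpha = 2400, S_bar = 456, p_w_bar = 1e-13, dP_os = 5000)
  expect_equal(linearized_solution(m, 0), 0)
  expect_equal(linearized_solution(m, 1e9), 5000 / 2400, tolerance = 1e-12)
  rate <- linearized_rate(m)
  expect_equal(rate, 2400 * 456 * 1e-13 * 1e6, tolerance = 1e-12)
  expect_equal(
    linearized_solution(m, 1 / rate),
    (1 - exp(-1)) * 5000 / 2400,
    tolerance = 1e-12
  )
})

test_that("small-drive simulation matches the linearized solution within 2%", {
  cfg <- swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = 2, Cl = 2), c(Na = 1, Cl = 1)),
    rigidity_params(), # full disruption law; strains stay tiny
    partition_rule = "self-similar", t_span = 120, n_out = 241
  )
  traj <- simulate_swelling(cfg)
  v0 <- traj$V_um3[1]
  expect_lt(max(traj$V_um3 - v0) / v0, 0.02) # the linear-regime premise

  m <- linearize_config(cfg)
  idx <- which(traj$time_s > 0.5 / linearized_rate(m))
  dv_sim <- traj$V_um3[idx] - v0
  dv_lin <- linearized_solution(m, traj$time_s[idx])
  expect_lt(max(abs(dv_sim - dv_lin) / dv_lin), 0.02)
})

test_that("fit_alpha recovers the coupling and rate from self-generated data", {
  m <- linearized_model(alpha = 1800, S_bar = 470, p_w_bar = 1e-13, dP_os = 8000)
  traj <- linearized_trajectory(m, t_end = 5 / linearized_rate(m))
  fit <- fit_alpha(traj)
  expect_equal(fit$alpha, 1800, tolerance = 1e-2)
  expect_equal(fit$rate, linearized_rate(m), tolerance = 1e-2)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unit"))
  expect_equal(glance(fit)$risetime_s, 1 / fit$rate)

  short <- linearized_trajectory(m, t_end = 1, n = 5)
  expect_error(fit_alpha(short), "at least 10")
})
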