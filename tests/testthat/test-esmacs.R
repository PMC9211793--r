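# End-point estimation: frame energies, 1traj aggregation, receptor
# adaptation and the replica bootstrap.

test_that("frame free energy is the component sum and rejects bad data", {
  expect_equal(frame_free_energy(c(E_vdw = 0, E_ele = 0, E_internal = 0,
                                   G_PB = 0, G_SA = 0)), 0)
  expect_equal(frame_free_energy(c(E_vdw = -10, E_ele = -20,
                                   E_internal = 100, G_PB = -35,
                                   G_SA = 5)), 40)
  expect_error(frame_free_energy(c(E_vdw = NaN, E_ele = 0, E_internal = 0,
                                   G_PB = 0, G_SA = 0)), "E_vdw")
})

test_that("1traj cancels internal energies when interaction is zero", {
  est <- one_traj_estimate(tiny_energy_table(interaction = 0), B = 200)
  expect_equal(est$value, 0)
  expect_equal(unname(est$components[["dE_internal"]]), 0)
  # a pure vdW interaction shows up in value and dE_vdw alone
  est2 <- one_traj_estimate(tiny_energy_table(interaction = -7), B = 200)
  expect_equal(est2$value, -7)
  expect_equal(unname(est2$components[["dE_vdw"]]), -7)
})

test_that("1traj value equals the sum of its component breakdown", {
  en <- gen_esmacs_dataset(esmacs_series_spec(c(A = -38), n_replicas = 4,
                                              n_frames = 6, seed = 2))
  est <- one_traj_estimate(en, B = 200, seed = 1)
  expect_equal(est$value, sum(est$components), tolerance = 1e-9)
  expect_equal(est$value, mean(est$replica_means))
  expect_equal(est$n_replicas, length(est$replica_means))
})

test_that("misaligned species frames raise an alignment error", {
  en <- tiny_energy_table()
  broken <- en[!(en$species == "ligand" & en$replica == 2 & en$frame == 3), ]
  expect_error(one_traj_estimate(broken, B = 200), "2, 3|2:3")
})

test_that("1traj coverage: planted value inside 4 bootstrap SE", {
  hits <- 0
  for (s in 1:100) {
    en <- gen_esmacs_dataset(esmacs_series_spec(
      c(A = -40), n_replicas = 25, n_frames = 4,
      component_noise_sds = zero_noise_sds, between_replica_sd = 1.0,
      interaction_frame_sd = 0, seed = s))
    est <- one_traj_estimate(en, B = 500, seed = s)
    if (abs(est$value + 40) < 4 * est$se) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("relative adaptation is the deviation from the compound mean", {
  en <- rbind(cbind(compound_id = "A", tiny_energy_table()),
              cbind(compound_id = "B", tiny_energy_table()))
  tab <- receptor_adaptation_relative(en, B = 200)
  expect_equal(tab$adaptation, c(0, 0))
  # shift compound B's receptor energy by +4: adaptations are -2 / +2
  en$E_ele[en$compound_id == "B" & en$species == "receptor"] <-
    en$E_ele[en$compound_id == "B" & en$species == "receptor"] + 4
  tab <- receptor_adaptation_relative(en, B = 200)
  expect_equal(tab$adaptation[match(c("A", "B"), tab$compound_id)],
               c(-2, 2))
  expect_equal(sum(tab$adaptation), 0, tolerance = 1e-9)
  expect_error(receptor_adaptation_relative(
    cbind(compound_id = "A", tiny_energy_table())), ">= 2 compounds")
})

test_that("1traj-ar shifts the value and propagates SE in quadrature", {
  est <- one_traj_estimate(tiny_energy_table(interaction = -40), B = 200)
  same <- one_traj_ar_estimate(est, 0)
  expect_equal(same$value, est$value)
  ar <- one_traj_ar_estimate(est, 3, adaptation_se = 0.5)
  expect_equal(ar$value, est$value + 3)
  expect_equal(ar$se, sqrt(est$se^2 + 0.25))
  expect_equal(ar$protocol, "1traj-ar")
})

test_that("heterogeneous adaptation offsets widen the estimate spread", {
  map <- setNames(runif(8, -45, -30), paste0("C", 1:8))
  set.seed(3)
  offs <- setNames(rnorm(8, 0, 3), names(map))
  en <- gen_esmacs_dataset(noiseless_esmacs_spec(
    map, receptor_adaptation_offsets = offs, n_replicas = 2, n_frames = 2))
  plain <- esmacs_series(en, protocol = "1traj", B = 200, seed = 1)
  ar <- esmacs_series(en, protocol = "1traj-ar", B = 200, seed = 1)
  expect_gte(sd(ar$dG), sd(plain$dG))
})

test_that("bootstrap SE matches the closed-form SE of the mean", {
  expect_equal(bootstrap_se(rep(3.2, 10), B = 500), 0)
  # average over draws of 25 means from Normal(0, 1): SE of the mean is 0.2
  ses <- sapply(1:10, function(s) {
    set.seed(s)
    bootstrap_se(rnorm(25), B = 5000, seed = s)
  })
  expect_lt(abs(mean(ses) - 0.2) / 0.2, 0.25)
  # for a fixed sample the bootstrap converges to the plug-in SE
  set.seed(42)
  x <- rnorm(25)
  se <- bootstrap_se(x, B = 5000, seed = 9)
  plug_in <- sd(x) * sqrt(1 - 1 / 25) / sqrt(25)
  expect_lt(abs(se - plug_in) / plug_in, 0.05)
  expect_identical(se, bootstrap_se(x, B = 5000, seed = 9))
  expect_error(bootstrap_se(1.0), "at least 2")
})

test_that("replica relabelling changes neither value nor bootstrap SE", {
  en <- gen_esmacs_dataset(esmacs_series_spec(c(A = -40), n_replicas = 5,
                                              n_frames = 4, seed = 6))
  est <- one_traj_estimate(en, B = 1000, seed = 4)
  perm <- en
  relab <- c(3L, 5L, 1L, 2L, 4L)
  perm$replica <- relab[perm$replica]
  est_p <- one_traj_estimate(perm, B = 1000, seed = 4)
  expect_equal(est_p$value, est$value)
  expect_identical(est_p$se, est$se)
})
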