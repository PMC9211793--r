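# Generators: planted truths, determinism, and the exact structural
# identities they promise.

test_that("noiseless TI data recovers the planted ddG exactly", {
  sp <- noiseless_ti_spec(data.frame(ref_id = "L30", target_id = "L2",
                                     ddg_true = -2.88))
  res <- ties_analyze(gen_ti_dataset(sp), B = 200, seed = 1)
  expect_equal(res$ddG_calc, -2.88, tolerance = 1e-9)
  expect_equal(res$se_calc, 0)
})

test_that("generators are pure functions of their spec", {
  sp <- ti_series_spec(data.frame(ref_id = "A", target_id = "B",
                                  ddg_true = 1.5),
                       n_samples_per_window = 10, seed = 5)
  expect_identical(gen_ti_dataset(sp)$dudl, gen_ti_dataset(sp)$dudl)
  es <- esmacs_series_spec(c(A = -40), n_replicas = 2, n_frames = 3,
                           seed = 5)
  expect_identical(gen_esmacs_dataset(es), gen_esmacs_dataset(es))
  cs <- compound_series_spec(seed = 5)
  expect_identical(gen_compound_series(cs), gen_compound_series(cs))
})

test_that("adding replicas never perturbs existing replica streams", {
  edges <- data.frame(ref_id = "A", target_id = "B", ddg_true = 0.7)
  small <- gen_ti_dataset(ti_series_spec(edges, n_replicas = 3,
                                         n_samples_per_window = 8,
                                         seed = 3))$dudl
  big <- gen_ti_dataset(ti_series_spec(edges, n_replicas = 5,
                                       n_samples_per_window = 8,
                                       seed = 3))$dudl
  big3 <- big[big$replica <= 3, ]
  rownames(big3) <- rownames(small) <- NULL
  expect_identical(small, big3)
})

test_that("recovered ddG across many noisy edges is unbiased", {
  n_edges <- 200
  set.seed(10)
  edges <- data.frame(ref_id = paste0("R", seq_len(n_edges)),
                      target_id = paste0("T", seq_len(n_edges)),
                      ddg_true = runif(n_edges, -4, 4))
  sp <- ti_series_spec(edges, n_replicas = 5, n_samples_per_window = 10,
                       within_replica_sd = 0.3, between_replica_sd = 0.2,
                       seed = 11)
  res <- ties_analyze(gen_ti_dataset(sp), B = 200, seed = 2)
  err <- res$ddG_calc - edges$ddg_true[match(paste(edges$ref_id,
                                                   edges$target_id,
                                                   sep = ">"),
                                             res$edge_id)]
  se_mean <- sd(err) / sqrt(n_edges)
  expect_lt(abs(mean(err)), 3 * se_mean)
})

test_that("quadrature refinement: doubling window density changes the
          noiseless estimate by less than the coarse trapezoid bound", {
  coarse <- ti_lambda_schedule()
  mids <- (coarse[-1] + coarse[-length(coarse)]) / 2
  fine <- sort(c(coarse, mids))
  edges <- data.frame(ref_id = "A", target_id = "B", ddg_true = -1.7)
  dg <- function(lams) {
    sp <- noiseless_ti_spec(edges, n_samples = 2, lambda_schedule = lams)
    ties_analyze(gen_ti_dataset(sp), B = 200, seed = 1)$ddG_calc
  }
  # the planted profile is quadratic with f'' = 2 * curvature = 8 on each
  # leg; the bound legs differ, so the ddG difference is bounded by twice
  # one leg's composite trapezoid error sum(|f''| h^3 / 12)
  bound <- 2 * sum(8 * diff(coarse)^3 / 12)
  expect_lt(abs(dg(fine) - dg(coarse)), bound)
})

test_that("ESMACS frames decompose exactly as receptor + ligand + interaction", {
  es <- esmacs_series_spec(c(A = -40, B = -35), n_replicas = 3, n_frames = 5,
                           seed = 8)
  en <- gen_esmacs_dataset(es)
  comp <- c("E_vdw", "E_ele", "E_internal", "G_PB", "G_SA")
  for (cid in c("A", "B")) {
    sub <- en[en$compound_id == cid, ]
    key <- function(sp) {
      p <- sub[sub$species == sp, ]
      p[order(p$replica, p$frame), comp]
    }
    int <- key("complex") - key("receptor") - key("ligand")
    # the interaction term exists and the complex is its exact bitwise sum
    expect_identical(unname(as.matrix(key("complex"))),
                     unname(as.matrix(key("receptor") + key("ligand") +
                                        int)))
    # per-compound interaction mean equals the planted affinity
    expect_equal(mean(rowSums(int)), c(A = -40, B = -35)[[cid]],
                 tolerance = 0.5)
  }
})

test_that("noiseless ESMACS data recovers the planted affinity exactly", {
  en <- gen_esmacs_dataset(noiseless_esmacs_spec(c(A = -40)))
  est <- one_traj_estimate(en, B = 200, seed = 1)
  expect_equal(est$value, -40)
  expect_equal(est$se, 0)
  expect_equal(unname(est$components[["dE_internal"]]), 0)
})

test_that("equal adaptation offsets make 1traj-ar coincide with 1traj", {
  map <- c(A = -40, B = -35, C = -30)
  offs <- c(A = 3, B = 3, C = 3)
  en <- gen_esmacs_dataset(noiseless_esmacs_spec(map,
                                                 receptor_adaptation_offsets = offs))
  plain <- esmacs_series(en, protocol = "1traj", B = 200, seed = 1)
  ar <- esmacs_series(en, protocol = "1traj-ar", B = 200, seed = 1)
  expect_equal(ar$dG, plain$dG, tolerance = 1e-9)
})

test_that("planted adaptation offsets are recovered relative to the mean", {
  map <- c(A = -40, B = -35, C = -30)
  offs <- c(A = -4, B = 1, C = 3)
  en <- gen_esmacs_dataset(noiseless_esmacs_spec(map,
                                                 receptor_adaptation_offsets = offs))
  tab <- receptor_adaptation_relative(en, B = 200, seed = 1)
  expect_equal(tab$adaptation[match(c("A", "B", "C"), tab$compound_id)],
               unname(offs - mean(offs)), tolerance = 1e-9)
})

test_that("default compound series mimics the reference series structure", {
  cs <- gen_compound_series(compound_series_spec())
  expect_equal(sum(cs$subgroup == "1", na.rm = TRUE), 36)
  expect_equal(sum(cs$subgroup == "14", na.rm = TRUE), 31)
  expect_equal(sum(cs$subgroup %in% c("1", "14")), 67)
  expect_equal(sum(cs$censored), 5)
  expect_true(all(cs$pIC50[cs$censored] == 5.00))
  # the uncensored activities span the configured range exactly
  expect_equal(pic50_span(cs$pIC50[!cs$censored]), 3.34)
  expect_equal(nrow(cs), 150)
  expect_equal(sum(cs$charged), 10)
  # four subgroup-14 compounds carry the minor fluorine-only category-3
  expect_equal(sum(cs$minor_cat3), 4)
  expect_true(all(cs$categories[cs$minor_cat3] == "1,3,4"))
})

test_that("censoring count and single-compound subgroups behave", {
  cs <- gen_compound_series(compound_series_spec(n_censored = 5))
  expect_equal(sum(cs$censored & cs$pIC50 == 5.00), 5)
  solo <- gen_compound_series(compound_series_spec(
    subgroup_sizes = c(`0` = 1), n_charged = 0, n_censored = 0))
  expect_equal(nrow(solo), 1)
  expect_equal(solo$subgroup, "0")
  expect_equal(solo$compound_id, "L30")
})

test_that("planted affinities reach the requested correlation", {
  cs <- gen_compound_series(compound_series_spec())
  pic50 <- setNames(cs$pIC50, cs$compound_id)
  rs <- replicate(20, {
    g <- plant_affinity_map(pic50, target_r = 0.9,
                            seed = sample.int(1e6, 1))
    cor(g, pic50)
  })
  # negative slope: score anti-correlates with pIC50; Fisher-z interval at
  # n = 150 around |r| = 0.9 is roughly (0.86, 0.93)
  expect_true(all(abs(rs) > 0.8 & abs(rs) < 0.97))
})
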