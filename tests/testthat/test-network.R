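# Perturbation-network diagnostics: path composition, cycle closure,
# signed-error accounting and the common-change offset.

test_that("paths compose with signed edges and quadrature SEs", {
  e <- data.frame(ref_id = c("A", "B"), target_id = c("B", "C"),
                  ddG_calc = c(-4.16, 1.5), se_calc = c(0.3, 0.4))
  one <- compose_path(e, c("A", "B"))
  expect_equal(one$ddG, -4.16)
  expect_equal(one$se, 0.3)
  expect_equal(compose_path(e, c("A", "B", "C"))$ddG, -2.66)
  expect_equal(compose_path(e, c("A", "B", "C"))$se, 0.5)
  # traversing back over the same edge cancels
  expect_equal(compose_path(e, c("A", "B", "A"))$ddG, 0)
  expect_error(compose_path(e, c("A", "C")), "no edge between 'A' and 'C'")
})

test_that("cycle closure sums calc ddG and flags per-leg discrepancies", {
  a <- 1.2
  b <- -0.4
  e <- data.frame(ref_id = c("X", "Y", "Z"), target_id = c("Y", "Z", "X"),
                  ddG_calc = c(a, b, -(a + b)),
                  ddG_exp = c(a, b, -(a + b)))
  rep <- cycle_closure(e, c("X", "Y", "Z"))
  expect_equal(rep$calc_sum, 0, tolerance = 1e-12)
  expect_equal(rep$discrepancy_sum, 0, tolerance = 1e-12)
  # discrepancies (-1.28, +0.46, +0.99) sum to +0.17; two exceed 0.5
  e2 <- e
  e2$ddG_calc <- e2$ddG_exp + c(-1.28, 0.46, 0.99)
  rep2 <- cycle_closure(e2, c("X", "Y", "Z"), flag_threshold = 0.5)
  expect_equal(rep2$discrepancy_sum, 0.17)
  expect_equal(sum(rep2$legs$flagged), 2)
  expect_error(cycle_closure(e, c("X", "Y", "Q")), "no edge")
})

test_that("a planted network closes every hub triangle", {
  compounds <- gen_compound_series(compound_series_spec(
    subgroup_sizes = c(`0` = 1, `1` = 13), n_charged = 0, n_censored = 0,
    seed = 7))
  net <- gen_perturbation_network(compounds, n_edges = 15, n_dual = 3,
                                  seed = 7)
  tri <- hub_triangles(net)
  expect_length(tri, 3)
  for (cy in tri)
    expect_lt(abs(cycle_closure(net, cy)$calc_sum), 1e-9)
  # composition equals the planted endpoint difference along two-step paths
  g <- setNames(pic50_to_dg(compounds$pIC50), compounds$compound_id)
  x <- tri[[1]][3]
  two_step <- compose_path(net, c("L30", "L2", x))
  expect_equal(two_step$ddG, unname(g[x] - g["L30"]), tolerance = 1e-9)
})

test_that("mean signed error follows its defining arithmetic", {
  same <- data.frame(ref_id = "A", target_id = "B", ddG_calc = -2,
                     ddG_exp = -2)
  expect_equal(mean_signed_error(same), 0)
  one <- data.frame(ref_id = "L30", target_id = "L2", ddG_calc = -4.16,
                    ddG_exp = -2.88)
  expect_equal(mean_signed_error(one), -1.28)
  expect_error(mean_signed_error(one[0, ]), "empty")
})

test_that("directional agreement counts matching signs with a tie rule", {
  e <- data.frame(ref_id = letters[1:4], target_id = LETTERS[1:4],
                  ddG_calc = c(-1, 2, -3, 4), ddG_exp = c(-2, 1, -1, 2))
  expect_equal(as.numeric(directional_agreement(e)), 1)
  flip <- e
  flip$ddG_calc <- -flip$ddG_calc
  expect_equal(as.numeric(directional_agreement(flip)), 0)
  # near-zero edges leave the denominator and are counted
  tied <- e
  tied$ddG_calc[1] <- 1e-15
  da <- directional_agreement(tied)
  expect_equal(as.numeric(da), 1)
  expect_equal(attr(da, "n_excluded"), 1)
})

test_that("noisy sign flips track the planted flip rate", {
  set.seed(99)
  n <- 400
  exp_vals <- rep(-1, n)
  noise_sd <- 1 / qnorm(0.94)  # P(calc > 0) = 0.06 for exp = -1
  e <- data.frame(ref_id = paste0("r", 1:n), target_id = paste0("t", 1:n),
                  ddG_calc = exp_vals + rnorm(n, 0, noise_sd),
                  ddG_exp = exp_vals)
  agree <- as.numeric(directional_agreement(e))
  ci <- qbinom(c(0.005, 0.995), n, 0.94) / n
  expect_gte(agree, ci[1])
  expect_lte(agree, ci[2])
})

test_that("offset correction shifts the MSE exactly and keeps Pearson r", {
  net <- planted_network()
  net$ddG_calc <- net$ddG_calc - 1.4  # systematic overestimation
  r_before <- cor(net$ddG_calc, net$ddG_exp)
  out <- apply_common_change_offset(net, 1.28)
  expect_equal(out$mse_before, -1.4, tolerance = 1e-12)
  expect_equal(out$mse_after, out$mse_before + 1.28, tolerance = 1e-12)
  expect_identical(cor(out$edges$ddG_calc, out$edges$ddG_exp), r_before)
  # zero offset is a no-op; fitted mode drives the MSE to zero
  expect_equal(apply_common_change_offset(net, 0)$edges$ddG_calc,
               net$ddG_calc)
  fit <- apply_common_change_offset(net)
  expect_equal(fit$offset_mode, "fitted")
  expect_equal(fit$mse_after, 0, tolerance = 1e-12)
})

test_that("MSE is linear in an applied offset over a random grid", {
  net <- planted_network(seed = 11)
  base <- mean_signed_error(net)
  for (delta in c(-2.5, -0.3, 0.17, 1.28))
    expect_equal(mean_signed_error(apply_common_change_offset(net,
                                                              delta)$edges),
                 base + delta, tolerance = 1e-12)
})

test_that("directional agreement is invariant under positive rescaling", {
  net <- planted_network(seed = 5)
  net$ddG_calc <- net$ddG_calc + rnorm(nrow(net), 0, 0.4)
  a0 <- as.numeric(directional_agreement(net))
  scaled <- net
  scaled$ddG_calc <- 3.7 * scaled$ddG_calc
  scaled$ddG_exp <- 0.2 * scaled$ddG_exp
  expect_equal(as.numeric(directional_agreement(scaled)), a0)
})

test_that("reverse-edge involution reproduces the table bit for bit", {
  net <- planted_network(seed = 3)
  flip <- function(e) {
    data.frame(edge_id = e$edge_id, ref_id = e$target_id,
               target_id = e$ref_id, ddG_calc = -e$ddG_calc,
               se_calc = e$se_calc, ddG_exp = -e$ddG_exp, tags = e$tags,
               stringsAsFactors = FALSE)
  }
  expect_identical(flip(flip(net)), net[names(flip(net))])
})
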