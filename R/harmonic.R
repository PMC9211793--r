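# Harmonic alchemical test system.
#
# A particle in a harmonic well whose spring constant is interpolated
# linearly in the coupling parameter, U(x; lambda) = k(lambda) x^2 / 2 with
# k(lambda) = (1 - lambda) k0 + lambda k1, has a closed-form alchemical free
# energy change, which makes it an exactness oracle for the whole
# thermodynamic-integration machinery: dU/dlambda = (k1 - k0) x^2 / 2 can be
# sampled from the exact Boltzmann distribution at any lambda, and the
# integral of its ensemble average over [0, 1] must equal (kT/2) log(k1/k0).

#' Harmonic alchemical model
#'
#' Defines the analytically solvable one-dimensional alchemical system used
#' to validate the TI pipeline: end-state spring constants `k0` and `k1`
#' (energy/length^2) and thermal energy `kT` (kcal/mol).
#'
#' @param k0 spring constant at lambda = 0; must be > 0.
#' @param k1 spring constant at lambda = 1; must be > 0.
#' @param kT thermal energy in kcal/mol; must be > 0.
#' @param seed integer seed used as the default RNG root for sampling.
#' @return an object of class `harmonic_model`.
#' @seealso [analytic_harmonic_dg()], [sample_harmonic_dudl()]
#' @examples
#' m <- harmonic_model(k0 = 1, k1 = 4, kT = 0.5961)
#' analytic_harmonic_dg(m)
#' @export
harmonic_model <- function(k0, k1, kT, seed = 1L) {
  assert_number(k0, "k0", lower = 0, strict_lower = TRUE)
  assert_number(k1, "k1", lower = 0, strict_lower = TRUE)
  assert_number(kT, "kT", lower = 0, strict_lower = TRUE)
  seed <- assert_count(seed, "seed")
  structure(list(k0 = k0, k1 = k1, kT = kT, seed = seed),
            class = "harmonic_model")
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat(sprintf("Harmonic alchemical model: k0 = %g, k1 = %g, kT = %g kcal/mol\n",
              x$k0, x$k1, x$kT))
  cat(sprintf("  exact dG = %.6f kcal/mol\n", analytic_harmonic_dg(x)))
  invisible(x)
}

#' Exact alchemical free energy of the harmonic model
#'
#' The configurational partition function of a harmonic well is proportional
#' to k^(-1/2), so the free energy change from the `k0` to the `k1` end state
#' is `(kT/2) * log(k1/k0)` exactly.
#'
#' @param model a [harmonic_model()].
#' @return free energy change in kcal/mol.
#' @examples
#' analytic_harmonic_dg(harmonic_model(1, 4, 0.5961))  # (0.5961/2) * log(4)
#' @export
analytic_harmonic_dg <- function(model) {
  if (!inherits(model, "harmonic_model"))
    stopf("'model' must be a harmonic_model")
  (model$kT / 2) * log(model$k1 / model$k0)
}

#' Sample dU/dlambda for the harmonic model at one lambda
#'
#' Draws positions from the exact Boltzmann distribution at coupling `lam`,
#' `x ~ Normal(0, kT / k(lam))` with `k(lam) = (1 - lam) k0 + lam k1`, and
#' returns `(k1 - k0) x^2 / 2` per draw. The expectation of the samples is
#' `(k1 - k0) kT / (2 k(lam))`.
#'
#' @param model a [harmonic_model()].
#' @param lam coupling parameter in `[0, 1]`.
#' @param n number of samples, >= 1.
#' @param seed RNG seed; defaults to the model's seed.
#' @return numeric vector of `n` dU/dlambda samples (kcal/mol).
#' @examples
#' s <- sample_harmonic_dudl(harmonic_model(1, 4, 1), lam = 0, n = 1000)
#' mean(s)  # near (4 - 1) * 1 / (2 * 1) = 1.5
#' @export
sample_harmonic_dudl <- function(model, lam, n, seed = model$seed) {
  if (!inherits(model, "harmonic_model"))
    stopf("'model' must be a harmonic_model")
  assert_number(lam, "lam", lower = 0, upper = 1)
  n <- assert_count(n, "n", lower = 1L)
  k_lam <- (1 - lam) * model$k0 + lam * model$k1
  set.seed(seed)
  x <- stats::rnorm(n, mean = 0, sd = sqrt(model$kT / k_lam))
  0.5 * (model$k1 - model$k0) * x^2
}

#' Generate a dU/dlambda table for one leg of the harmonic model
#'
#' Builds a replica-ensemble dU/dlambda table in the same layout the TI
#' engine consumes from simulation output, sampling every window of the
#' schedule exactly. Replica streams are derived with [child_seed()] so each
#' (window, replica) pair is an independent simulation.
#'
#' @param model a [harmonic_model()].
#' @param lambdas lambda schedule; strictly increasing from 0 to 1.
#' @param n_replicas replicas per window (default 5, the ensemble-TI
#'   standard).
#' @param n_samples samples per replica per window.
#' @param seed RNG root seed; defaults to the model's seed.
#' @param edge_id,leg labels for the output table.
#' @return data.frame with columns `edge_id, leg, lambda, replica, frame,
#'   dudl`.
#' @export
harmonic_leg_windows <- function(model, lambdas = ti_lambda_schedule(),
                                 n_replicas = 5L, n_samples = 1000L,
                                 seed = model$seed, edge_id = "harmonic",
                                 leg = "bound") {
  validate_lambda_schedule(lambdas)
  n_replicas <- assert_count(n_replicas, "n_replicas", lower = 1L)
  n_samples <- assert_count(n_samples, "n_samples", lower = 1L)
  rows <- vector("list", length(lambdas) * n_replicas)
  i <- 0L
  for (w in seq_along(lambdas)) {
    for (r in seq_len(n_replicas)) {
      i <- i + 1L
      s <- sample_harmonic_dudl(model, lambdas[w], n_samples,
                                seed = child_seed(seed, edge_id, leg, w, r))
      rows[[i]] <- data.frame(edge_id = edge_id, leg = leg,
                              lambda = lambdas[w], replica = r,
                              frame = seq_len(n_samples), dudl = s)
    }
  }
  do.call(rbind, rows)
}
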