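# Ensemble thermodynamic integration.
#
# A relative binding free energy (ddG) is assembled from two alchemical legs
# (ligand bound to the receptor, ligand free in solvent). For each leg an
# ensemble of independent replicas samples dU/dlambda at every window of the
# lambda schedule; the leg dG is the trapezoidal quadrature of the
# between-replica window means, and its uncertainty comes from bootstrap
# resampling of replicas independently per window (each window is an
# independent set of simulations).

#' Default lambda schedule
#'
#' A 13-window schedule, dense near the end points where the integrand of an
#' alchemical transformation changes fastest: 0, 0.05, 0.1, 0.2, ..., 0.9,
#' 0.95, 1.
#'
#' @return numeric vector of lambda values.
#' @export
ti_lambda_schedule <- function() {
  c(0, 0.05, seq(0.1, 0.9, by = 0.1), 0.95, 1)
}

validate_lambda_schedule <- function(lambdas) {
  if (!is.numeric(lambdas) || length(lambdas) < 2L || anyNA(lambdas))
    stopf("lambda schedule must be a numeric vector of length >= 2")
  if (any(duplicated(lambdas)))
    stopf("lambda schedule contains duplicate values")
  if (is.unsorted(lambdas, strictly = TRUE))
    stopf("lambda schedule must be strictly increasing")
  if (abs(lambdas[1L]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12)
    stopf("lambda schedule must start at 0 and end at 1 (got [%g, %g])",
          lambdas[1L], lambdas[length(lambdas)])
  invisible(lambdas)
}

# composite-trapezoid weights; sum to the span of the schedule (1 on [0, 1])
trapezoid_weights <- function(lambdas) {
  n <- length(lambdas)
  d <- diff(lambdas)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

#' Mean dU/dlambda of one window
#'
#' Averages within each replica first, then takes the unweighted mean across
#' replicas, so an imbalance in sample counts between replicas cannot bias
#' the window mean.
#'
#' @param samples a list of numeric vectors, one per replica, each the
#'   dU/dlambda samples of that replica at this window.
#' @return list with `mean` (scalar, kcal/mol) and `replica_means`.
#' @examples
#' window_mean(list(c(0.9, 1.1), 2, 3))$mean  # 2
#' @export
window_mean <- function(samples) {
  if (!is.list(samples) || length(samples) < 1L)
    stopf("'samples' must be a non-empty list of per-replica sample vectors")
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!is.numeric(s) || length(s) < 1L)
      stopf("replica %d has no samples", i)
    if (!all(is.finite(s)))
      stopf("replica %d contains non-finite dU/dlambda values", i)
  }
  rm_ <- vapply(samples, mean, numeric(1L))
  list(mean = mean(rm_), replica_means = rm_)
}

#' Trapezoidal quadrature of window means over the lambda schedule
#'
#' @param lambdas strictly increasing lambda values spanning `[0, 1]`.
#' @param means mean dU/dlambda per window, same length as `lambdas`.
#' @return the integral, kcal/mol.
#' @examples
#' integrate_ti(c(0, 0.5, 1), c(0, 1, 2))  # exact for a linear integrand: 1
#' @export
integrate_ti <- function(lambdas, means) {
  validate_lambda_schedule(lambdas)
  if (!is.numeric(means) || length(means) != length(lambdas))
    stopf("'means' must be numeric and match the lambda schedule length")
  if (!all(is.finite(means))) stopf("'means' contains non-finite values")
  sum(trapezoid_weights(lambdas) * means)
}

#' Free energy of one alchemical leg with bootstrap uncertainty
#'
#' Computes per-window replica means, integrates the across-replica window
#' means with [integrate_ti()], and estimates the standard error by
#' resampling replicas with replacement independently in every window and
#' re-integrating each bootstrap realization.
#'
#' @param windows data.frame with columns `lambda`, `replica`, `dudl` (and
#'   optionally `edge_id`, `leg`, which must then be single-valued) holding
#'   every sample of one leg.
#' @param B number of bootstrap resamples (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `leg_result`: list with `edge_id`, `leg`,
#'   `dG`, `se`, `n_replicas`, and `window_means` (data.frame `lambda`,
#'   `mean`, `sd_between`, `n_replicas`).
#' @export
leg_dg <- function(windows, B = 5000L, seed = 1L) {
  assert_columns(windows, c("lambda", "replica", "dudl"), "dU/dlambda table")
  B <- assert_count(B, "B", lower = 100L)
  edge_id <- if ("edge_id" %in% names(windows))
    unique(windows$edge_id) else NA_character_
  leg <- if ("leg" %in% names(windows)) unique(windows$leg) else NA_character_
  if (length(edge_id) != 1L || length(leg) != 1L)
    stopf("'windows' must contain a single edge and leg (got %d edge(s), %d leg(s))",
          length(edge_id), length(leg))
  if (!all(is.finite(windows$dudl)))
    stopf("non-finite dU/dlambda values in leg '%s'", leg)

  lambdas <- sort(unique(windows$lambda))
  validate_lambda_schedule(lambdas)
  by_window <- split(windows, factor(windows$lambda, levels = lambdas))
  # canonical replica sort so bootstrap draws do not depend on row order
  rep_means <- lapply(by_window, function(w)
    sort(unname(replica_mean_vector(w$dudl, w$replica))))
  n_rep <- vapply(rep_means, length, integer(1L))
  if (length(unique(n_rep)) > 1L)
    warnf("replica counts differ across windows (%s); resampling is per-window",
          paste(unique(n_rep), collapse = ", "))

  means <- vapply(rep_means, mean, numeric(1L))
  sds <- vapply(rep_means, function(x) if (length(x) > 1L) stats::sd(x) else 0,
                numeric(1L))
  w <- trapezoid_weights(lambdas)
  dG <- sum(w * means)

  set.seed(seed)
  boot <- matrix(0, nrow = B, ncol = length(lambdas))
  for (j in seq_along(lambdas)) {
    rm_ <- rep_means[[j]]
    n <- length(rm_)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    boot[, j] <- rowMeans(matrix(rm_[idx], nrow = B))
  }
  se <- stats::sd(as.vector(boot %*% w))

  structure(list(edge_id = edge_id, leg = leg, dG = dG, se = se,
                 n_replicas = max(n_rep),
                 window_means = data.frame(lambda = lambdas, mean = means,
                                           sd_between = sds,
                                           n_replicas = n_rep,
                                           row.names = NULL)),
            class = "leg_result")
}

#' @export
print.leg_result <- function(x, ...) {
  cat(sprintf("TI leg '%s' of edge '%s': dG = %.4f +/- %.4f kcal/mol (%d windows, %d replicas)\n",
              x$leg, x$edge_id, x$dG, x$se, nrow(x$window_means),
              x$n_replicas))
  invisible(x)
}

#' Assemble a relative binding free energy from two legs
#'
#' `ddG = dG(bound) - dG(free)`, with the two bootstrap standard errors
#' combined in quadrature. Sign convention: `ddG = dG_bind(target) -
#' dG_bind(ref)`, so a negative value means the transformation improves
#' binding.
#'
#' @param bound,free `leg_result` objects for the bound and free legs of the
#'   same edge.
#' @return an object of class `edge_result`: list with `edge_id`, `ddG`,
#'   `se`, `bound`, `free`.
#' @export
edge_ddg <- function(bound, free) {
  if (!inherits(bound, "leg_result") || !inherits(free, "leg_result"))
    stopf("'bound' and 'free' must be leg_result objects")
  if (!identical(bound$edge_id, free$edge_id))
    stopf("legs belong to different edges ('%s' vs '%s')",
          bound$edge_id, free$edge_id)
  if (identical(bound$leg, free$leg))
    stopf("both inputs are '%s' legs", bound$leg)
  structure(list(edge_id = bound$edge_id,
                 ddG = bound$dG - free$dG,
                 se = sqrt(bound$se^2 + free$se^2),
                 bound = bound, free = free),
            class = "edge_result")
}

#' @export
print.edge_result <- function(x, ...) {
  cat(sprintf("Edge '%s': ddG = %.4f +/- %.4f kcal/mol\n",
              x$edge_id, x$ddG, x$se))
  invisible(x)
}

#' Run the TI analysis for every edge of a dU/dlambda table
#'
#' Splits the table by edge and leg, computes each leg with [leg_dg()] and
#' assembles [edge_ddg()] per edge.
#'
#' @param dudl a data.frame in the TI sample schema (`edge_id, leg, lambda,
#'   replica, frame, dudl`) or a `ti_dataset` from [gen_ti_dataset()].
#' @param edges optional data.frame mapping `edge_id` to `ref_id`,
#'   `target_id`; taken from the dataset when available.
#' @param B,seed bootstrap parameters, passed to [leg_dg()]; each leg gets a
#'   [child_seed()]-derived stream.
#' @return data.frame with one row per edge: `edge_id, ref_id, target_id,
#'   ddG_calc, se_calc, n_windows, n_replicas`.
#' @export
ties_analyze <- function(dudl, edges = NULL, B = 5000L, seed = 1L) {
  if (inherits(dudl, "ti_dataset")) {
    edges <- edges %||% dudl$edges
    dudl <- dudl$dudl
  }
  assert_columns(dudl, c("edge_id", "leg", "lambda", "replica", "dudl"),
                 "TI table")
  bad <- setdiff(unique(dudl$leg), c("bound", "free"))
  if (length(bad))
    stopf("unknown leg label(s): %s", paste(bad, collapse = ", "))
  ids <- unique(dudl$edge_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ed <- dudl[dudl$edge_id == ids[i], , drop = FALSE]
    legs <- lapply(c(bound = "bound", free = "free"), function(l) {
      sub <- ed[ed$leg == l, , drop = FALSE]
      if (!nrow(sub)) stopf("edge '%s' has no '%s' leg", ids[i], l)
      leg_dg(sub, B = B, seed = child_seed(seed, ids[i], l, "boot"))
    })
    res <- edge_ddg(legs$bound, legs$free)
    ref <- target <- NA_character_
    if (!is.null(edges)) {
      m <- match(ids[i], edges$edge_id)
      if (!is.na(m)) {
        ref <- edges$ref_id[m]
        target <- edges$target_id[m]
      }
    }
    out[[i]] <- data.frame(edge_id = ids[i], ref_id = ref, target_id = target,
                           ddG_calc = res$ddG, se_calc = res$se,
                           n_windows = nrow(legs$bound$window_means),
                           n_replicas = legs$bound$n_replicas)
  }
  do.call(rbind, out)
}
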