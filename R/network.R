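# Perturbation-network diagnostics.
#
# Relative free energies are state functions: the signed sum of ddG around
# any closed cycle of transformations must vanish. A nonzero cycle sum
# (hysteresis) diagnoses sampling or setup error, but a zero sum is only a
# necessary condition — per-leg calculated-minus-experimental discrepancies
# can cancel around the cycle, so they are reported and flagged
# individually. Systematic error shared by a set of edges (a common
# alchemical change) shows up as a nonzero mean signed error and can be
# removed by a constant offset, which shifts the MSE exactly and leaves
# correlations untouched.

validate_edge_table <- function(edges, need_exp = FALSE) {
  assert_columns(edges, c("ref_id", "target_id", "ddG_calc"), "edge table")
  if (any(edges$ref_id == edges$target_id))
    stopf("edge table contains self-edges")
  if (need_exp) {
    if (!"ddG_exp" %in% names(edges) || anyNA(edges$ddG_exp))
      stopf("experimental ddG values are required and must be complete")
  }
  invisible(edges)
}

# locate the edge joining a -> b, in either orientation; returns
# list(row, sign) or NULL
find_edge <- function(edges, a, b) {
  fwd <- which(edges$ref_id == a & edges$target_id == b)
  if (length(fwd)) return(list(row = fwd[1L], sign = 1))
  rev <- which(edges$ref_id == b & edges$target_id == a)
  if (length(rev)) return(list(row = rev[1L], sign = -1))
  NULL
}

#' Compose relative free energies along a path
#'
#' Chains edges head-to-tail through the given node sequence; an edge
#' traversed against its stored direction contributes with negated sign.
#' Standard errors combine in quadrature.
#'
#' @param edges edge table (`ref_id, target_id, ddG_calc`, optional
#'   `se_calc`).
#' @param path character vector of compound ids, length >= 2.
#' @return list with `ddG` and `se` (kcal/mol).
#' @examples
#' e <- data.frame(ref_id = c("A", "B"), target_id = c("B", "C"),
#'                 ddG_calc = c(-4.16, 1.5), se_calc = 0)
#' compose_path(e, c("A", "B", "C"))$ddG  # -2.66
#' @export
compose_path <- function(edges, path) {
  validate_edge_table(edges)
  if (length(path) < 2L) stopf("'path' needs at least two nodes")
  se2 <- 0
  total <- 0
  for (i in seq_len(length(path) - 1L)) {
    hit <- find_edge(edges, path[i], path[i + 1L])
    if (is.null(hit))
      stopf("no edge between '%s' and '%s' in either orientation",
            path[i], path[i + 1L])
    total <- total + hit$sign * edges$ddG_calc[hit$row]
    if ("se_calc" %in% names(edges)) se2 <- se2 + edges$se_calc[hit$row]^2
  }
  list(ddG = total, se = sqrt(se2))
}

#' Cycle-closure (hysteresis) report
#'
#' Traverses a closed cycle of transformations, summing the calculated ddG
#' (the hysteresis) and, when experimental values are present, the per-leg
#' calculated-minus-experimental discrepancies. Legs whose discrepancy
#' magnitude exceeds `flag_threshold` are flagged even when the cycle sum is
#' small, since a near-zero hysteresis can arise from cancellation between
#' legs.
#'
#' @param edges edge table.
#' @param cycle node sequence; closed automatically if the last node differs
#'   from the first.
#' @param flag_threshold per-leg discrepancy flag threshold, kcal/mol
#'   (default 0.5, around typical alchemical reproducibility).
#' @return object of class `cycle_report`: list with `nodes`, `legs`
#'   (data.frame `from, to, ddG_calc, ddG_exp, discrepancy, flagged`),
#'   `calc_sum`, `discrepancy_sum`, `flag_threshold`.
#' @export
cycle_closure <- function(edges, cycle, flag_threshold = 0.5) {
  validate_edge_table(edges)
  assert_number(flag_threshold, "flag_threshold", lower = 0)
  if (length(cycle) < 3L) stopf("a cycle needs at least 3 nodes")
  if (cycle[1L] != cycle[length(cycle)]) cycle <- c(cycle, cycle[1L])
  has_exp <- "ddG_exp" %in% names(edges)
  n_leg <- length(cycle) - 1L
  legs <- data.frame(from = cycle[-length(cycle)], to = cycle[-1L],
                     ddG_calc = NA_real_, ddG_exp = NA_real_,
                     discrepancy = NA_real_, flagged = FALSE)
  for (i in seq_len(n_leg)) {
    hit <- find_edge(edges, legs$from[i], legs$to[i])
    if (is.null(hit))
      stopf("cycle leg '%s' -> '%s' has no edge", legs$from[i], legs$to[i])
    legs$ddG_calc[i] <- hit$sign * edges$ddG_calc[hit$row]
    if (has_exp) {
      legs$ddG_exp[i] <- hit$sign * edges$ddG_exp[hit$row]
      legs$discrepancy[i] <- legs$ddG_calc[i] - legs$ddG_exp[i]
      legs$flagged[i] <- abs(legs$discrepancy[i]) > flag_threshold
    }
  }
  structure(list(nodes = cycle, legs = legs,
                 calc_sum = sum(legs$ddG_calc),
                 discrepancy_sum = if (has_exp) sum(legs$discrepancy)
                 else NA_real_,
                 flag_threshold = flag_threshold),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat("Cycle:", paste(x$nodes, collapse = " -> "), "\n")
  cat(sprintf("  hysteresis (sum of calculated ddG): %+.4f kcal/mol\n",
              x$calc_sum))
  if (!is.na(x$discrepancy_sum))
    cat(sprintf("  sum of (calc - exp) discrepancies: %+.4f kcal/mol; %d leg(s) above %.2f kcal/mol\n",
                x$discrepancy_sum, sum(x$legs$flagged), x$flag_threshold))
  invisible(x)
}

#' Enumerate triangles through a pair of hub compounds
#'
#' Finds every compound connected to both hubs (in any edge orientation) and
#' returns the corresponding hub1 -> hub2 -> compound -> hub1 cycles; the
#' hub-to-hub edge must exist.
#'
#' @param edges edge table.
#' @param hubs character vector of the two hub ids.
#' @return list of node vectors, each a closed triangle.
#' @export
hub_triangles <- function(edges, hubs = c("L30", "L2")) {
  validate_edge_table(edges)
  if (length(hubs) != 2L) stopf("'hubs' must have length 2")
  if (is.null(find_edge(edges, hubs[1L], hubs[2L])))
    stopf("no edge between hubs '%s' and '%s'", hubs[1L], hubs[2L])
  nodes <- setdiff(unique(c(edges$ref_id, edges$target_id)), hubs)
  touches <- function(x, h)
    !is.null(find_edge(edges, h, x))
  dual <- nodes[vapply(nodes, function(x)
    touches(x, hubs[1L]) && touches(x, hubs[2L]), logical(1L))]
  lapply(dual, function(x) c(hubs[1L], hubs[2L], x, hubs[1L]))
}

#' Mean signed error of calculated versus experimental ddG
#'
#' Mean over edges of `ddG_calc - ddG_exp`. Negative values mean the
#' calculation is systematically more favourable (more negative) than
#' experiment — an overestimated binding improvement.
#'
#' @param edges non-empty edge table with complete `ddG_exp`.
#' @return MSE in kcal/mol.
#' @examples
#' mean_signed_error(data.frame(ref_id = "L30", target_id = "L2",
#'                              ddG_calc = -4.16, ddG_exp = -2.88))  # -1.28
#' @export
mean_signed_error <- function(edges) {
  validate_edge_table(edges, need_exp = TRUE)
  if (!nrow(edges)) stopf("edge subset is empty")
  mean(edges$ddG_calc - edges$ddG_exp)
}

#' Fraction of edges whose calculated ddG agrees in sign with experiment
#'
#' Edges where either value has magnitude below `tol` are excluded from the
#' denominator (a sign is not defined there); the number excluded is
#' attached as attribute `n_excluded`.
#'
#' @param edges non-empty edge table with complete `ddG_exp`.
#' @param tol magnitude below which a ddG is treated as zero (default
#'   1e-12).
#' @return fraction in `[0, 1]` with attribute `n_excluded`.
#' @export
directional_agreement <- function(edges, tol = 1e-12) {
  validate_edge_table(edges, need_exp = TRUE)
  if (!nrow(edges)) stopf("edge subset is empty")
  keep <- abs(edges$ddG_calc) >= tol & abs(edges$ddG_exp) >= tol
  if (!any(keep))
    stopf("all %d edges have a ddG below the sign tolerance", nrow(edges))
  agree <- sign(edges$ddG_calc[keep]) == sign(edges$ddG_exp[keep])
  structure(mean(agree), n_excluded = sum(!keep))
}

#' Apply a common-change offset to calculated ddG values
#'
#' Shifts every calculated ddG by `offset` and reports the mean signed error
#' before and after. The identity `MSE_after = MSE_before + offset` is exact
#' and asserted; any correlation between calculated and experimental values
#' is untouched by the shift.
#'
#' @param edges edge table with complete `ddG_exp`.
#' @param offset shift in kcal/mol; if `NULL`, fitted as `-MSE` of the
#'   subset (which drives the post-correction MSE to zero). The mode used is
#'   recorded in the result.
#' @return list with `edges` (shifted table), `offset`, `offset_mode`
#'   (`"supplied"` or `"fitted"`), `mse_before`, `mse_after`.
#' @export
apply_common_change_offset <- function(edges, offset = NULL) {
  validate_edge_table(edges, need_exp = TRUE)
  if (!nrow(edges)) stopf("edge subset is empty")
  mse_before <- mean_signed_error(edges)
  mode <- if (is.null(offset)) "fitted" else "supplied"
  if (is.null(offset)) offset <- -mse_before
  assert_number(offset, "offset")
  out <- edges
  out$ddG_calc <- edges$ddG_calc + offset
  mse_after <- mean_signed_error(out)
  stopifnot(abs(mse_after - (mse_before + offset)) < 1e-9)
  list(edges = out, offset = offset, offset_mode = mode,
       mse_before = mse_before, mse_after = mse_after)
}
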