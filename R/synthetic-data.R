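# Synthetic inputs with planted ground truth.
#
# Every table the analysis consumes can be generated here with known
# answers: dU/dlambda samples whose trapezoidal integrals differ by a
# planted ddG, per-frame MMPBSA component tables whose interaction mean is a
# planted binding score, and a congeneric compound series with subgroup
# structure, charge classes and censoring. All generators are pure functions
# of their spec: the same seed reproduces identical tables, and per-stream
# child seeds mean that enlarging an ensemble never perturbs existing
# replicas.

#' Specification of a synthetic ensemble-TI series
#'
#' @param edges data.frame with columns `ref_id`, `target_id`, `ddg_true`
#'   (planted relative binding free energy, kcal/mol).
#' @param lambda_schedule strictly increasing lambda values from 0 to 1.
#' @param n_replicas replicas per window (default 5, the ensemble-TI
#'   standard).
#' @param n_samples_per_window dU/dlambda samples per replica per window
#'   (default 400, one per saved frame of a 4 ns production run).
#' @param within_replica_sd per-sample noise SD, kcal/mol.
#' @param between_replica_sd SD of the per-(edge, leg, window, replica)
#'   offset, kcal/mol.
#' @param curvature curvature of the quadratic mean profile in lambda.
#' @param seed RNG root seed.
#' @return object of class `ti_series_spec`.
#' @export
ti_series_spec <- function(edges, lambda_schedule = ti_lambda_schedule(),
                           n_replicas = 5L, n_samples_per_window = 400L,
                           within_replica_sd = 0.3, between_replica_sd = 0.2,
                           curvature = 4, seed = 1L) {
  assert_columns(edges, c("ref_id", "target_id", "ddg_true"), "edge table")
  if (any(edges$ref_id == edges$target_id))
    stopf("self-edges are not allowed")
  validate_lambda_schedule(lambda_schedule)
  structure(list(edges = edges, lambda_schedule = lambda_schedule,
                 n_replicas = assert_count(n_replicas, "n_replicas", 2L),
                 n_samples_per_window = assert_count(n_samples_per_window,
                                                     "n_samples_per_window",
                                                     1L),
                 within_replica_sd = assert_number(within_replica_sd,
                                                  "within_replica_sd", 0),
                 between_replica_sd = assert_number(between_replica_sd,
                                                    "between_replica_sd", 0),
                 curvature = assert_number(curvature, "curvature"),
                 seed = assert_count(seed, "seed")),
            class = "ti_series_spec")
}

# quadratic profile in lambda whose *trapezoidal* integral over the given
# schedule equals dg exactly, so the planted truth is the
# quadrature-consistent target and noiseless recovery is exact regardless of
# quadrature error
ti_mean_profile <- function(lambdas, dg, curvature) {
  shape <- curvature * (lambdas - 0.5)^2
  shape + (dg - sum(trapezoid_weights(lambdas) * shape))
}

#' Generate dU/dlambda tables for every edge of a TI series
#'
#' For each edge, smooth per-window mean profiles are built for the bound
#' and free legs such that their trapezoidal integrals differ by exactly the
#' planted `ddg_true`. Each (edge, leg, window, replica) stream then gets a
#' zero-mean Gaussian replica offset (SD `between_replica_sd`) plus
#' per-sample noise (SD `within_replica_sd`); windows are independent, as in
#' ensemble-TI practice where every window is a separate simulation.
#'
#' @param spec a [ti_series_spec()].
#' @return object of class `ti_dataset`: list with `dudl` (data.frame
#'   `edge_id, leg, lambda, replica, frame, dudl`), `edges` (edge table with
#'   `edge_id` and the planted per-leg dG values), and `spec`.
#' @export
gen_ti_dataset <- function(spec) {
  if (!inherits(spec, "ti_series_spec")) stopf("'spec' must be a ti_series_spec")
  lambdas <- spec$lambda_schedule
  edges <- spec$edges
  edges$edge_id <- paste(edges$ref_id, edges$target_id, sep = ">")
  # deterministic free-leg dG per edge; bound leg carries the planted ddG
  u <- vapply(edges$edge_id,
              function(e) child_seed(spec$seed, e, "dg_free") / 2147483563,
              numeric(1L))
  edges$dg_free <- -8 + 4 * u
  edges$dg_bound <- edges$dg_free + edges$ddg_true

  n <- spec$n_samples_per_window
  blocks <- vector("list", nrow(edges) * 2L * length(lambdas) *
                     spec$n_replicas)
  i <- 0L
  for (e in seq_len(nrow(edges))) {
    for (leg in c("bound", "free")) {
      dg <- if (leg == "bound") edges$dg_bound[e] else edges$dg_free[e]
      prof <- ti_mean_profile(lambdas, dg, spec$curvature)
      for (w in seq_along(lambdas)) {
        for (r in seq_len(spec$n_replicas)) {
          i <- i + 1L
          set.seed(child_seed(spec$seed, edges$edge_id[e], leg, w, r))
          offset <- if (spec$between_replica_sd > 0)
            stats::rnorm(1L, 0, spec$between_replica_sd) else 0
          noise <- if (spec$within_replica_sd > 0)
            stats::rnorm(n, 0, spec$within_replica_sd) else numeric(n)
          blocks[[i]] <- data.frame(edge_id = edges$edge_id[e], leg = leg,
                                    lambda = lambdas[w], replica = r,
                                    frame = seq_len(n),
                                    dudl = prof[w] + offset + noise)
        }
      }
    }
  }
  structure(list(dudl = do.call(rbind, blocks), edges = edges, spec = spec),
            class = "ti_dataset")
}

#' Specification of a synthetic ESMACS compound series
#'
#' @param true_affinity_map named numeric vector: planted per-compound mean
#'   interaction + solvation free energy (the quantity 1traj estimates),
#'   kcal/mol.
#' @param receptor_adaptation_offsets named numeric vector of per-compound
#'   receptor-energy offsets, kcal/mol (default all 0); recovered by
#'   [receptor_adaptation_relative()] relative to their mean.
#' @param n_replicas replicas per compound (default 25).
#' @param n_frames production frames per replica (default 400, one frame per
#'   10 ps of a 4 ns run).
#' @param component_noise_sds named per-component SD of the per-frame noise
#'   on receptor and ligand components, kcal/mol.
#' @param between_replica_sd SD of the per-(compound, replica) offset on the
#'   interaction energy, kcal/mol.
#' @param interaction_frame_sd per-frame SD of the interaction energy,
#'   kcal/mol.
#' @param slope,intercept linear link between pIC50 and planted score used
#'   by [plant_affinity_map()] (default slope -1.3726 kcal/mol per log unit,
#'   i.e. dG = -RT ln10 pIC50 at 300 K).
#' @param seed RNG root seed.
#' @return object of class `esmacs_series_spec`.
#' @export
esmacs_series_spec <- function(true_affinity_map,
                               receptor_adaptation_offsets = NULL,
                               n_replicas = 25L, n_frames = 400L,
                               component_noise_sds = c(E_vdw = 1, E_ele = 1.5,
                                                       E_internal = 2,
                                                       G_PB = 1.5,
                                                       G_SA = 0.2),
                               between_replica_sd = 1.0,
                               interaction_frame_sd = 2.0,
                               slope = -1.3726, intercept = 0, seed = 1L) {
  if (is.null(names(true_affinity_map)) || !is.numeric(true_affinity_map) ||
      !length(true_affinity_map))
    stopf("'true_affinity_map' must be a non-empty named numeric vector")
  if (is.null(receptor_adaptation_offsets)) {
    receptor_adaptation_offsets <- stats::setNames(
      numeric(length(true_affinity_map)), names(true_affinity_map))
  }
  missing <- setdiff(names(true_affinity_map),
                     names(receptor_adaptation_offsets))
  if (length(missing))
    stopf("receptor_adaptation_offsets missing compound(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  if (!all(ENERGY_COMPONENTS %in% names(component_noise_sds)) ||
      any(component_noise_sds < 0))
    stopf("'component_noise_sds' must name all of %s with values >= 0",
          paste(ENERGY_COMPONENTS, collapse = ", "))
  structure(list(true_affinity_map = true_affinity_map,
                 receptor_adaptation_offsets = receptor_adaptation_offsets,
                 n_replicas = assert_count(n_replicas, "n_replicas", 2L),
                 n_frames = assert_count(n_frames, "n_frames", 1L),
                 component_noise_sds = component_noise_sds[ENERGY_COMPONENTS],
                 between_replica_sd = assert_number(between_replica_sd,
                                                    "between_replica_sd", 0),
                 interaction_frame_sd = assert_number(interaction_frame_sd,
                                                      "interaction_frame_sd",
                                                      0),
                 slope = assert_number(slope, "slope"),
                 intercept = assert_number(intercept, "intercept"),
                 seed = assert_count(seed, "seed")),
            class = "esmacs_series_spec")
}

# baseline component means for the receptor and ligand species; arbitrary
# but realistic magnitudes for a solvated kinase domain and a small molecule
RECEPTOR_BASE <- c(E_vdw = -780, E_ele = -6400, E_internal = 4900,
                   G_PB = -2900, G_SA = 230)
LIGAND_BASE <- c(E_vdw = -15, E_ele = -40, E_internal = 85,
                 G_PB = -30, G_SA = 5)
# split of the planted interaction + solvation mean across components;
# E_internal gets none, so 1traj's internal-energy cancellation is exact
INTERACTION_SPLIT <- c(E_vdw = 0.45, E_ele = 0.35, E_internal = 0,
                       G_PB = 0.15, G_SA = 0.05)

#' Generate per-frame MMPBSA energy tables for an ESMACS series
#'
#' Emulates single-trajectory extraction: receptor and ligand frames are
#' generated first, an interaction term is added whose per-compound mean
#' equals the planted affinity, and the complex frame components are the
#' exact sum `receptor + ligand + interaction`, component by component. The
#' planted receptor adaptation offset is added to the receptor `E_ele`
#' baseline. Between-replica variability enters through a per-(compound,
#' replica) offset on the interaction `E_vdw`.
#'
#' @param spec an [esmacs_series_spec()].
#' @return data.frame in the energy schema: `compound_id, species, replica,
#'   frame, E_vdw, E_ele, E_internal, G_PB, G_SA`.
#' @export
gen_esmacs_dataset <- function(spec) {
  if (!inherits(spec, "esmacs_series_spec"))
    stopf("'spec' must be an esmacs_series_spec")
  ids <- names(spec$true_affinity_map)
  n_f <- spec$n_frames
  sds <- spec$component_noise_sds
  out <- vector("list", length(ids) * 3L)
  i <- 0L
  for (cid in ids) {
    base_rec <- RECEPTOR_BASE
    base_rec["E_ele"] <- base_rec["E_ele"] +
      spec$receptor_adaptation_offsets[[cid]]
    int_mean <- INTERACTION_SPLIT * spec$true_affinity_map[[cid]]
    rec <- lig <- cpx <- vector("list", spec$n_replicas)
    for (r in seq_len(spec$n_replicas)) {
      mk_species <- function(base, tag) {
        set.seed(child_seed(spec$seed, cid, tag, r))
        m <- matrix(stats::rnorm(n_f * 5L, 0, rep(sds, each = n_f)),
                    nrow = n_f)
        sweep(m, 2L, base, `+`)
      }
      m_rec <- mk_species(base_rec, "receptor")
      m_lig <- mk_species(LIGAND_BASE, "ligand")
      set.seed(child_seed(spec$seed, cid, "interaction", r))
      rep_offset <- if (spec$between_replica_sd > 0)
        stats::rnorm(1L, 0, spec$between_replica_sd) else 0
      frame_noise <- if (spec$interaction_frame_sd > 0)
        stats::rnorm(n_f, 0, spec$interaction_frame_sd) else numeric(n_f)
      m_int <- matrix(rep(int_mean, each = n_f), nrow = n_f)
      m_int[, 1L] <- m_int[, 1L] + rep_offset + frame_noise
      rec[[r]] <- m_rec
      lig[[r]] <- m_lig
      cpx[[r]] <- m_rec + m_lig + m_int
    }
    mk_df <- function(mats, sp) {
      m <- do.call(rbind, mats)
      colnames(m) <- ENERGY_COMPONENTS
      cbind(data.frame(compound_id = cid, species = sp,
                       replica = rep(seq_len(spec$n_replicas), each = n_f),
                       frame = rep(seq_len(n_f), spec$n_replicas)),
            as.data.frame(m))
    }
    out[[i <- i + 1L]] <- mk_df(cpx, "complex")
    out[[i <- i + 1L]] <- mk_df(rec, "receptor")
    out[[i <- i + 1L]] <- mk_df(lig, "ligand")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant per-compound affinities correlated with pIC50
#'
#' Builds a `true_affinity_map` linearly linked to pIC50 (`score = intercept
#' + slope * pIC50`) plus Gaussian scatter sized so that the population
#' Pearson correlation between score and pIC50 is `target_r` (given the
#' empirical SD of the supplied pIC50 values).
#'
#' @param pic50 named numeric vector of pIC50 values (names = compound ids).
#' @param target_r desired population correlation magnitude, in (0, 1].
#' @param slope,intercept linear link (defaults: -1.3726 kcal/mol per log
#'   unit, 0).
#' @param seed RNG seed.
#' @return named numeric vector of planted scores, kcal/mol.
#' @export
plant_affinity_map <- function(pic50, target_r = 0.9, slope = -1.3726,
                               intercept = 0, seed = 1L) {
  if (is.null(names(pic50)) || !is.numeric(pic50))
    stopf("'pic50' must be a named numeric vector")
  assert_number(target_r, "target_r", lower = 0, upper = 1,
                strict_lower = TRUE)
  signal_sd <- abs(slope) * stats::sd(pic50)
  noise_sd <- signal_sd * sqrt(1 / target_r^2 - 1)
  set.seed(seed)
  stats::setNames(intercept + slope * pic50 +
                    stats::rnorm(length(pic50), 0, noise_sd), names(pic50))
}

#' Specification of a synthetic congeneric compound series
#'
#' The default fixture mimics a 150-compound kinase-inhibitor lead
#' optimization series: 140 electrostatically neutral compounds split into
#' subgroups by modification position (codes 0, 1, 2, 3, 4, 14, 34), plus 10
#' charged compounds, with pIC50 between 5.03 and 8.37 and 5 compounds
#' censored at the assay floor (pIC50 = 5.00).
#'
#' @param subgroup_sizes named integer vector, subgroup code -> count.
#' @param pic50_range numeric length 2, the uncensored pIC50 range.
#' @param n_charged number of (extra) charged compounds.
#' @param n_censored number of compounds with no detected activity; they are
#'   assigned pIC50 = 5.00 and flagged.
#' @param n_minor_cat3 how many subgroup-14 compounds additionally carry the
#'   minor (fluorine-only) category-3 modification (default 4).
#' @param seed RNG seed.
#' @return object of class `compound_series_spec`.
#' @export
compound_series_spec <- function(subgroup_sizes = c(`0` = 1, `1` = 36,
                                                    `2` = 7, `3` = 25,
                                                    `4` = 26, `14` = 31,
                                                    `34` = 14),
                                 pic50_range = c(5.03, 8.37),
                                 n_charged = 10L, n_censored = 5L,
                                 n_minor_cat3 = 4L, seed = 1L) {
  if (is.null(names(subgroup_sizes)) || any(subgroup_sizes < 0))
    stopf("'subgroup_sizes' must be a named vector of counts >= 0")
  bad <- setdiff(names(subgroup_sizes), c("0", "1", "2", "3", "4", "14", "34"))
  if (length(bad)) stopf("unknown subgroup code(s): %s",
                         paste(bad, collapse = ", "))
  if (length(pic50_range) != 2L || pic50_range[1L] >= pic50_range[2L])
    stopf("'pic50_range' must be (min, max) with min < max")
  structure(list(subgroup_sizes = subgroup_sizes,
                 pic50_range = pic50_range,
                 n_charged = assert_count(n_charged, "n_charged"),
                 n_censored = assert_count(n_censored, "n_censored"),
                 n_minor_cat3 = assert_count(n_minor_cat3, "n_minor_cat3"),
                 seed = assert_count(seed, "seed")),
            class = "compound_series_spec")
}

subgroup_categories <- function(code) {
  switch(code,
         "0" = integer(0), "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
         "14" = c(1L, 4L), "34" = c(3L, 4L),
         stopf("unknown subgroup code '%s'", code))
}

#' Generate a congeneric compound series
#'
#' Assigns compound ids, subgroup codes with consistent modification
#' categories, uniform pIC50 values (the uncensored extremes are pinned at
#' the range limits), charge classes and censoring flags. The subgroup-0
#' compound is the reference `L30`; the first subgroup-1 compound is `L2`
#' and is pinned at the pIC50 maximum (the best binder). In subgroup 14,
#' `n_minor_cat3` compounds carry categories `{1,3,4}` with the
#' `minor_cat3` flag (a fluorine-for-hydrogen change), which still
#' classifies as 14.
#'
#' @param spec a [compound_series_spec()].
#' @return data.frame: `compound_id, pIC50, charged, categories
#'   (comma-joined), censored, minor_cat3, subgroup`.
#' @export
gen_compound_series <- function(spec) {
  if (!inherits(spec, "compound_series_spec"))
    stopf("'spec' must be a compound_series_spec")
  sizes <- spec$subgroup_sizes
  codes <- rep(names(sizes), times = sizes)
  n_neutral <- length(codes)
  n_total <- n_neutral + spec$n_charged
  if (spec$n_censored > n_total)
    stopf("n_censored exceeds the number of compounds")

  ids <- character(n_total)
  used <- 0L
  next_id <- function() {
    repeat {
      used <<- used + 1L
      cand <- paste0("L", used)
      if (!cand %in% c("L2", "L30")) return(cand)
    }
  }
  sub1_seen <- FALSE
  for (i in seq_len(n_neutral)) {
    if (codes[i] == "0") ids[i] <- "L30"
    else if (codes[i] == "1" && !sub1_seen) { ids[i] <- "L2"; sub1_seen <- TRUE }
    else ids[i] <- next_id()
  }
  for (i in seq.int(n_neutral + 1L, length.out = spec$n_charged))
    ids[i] <- next_id()
  if (anyDuplicated(ids)) stopf("internal error: duplicate compound ids")

  charged <- c(rep(FALSE, n_neutral), rep(TRUE, spec$n_charged))
  subgroup <- c(codes, rep(NA_character_, spec$n_charged))

  set.seed(child_seed(spec$seed, "series", "pic50"))
  pic50 <- stats::runif(n_total, spec$pic50_range[1L], spec$pic50_range[2L])
  # pin the observed extremes to the stated range; L30 is the weakest
  # binder (every transformation from it improves binding), L2 the best
  pic50[ids == "L30"] <- spec$pic50_range[1L]
  if (any(ids == "L2")) pic50[ids == "L2"] <- spec$pic50_range[2L]

  categories <- vapply(seq_len(n_total), function(i) {
    if (charged[i]) {
      set.seed(child_seed(spec$seed, "series", "charged_cat", ids[i]))
      as.character(sample(1:4, 1L))
    } else paste(subgroup_categories(subgroup[i]), collapse = ",")
  }, character(1L))

  minor_cat3 <- rep(FALSE, n_total)
  idx14 <- which(!charged & subgroup == "14")
  if (length(idx14) && spec$n_minor_cat3 > 0L) {
    take <- utils::head(idx14, spec$n_minor_cat3)
    minor_cat3[take] <- TRUE
    categories[take] <- "1,3,4"
  }

  censored <- rep(FALSE, n_total)
  if (spec$n_censored > 0L) {
    # censor the weakest-activity compounds, never the named references
    cand <- setdiff(order(pic50), which(ids %in% c("L30", "L2")))
    take <- utils::head(cand, spec$n_censored)
    censored[take] <- TRUE
    pic50[take] <- 5.00
  }

  data.frame(compound_id = ids, pIC50 = pic50, charged = charged,
             categories = categories, censored = censored,
             minor_cat3 = minor_cat3, subgroup = subgroup,
             stringsAsFactors = FALSE)
}

#' Generate a perturbation network over a compound series
#'
#' Builds a two-hub alchemical transformation network in the shape used for
#' lead optimization: one hub-to-hub edge, `n_dual` compounds paired with
#' both hubs (closing triangles through the hubs), and further single-hub
#' edges up to `n_edges` in total. Experimental ddG values come from
#' [pic50_to_dg()] differences; calculated ddG values are the planted truth
#' (from `true_dg` if given, otherwise the experimental values) plus
#' optional Gaussian noise and a systematic offset on edges tagged with the
#' hub-1 common change.
#'
#' @param compounds a compound series from [gen_compound_series()].
#' @param true_dg optional named vector of planted per-compound binding free
#'   energies used for the calculated values; defaults to the experimental
#'   ones.
#' @param hubs character vector of two hub compound ids (default `L30`,
#'   `L2`).
#' @param n_edges total number of edges (default 103).
#' @param n_dual number of compounds paired with both hubs (default 17).
#' @param calc_noise_sd SD of per-edge noise added to the calculated ddG.
#' @param common_change_offset systematic shift (kcal/mol) added to the
#'   calculated ddG of every edge tagged `common-change` (edges departing
#'   from the first hub, which all share its alchemical modification);
#'   negative values emulate overestimation of the binding improvement.
#' @param temperature kelvin, for the pIC50 conversion.
#' @param seed RNG seed.
#' @return data.frame of edges: `edge_id, ref_id, target_id, ddG_calc,
#'   se_calc, ddG_exp, tags`.
#' @export
gen_perturbation_network <- function(compounds, true_dg = NULL,
                                     hubs = c("L30", "L2"), n_edges = 103L,
                                     n_dual = 17L, calc_noise_sd = 0,
                                     common_change_offset = 0,
                                     temperature = 300, seed = 1L) {
  assert_columns(compounds, c("compound_id", "pIC50", "charged"),
                 "compound table")
  if (length(hubs) != 2L || !all(hubs %in% compounds$compound_id))
    stopf("'hubs' must be two compound ids present in the series")
  n_edges <- assert_count(n_edges, "n_edges", 1L)
  n_dual <- assert_count(n_dual, "n_dual")
  g_exp <- stats::setNames(pic50_to_dg(compounds$pIC50, temperature),
                           compounds$compound_id)
  g_calc <- if (is.null(true_dg)) g_exp else {
    missing <- setdiff(compounds$compound_id, names(true_dg))
    if (length(missing)) stopf("'true_dg' missing compound(s): %s",
                               paste(utils::head(missing, 5L), collapse = ", "))
    true_dg
  }

  others <- setdiff(compounds$compound_id[!compounds$charged], hubs)
  n_single <- n_edges - 1L - 2L * n_dual
  if (n_single < 0L) stopf("n_edges too small for n_dual dual-hub pairs")
  if (n_dual + n_single > length(others))
    stopf("not enough compounds for %d edges (%d available)", n_edges,
          length(others))
  dual <- utils::head(others, n_dual)
  single <- utils::head(setdiff(others, dual), n_single)
  single_hub <- rep(hubs, length.out = n_single)

  ref <- c(hubs[1L], rep(hubs, n_dual), single_hub)
  target <- c(hubs[2L], rep(dual, each = 2L), single)
  tags <- ifelse(ref == hubs[1L], "common-change", "")

  ddg_exp <- unname(g_exp[target] - g_exp[ref])
  ddg_calc <- unname(g_calc[target] - g_calc[ref])
  ddg_calc <- ddg_calc + ifelse(tags == "common-change",
                                common_change_offset, 0)
  if (calc_noise_sd > 0) {
    set.seed(child_seed(seed, "network", "calc_noise"))
    ddg_calc <- ddg_calc + stats::rnorm(length(ddg_calc), 0, calc_noise_sd)
  }
  data.frame(edge_id = paste(ref, target, sep = ">"),
             ref_id = ref, target_id = target,
             ddG_calc = ddg_calc, se_calc = calc_noise_sd,
             ddG_exp = ddg_exp, tags = tags, stringsAsFactors = FALSE)
}
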