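# Ensemble end-point (MMPBSA-style) binding free energy estimation.
#
# In the 1traj protocol the complex, receptor and ligand conformations are
# all extracted from the complex trajectory, so the noisy internal-energy
# terms cancel frame by frame. Ensembles of replicas started from
# independent velocities give the reproducibility: each replica contributes
# its frame-mean, replicas are averaged with equal weight, and the
# uncertainty is the bootstrap standard error over replica means (frames
# within a replica are autocorrelated, so resampling is at the replica level
# only). The entropic contribution is omitted throughout: the estimates are
# ranking scores, not absolute affinities.

#' Single-frame MMPBSA free energy
#'
#' Sums the molecular-mechanics and implicit-solvation components of one or
#' more frames: `E_vdw + E_ele + E_internal + G_PB + G_SA`. There is no
#' entropy term.
#'
#' @param frame a data.frame holding the component columns (extra columns
#'   are ignored), or a named numeric vector for a single frame.
#' @return numeric vector of per-frame free energies, kcal/mol.
#' @examples
#' frame_free_energy(c(E_vdw = -10, E_ele = -20, E_internal = 100,
#'                     G_PB = -35, G_SA = 5))  # 40
#' @export
frame_free_energy <- function(frame) {
  if (is.numeric(frame)) frame <- as.data.frame(as.list(frame))
  assert_columns(frame, ENERGY_COMPONENTS, "energy frame")
  for (cc in ENERGY_COMPONENTS) {
    v <- frame[[cc]]
    if (!is.numeric(v) || !all(is.finite(v)))
      stopf("non-finite value in energy component '%s'", cc)
  }
  rowSums(as.matrix(frame[ENERGY_COMPONENTS]))
}

#' Bootstrap standard error of an ensemble mean
#'
#' Resamples replica means with replacement `B` times and returns the
#' standard deviation of the bootstrap means. Values are put in canonical
#' (sorted) order before resampling so the result does not depend on replica
#' labelling.
#'
#' @param replica_means numeric vector of per-replica means (length >= 2).
#' @param B number of bootstrap resamples (>= 100; default 5000).
#' @param seed RNG seed.
#' @return bootstrap standard error, kcal/mol.
#' @examples
#' bootstrap_se(rnorm(25), B = 1000, seed = 7)
#' @export
bootstrap_se <- function(replica_means, B = 5000L, seed = 1L) {
  if (!is.numeric(replica_means) || length(replica_means) < 2L)
    stopf("need at least 2 replica means for a bootstrap standard error")
  if (!all(is.finite(replica_means)))
    stopf("'replica_means' contains non-finite values")
  B <- assert_count(B, "B", lower = 100L)
  x <- sort(replica_means)
  n <- length(x)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  stats::sd(rowMeans(matrix(x[idx], nrow = B)))
}

# split a one-compound energy table into aligned per-species component
# matrices, erroring on any (replica, frame) mismatch
align_species_frames <- function(energy, discard_frames = 0L) {
  assert_columns(energy, c("species", "replica", "frame", ENERGY_COMPONENTS),
                 "energy table")
  if ("compound_id" %in% names(energy) &&
      length(unique(energy$compound_id)) > 1L)
    stopf("energy table contains %d compounds; pass one compound at a time",
          length(unique(energy$compound_id)))
  bad <- setdiff(unique(energy$species), c("complex", "receptor", "ligand"))
  if (length(bad)) stopf("unknown species label(s): %s",
                         paste(bad, collapse = ", "))
  for (cc in ENERGY_COMPONENTS)
    if (!all(is.finite(energy[[cc]])))
      stopf("non-finite value in energy component '%s'", cc)
  if (discard_frames > 0L)
    energy <- energy[energy$frame > discard_frames, , drop = FALSE]
  parts <- lapply(c(complex = "complex", receptor = "receptor",
                    ligand = "ligand"), function(sp) {
    p <- energy[energy$species == sp, , drop = FALSE]
    if (!nrow(p)) stopf("no '%s' frames in energy table", sp)
    key <- paste(p$replica, p$frame, sep = ":")
    if (anyDuplicated(key))
      stopf("duplicate (replica, frame) pairs for species '%s'", sp)
    p[order(p$replica, p$frame), , drop = FALSE]
  })
  keys <- lapply(parts, function(p) paste(p$replica, p$frame, sep = ":"))
  ref <- keys$complex
  for (sp in c("receptor", "ligand")) {
    missing <- setdiff(ref, keys[[sp]])
    extra <- setdiff(keys[[sp]], ref)
    if (length(missing) || length(extra))
      stopf("(replica, frame) sets differ between complex and %s: missing [%s], extra [%s]",
            sp,
            paste(utils::head(missing, 5L), collapse = ", "),
            paste(utils::head(extra, 5L), collapse = ", "))
  }
  parts
}

#' 1traj end-point estimate for one compound
#'
#' Per matched (replica, frame), `dG_frame = G(complex) - G(receptor) -
#' G(ligand)`; frames are averaged within each replica, replica means are
#' averaged with equal weight, and the standard error is [bootstrap_se()]
#' over the replica means. The same aggregation is applied to each energy
#' component, so the reported breakdown sums exactly to the estimate.
#'
#' @param energy data.frame of one compound's frames in the energy schema
#'   (`species, replica, frame`, component columns).
#' @param B,seed bootstrap parameters.
#' @param discard_frames drop the first N frames of every replica (e.g.
#'   residual equilibration) before averaging.
#' @return an object of class `ensemble_estimate`: list with `value`, `se`,
#'   `n_replicas`, `replica_means`, `components`, `protocol`.
#' @export
one_traj_estimate <- function(energy, B = 5000L, seed = 1L,
                              discard_frames = 0L) {
  discard_frames <- assert_count(discard_frames, "discard_frames")
  parts <- align_species_frames(energy, discard_frames)
  g <- lapply(parts, frame_free_energy)
  dg_frame <- g$complex - g$receptor - g$ligand
  replica <- parts$complex$replica
  rep_means <- replica_mean_vector(dg_frame, replica)
  components <- vapply(ENERGY_COMPONENTS, function(cc) {
    d <- parts$complex[[cc]] - parts$receptor[[cc]] - parts$ligand[[cc]]
    mean(replica_mean_vector(d, replica))
  }, numeric(1L))
  names(components) <- sub("^E_", "dE_", sub("^G_", "dG_",
                                             ENERGY_COMPONENTS))
  se <- if (length(rep_means) > 1L)
    bootstrap_se(rep_means, B = B, seed = seed) else 0
  structure(list(value = mean(rep_means), se = se,
                 n_replicas = length(rep_means),
                 replica_means = unname(rep_means),
                 components = components, protocol = "1traj"),
            class = "ensemble_estimate")
}

#' @export
print.ensemble_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: %.4f +/- %.4f kcal/mol (%d replicas)\n",
              x$protocol, x$value, x$se, x$n_replicas))
  comp <- paste(sprintf("%s = %.3f", names(x$components), x$components),
                collapse = ", ")
  cat("  components: ", comp, "\n", sep = "")
  invisible(x)
}

#' Relative receptor adaptation energies across a compound series
#'
#' For each compound, the mean receptor energy over its complex-trajectory
#' frames (replica mean of frame means); the relative adaptation is the
#' deviation of that mean from the grand mean over compounds, so the values
#' sum to zero across the series. Used by the 1traj-ar protocol.
#'
#' @param energy data.frame of receptor frames for all compounds (rows with
#'   `species != "receptor"` are ignored); must contain `compound_id`.
#' @param adaptation_energy which energy enters the receptor mean:
#'   `"total"` (full MMPBSA energy, default) or `"mm_only"` (`E_vdw + E_ele
#'   + E_internal`).
#' @param B,seed bootstrap parameters for the per-compound standard error.
#' @return an object of class `adaptation_table`: data.frame `compound_id,
#'   g_rec, se, adaptation`, with the grand mean as attribute `grand_mean`.
#' @export
receptor_adaptation_relative <- function(energy,
                                         adaptation_energy = c("total",
                                                               "mm_only"),
                                         B = 5000L, seed = 1L) {
  adaptation_energy <- match.arg(adaptation_energy)
  assert_columns(energy, c("compound_id", "species", "replica", "frame",
                           ENERGY_COMPONENTS), "energy table")
  rec <- energy[energy$species == "receptor", , drop = FALSE]
  ids <- unique(rec$compound_id)
  if (length(ids) < 2L)
    stopf("relative adaptation needs >= 2 compounds (got %d)", length(ids))
  comps <- if (adaptation_energy == "total") ENERGY_COMPONENTS else
    c("E_vdw", "E_ele", "E_internal")
  res <- lapply(ids, function(cid) {
    p <- rec[rec$compound_id == cid, , drop = FALSE]
    g <- rowSums(as.matrix(p[comps]))
    if (!all(is.finite(g)))
      stopf("non-finite receptor energy for compound '%s'", cid)
    rm_ <- replica_mean_vector(g, p$replica)
    se <- if (length(rm_) > 1L)
      bootstrap_se(rm_, B = B, seed = child_seed(seed, cid, "adapt"))
    else 0
    c(g_rec = mean(rm_), se = se)
  })
  g_rec <- vapply(res, `[[`, numeric(1L), "g_rec")
  tab <- data.frame(compound_id = ids, g_rec = g_rec,
                    se = vapply(res, `[[`, numeric(1L), "se"),
                    adaptation = g_rec - mean(g_rec), row.names = NULL)
  structure(tab, grand_mean = mean(g_rec),
            adaptation_energy = adaptation_energy,
            class = c("adaptation_table", "data.frame"))
}

#' 1traj-ar estimate: add the relative receptor adaptation to 1traj
#'
#' @param one_traj an `ensemble_estimate` from [one_traj_estimate()].
#' @param adaptation relative receptor adaptation energy for this compound,
#'   kcal/mol.
#' @param adaptation_se its bootstrap standard error (default 0); combined
#'   in quadrature with the 1traj standard error.
#' @return an `ensemble_estimate` with protocol `"1traj-ar"`.
#' @export
one_traj_ar_estimate <- function(one_traj, adaptation, adaptation_se = 0) {
  if (!inherits(one_traj, "ensemble_estimate"))
    stopf("'one_traj' must be an ensemble_estimate")
  assert_number(adaptation, "adaptation")
  assert_number(adaptation_se, "adaptation_se", lower = 0)
  out <- one_traj
  out$value <- one_traj$value + adaptation
  out$se <- sqrt(one_traj$se^2 + adaptation_se^2)
  out$components <- c(one_traj$components, adaptation = adaptation)
  out$protocol <- "1traj-ar"
  out
}

#' ESMACS estimates for a whole compound series
#'
#' Runs [one_traj_estimate()] per compound and, for the `"1traj-ar"`
#' protocol, adds the relative receptor adaptation from
#' [receptor_adaptation_relative()].
#'
#' @param energy data.frame of all compounds' frames in the energy schema
#'   (must contain `compound_id`).
#' @param protocol `"1traj"` (default) or `"1traj-ar"`.
#' @param adaptation_energy passed to [receptor_adaptation_relative()].
#' @param B,seed bootstrap parameters; per-compound streams are derived with
#'   [child_seed()].
#' @param discard_frames passed to [one_traj_estimate()].
#' @return data.frame with one row per compound: `compound_id, dG, se,
#'   n_replicas` and the component breakdown columns.
#' @export
esmacs_series <- function(energy, protocol = c("1traj", "1traj-ar"),
                          adaptation_energy = "total", B = 5000L, seed = 1L,
                          discard_frames = 0L) {
  protocol <- match.arg(protocol)
  assert_columns(energy, c("compound_id", "species", "replica", "frame",
                           ENERGY_COMPONENTS), "energy table")
  ids <- unique(energy$compound_id)
  adapt <- NULL
  if (protocol == "1traj-ar")
    adapt <- receptor_adaptation_relative(energy,
                                          adaptation_energy = adaptation_energy,
                                          B = B, seed = seed)
  rows <- lapply(ids, function(cid) {
    est <- one_traj_estimate(energy[energy$compound_id == cid, , drop = FALSE],
                             B = B, seed = child_seed(seed, cid, "1traj"),
                             discard_frames = discard_frames)
    if (!is.null(adapt)) {
      m <- match(cid, adapt$compound_id)
      est <- one_traj_ar_estimate(est, adapt$adaptation[m], adapt$se[m])
    }
    comp <- est$components
    if (!"adaptation" %in% names(comp) && protocol == "1traj-ar")
      comp <- c(comp, adaptation = 0)
    cbind(data.frame(compound_id = cid, dG = est$value, se = est$se,
                     n_replicas = est$n_replicas),
          as.data.frame(as.list(comp)))
  })
  out <- do.call(rbind, rows)
  attr(out, "protocol") <- protocol
  out
}
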