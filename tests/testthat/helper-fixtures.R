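# Shared fixture builders. All fixtures are generated in code; sizes are
# kept small so each builder runs in milliseconds.

# a noiseless TI spec for the given edges
noiseless_ti_spec <- function(edges, n_samples = 5L, seed = 1L, ...) {
  ti_series_spec(edges, n_samples_per_window = n_samples,
                 within_replica_sd = 0, between_replica_sd = 0,
                 seed = seed, ...)
}

zero_noise_sds <- c(E_vdw = 0, E_ele = 0, E_internal = 0, G_PB = 0, G_SA = 0)

# a noiseless ESMACS spec for a named affinity map
noiseless_esmacs_spec <- function(true_map, n_replicas = 3L, n_frames = 4L,
                                  seed = 1L, ...) {
  esmacs_series_spec(true_map, n_replicas = n_replicas, n_frames = n_frames,
                     component_noise_sds = zero_noise_sds,
                     between_replica_sd = 0, interaction_frame_sd = 0,
                     seed = seed, ...)
}

# hand-built one-compound energy table: receptor + ligand == complex except
# for an interaction term added to the complex E_vdw
tiny_energy_table <- function(interaction = 0, n_replicas = 2L,
                              n_frames = 3L) {
  base <- expand.grid(replica = seq_len(n_replicas),
                      frame = seq_len(n_frames))
  mk <- function(species, E_vdw, E_ele, E_internal, G_PB, G_SA) {
    cbind(data.frame(species = species, replica = base$replica,
                     frame = base$frame),
          data.frame(E_vdw = E_vdw, E_ele = E_ele, E_internal = E_internal,
                     G_PB = G_PB, G_SA = G_SA))
  }
  rec <- mk("receptor", -700, -6000, 4800, -2800, 200)
  lig <- mk("ligand", -10, -30, 80, -25, 4)
  cpx <- mk("complex", -710 + interaction, -6030, 4880, -2825, 204)
  rbind(cpx, rec, lig)
}

# exhaustive pair-counting Kendall tau-b oracle (independent of stats::cor)
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# small planted two-hub network from per-compound absolute values
planted_network <- function(n_compounds = 14L, n_edges = 15L, n_dual = 3L,
                            seed = 7L) {
  spec <- compound_series_spec(subgroup_sizes = c(`0` = 1,
                                                  `1` = n_compounds - 1L),
                               n_charged = 0L, n_censored = 0L, seed = seed)
  compounds <- gen_compound_series(spec)
  gen_perturbation_network(compounds, n_edges = n_edges, n_dual = n_dual,
                           seed = seed)
}
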