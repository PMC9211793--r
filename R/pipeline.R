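# End-to-end pipeline: generate -> esmacs -> ties -> network -> evaluate,
# with a manifest written alongside every run. Identical config + seed
# gives byte-identical outputs (table numerics are pinned to 6 decimals and
# every random stream is derived from the one seed).

pipeline_defaults <- function() {
  list(
    seed = 1L,
    temperature = 300,
    bootstrap_B = 1000L,
    out_dir = "enfea-out",
    series = list(subgroup_sizes = c(`0` = 1, `1` = 6, `14` = 5),
                  pic50_range = c(5.03, 8.37),
                  n_charged = 2L, n_censored = 1L, planted_r = 0.9),
    esmacs = list(n_replicas = 5L, n_frames = 25L, protocol = "1traj",
                  adaptation_energy = "total", between_replica_sd = 1.0),
    ti = list(n_edges = 8L, n_dual = 2L, n_replicas = 5L,
              n_samples_per_window = 50L, within_replica_sd = 0.3,
              between_replica_sd = 0.2),
    network = list(hubs = c("L30", "L2"), offset = "fit",
                   flag_threshold = 0.5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      merge_config(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  assert_count(cfg$seed, "seed")
  assert_number(cfg$temperature, "temperature", lower = 0,
                strict_lower = TRUE)
  assert_count(cfg$bootstrap_B, "bootstrap_B", lower = 100L)
  if (!is.character(cfg$out_dir) || !nzchar(cfg$out_dir))
    stopf("'out_dir' must be a non-empty path")
  if (!cfg$esmacs$protocol %in% c("1traj", "1traj-ar"))
    stopf("esmacs protocol must be '1traj' or '1traj-ar'")
  if (!(identical(cfg$network$offset, "fit") ||
        is.numeric(cfg$network$offset)))
    stopf("network offset must be a number or 'fit'")
  invisible(cfg)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults, and validates.
#'
#' @param config path to a YAML file, or a (possibly partial) named list;
#'   `NULL` gives the defaults.
#' @return validated config list.
#' @export
load_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stopf("'config' must be a path, a list, or NULL")
  if (!is.null(user$series$subgroup_sizes))
    user$series$subgroup_sizes <- unlist(user$series$subgroup_sizes)
  cfg <- merge_config(pipeline_defaults(), user)
  validate_config(cfg)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: synthetic-data generation,
#' ESMACS series estimation, ensemble-TI edge estimation, network
#' diagnostics, and series evaluation. All outputs plus a `manifest.json`
#' (tool version, config hash, file checksums, per-stage runtimes, seed)
#' are written under `out_dir`.
#'
#' @param config a YAML path, config list, or `NULL` for defaults (see
#'   [load_config()]).
#' @param out_dir optional override of the configured output directory.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  cfg <- load_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  runtimes <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    runtimes[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("[%s] done in %.2f s", name, runtimes[[name]])
    res
  }
  path_in <- function(f) file.path(cfg$out_dir, f)

  # -- generate ------------------------------------------------------------
  gen <- stage("generate", function() {
    sspec <- compound_series_spec(subgroup_sizes = cfg$series$subgroup_sizes,
                                  pic50_range = cfg$series$pic50_range,
                                  n_charged = cfg$series$n_charged,
                                  n_censored = cfg$series$n_censored,
                                  seed = child_seed(cfg$seed, "series"))
    compounds <- gen_compound_series(sspec)
    write_compound_table(compounds, path_in("compounds.tsv"))
    pic50 <- stats::setNames(compounds$pIC50, compounds$compound_id)
    true_dg <- plant_affinity_map(pic50, target_r = cfg$series$planted_r,
                                  seed = child_seed(cfg$seed, "plant"))
    espec <- esmacs_series_spec(true_affinity_map = true_dg,
                                n_replicas = cfg$esmacs$n_replicas,
                                n_frames = cfg$esmacs$n_frames,
                                between_replica_sd =
                                  cfg$esmacs$between_replica_sd,
                                seed = child_seed(cfg$seed, "esmacs_gen"))
    energy <- gen_esmacs_dataset(espec)
    write_energy_table(energy, path_in("energies.csv"))
    net <- gen_perturbation_network(compounds, true_dg = true_dg,
                                    hubs = cfg$network$hubs,
                                    n_edges = cfg$ti$n_edges,
                                    n_dual = cfg$ti$n_dual,
                                    temperature = cfg$temperature,
                                    seed = child_seed(cfg$seed, "network"))
    tspec <- ti_series_spec(edges = data.frame(ref_id = net$ref_id,
                                               target_id = net$target_id,
                                               ddg_true = net$ddG_calc),
                            n_replicas = cfg$ti$n_replicas,
                            n_samples_per_window =
                              cfg$ti$n_samples_per_window,
                            within_replica_sd = cfg$ti$within_replica_sd,
                            between_replica_sd = cfg$ti$between_replica_sd,
                            seed = child_seed(cfg$seed, "ti_gen"))
    ti <- gen_ti_dataset(tspec)
    write_dudl_table(ti, path_in("dudl.csv"))
    files <<- c(files, "compounds.tsv", "energies.csv", "dudl.csv")
    list(compounds = compounds, energy = energy, ti = ti, net = net)
  })

  # -- esmacs --------------------------------------------------------------
  est <- stage("esmacs", function() {
    est <- esmacs_series(gen$energy, protocol = cfg$esmacs$protocol,
                         adaptation_energy = cfg$esmacs$adaptation_energy,
                         B = cfg$bootstrap_B,
                         seed = child_seed(cfg$seed, "esmacs_boot"))
    out <- est
    for (cc in setdiff(names(out), c("compound_id", "n_replicas")))
      out[[cc]] <- fmt_num(out[[cc]])
    utils::write.table(out, path_in("esmacs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <<- c(files, "esmacs.tsv")
    est
  })

  # -- ties ----------------------------------------------------------------
  edges <- stage("ties", function() {
    res <- ties_analyze(gen$ti, B = cfg$bootstrap_B,
                        seed = child_seed(cfg$seed, "ties_boot"))
    m <- match(res$edge_id, gen$net$edge_id)
    edges <- data.frame(edge_id = res$edge_id, ref_id = res$ref_id,
                        target_id = res$target_id, ddG_calc = res$ddG_calc,
                        se_calc = res$se_calc,
                        ddG_exp = gen$net$ddG_exp[m],
                        tags = gen$net$tags[m], stringsAsFactors = FALSE)
    write_edge_table(edges, path_in("edges.tsv"))
    files <<- c(files, "edges.tsv")
    edges
  })

  # -- network -------------------------------------------------------------
  net_report <- stage("network", function() {
    offset <- if (identical(cfg$network$offset, "fit")) NULL
    else cfg$network$offset
    corrected <- apply_common_change_offset(edges, offset)
    tri <- tryCatch(hub_triangles(edges, cfg$network$hubs),
                    error = function(e) list())
    cycles <- lapply(tri, function(cy) {
      rep <- cycle_closure(edges, cy,
                           flag_threshold = cfg$network$flag_threshold)
      list(nodes = rep$nodes, calc_sum = rep$calc_sum,
           discrepancy_sum = rep$discrepancy_sum,
           n_flagged = sum(rep$legs$flagged))
    })
    report <- list(
      n_edges = nrow(edges),
      mse = mean_signed_error(edges),
      directional_agreement = as.numeric(directional_agreement(edges)),
      offset = corrected$offset, offset_mode = corrected$offset_mode,
      mse_before = corrected$mse_before, mse_after = corrected$mse_after,
      flag_threshold = cfg$network$flag_threshold,
      cycles = cycles)
    jsonlite::write_json(report, path_in("network_report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    files <<- c(files, "network_report.json")
    report
  })

  # -- evaluate ------------------------------------------------------------
  stage("evaluate", function() {
    rep <- evaluate_series(gen$compounds, est,
                           temperature = cfg$temperature)
    jsonlite::write_json(list(temperature = cfg$temperature,
                              convention = attr(rep, "convention"),
                              strata = rep),
                         path_in("series_report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE,
                         dataframe = "rows", na = "null")
    files <<- c(files, "series_report.json")
    rep
  })

  # -- manifest ------------------------------------------------------------
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  checksums <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    tool = "enfea",
    version = as.character(utils::packageVersion("enfea")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = checksums,
    runtimes_s = runtimes)
  unlink(cfg_file)
  jsonlite::write_json(manifest, path_in("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[manifest] %s", path_in("manifest.json"))
  invisible(manifest)
}
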