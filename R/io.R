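# Interchange formats. Plain CSV/TSV with explicit headers; energies are
# serialized with 6 decimal places so that re-running a pipeline with the
# same seed reproduces byte-identical files.

ENERGY_SCHEMA <- c("compound_id", "species", "replica", "frame",
                   ENERGY_COMPONENTS)
DUDL_SCHEMA <- c("edge_id", "leg", "lambda", "replica", "frame", "dudl")
COMPOUND_SCHEMA <- c("compound_id", "pIC50", "charged", "categories",
                     "censored")
EDGE_SCHEMA <- c("edge_id", "ref_id", "target_id", "ddG_calc", "se_calc",
                 "ddG_exp", "tags")

read_table_checked <- function(path, schema, numeric_cols, sep, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stopf("%s '%s' is missing column(s): %s", what, path,
          paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), schema)
  if (length(unknown))
    stopf("%s '%s' has unknown column(s): %s", what, path,
          paste(unknown, collapse = ", "))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & nzchar(df[[cc]]))
    if (length(bad))
      stopf("%s '%s': non-numeric value '%s' in column '%s' at data row %d",
            what, path, df[[cc]][bad[1L]], cc, bad[1L])
    if (anyNA(v) && nrow(df))
      stopf("%s '%s': empty value in column '%s'", what, path, cc)
    df[[cc]] <- v
  }
  message(sprintf("[io] read %d row(s) from %s", nrow(df), path))
  df
}

write_table_fixed <- function(df, path, numeric_cols, sep) {
  out <- df
  for (cc in intersect(numeric_cols, names(out)))
    out[[cc]] <- fmt_num(out[[cc]])
  for (cc in names(out)) if (is.logical(out[[cc]]))
    out[[cc]] <- as.integer(out[[cc]])
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write per-frame MMPBSA energy tables (CSV)
#'
#' Schema: `compound_id, species {complex|receptor|ligand}, replica, frame,
#' E_vdw, E_ele, E_internal, G_PB, G_SA` (kcal/mol). The same schema is
#' accepted from real MMPBSA post-processing exports.
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_energy_table <- function(path) {
  df <- read_table_checked(path, ENERGY_SCHEMA,
                           c("replica", "frame", ENERGY_COMPONENTS), ",",
                           "energy CSV")
  if (nrow(df)) {
    bad <- setdiff(unique(df$species), c("complex", "receptor", "ligand"))
    if (length(bad))
      stopf("energy CSV '%s': unknown species label(s): %s", path,
            paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_energy_table
#' @param energy data.frame in the energy schema.
#' @export
write_energy_table <- function(energy, path) {
  assert_columns(energy, ENERGY_SCHEMA, "energy table")
  write_table_fixed(energy[ENERGY_SCHEMA], path, ENERGY_COMPONENTS, ",")
}

#' Read / write dU/dlambda sample tables (CSV)
#'
#' Schema: `edge_id, leg {bound|free}, lambda, replica, frame, dudl`
#' (kcal/mol).
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_dudl_table <- function(path) {
  df <- read_table_checked(path, DUDL_SCHEMA,
                           c("lambda", "replica", "frame", "dudl"), ",",
                           "TI CSV")
  if (nrow(df)) {
    bad <- setdiff(unique(df$leg), c("bound", "free"))
    if (length(bad))
      stopf("TI CSV '%s': unknown leg label(s): %s", path,
            paste(bad, collapse = ", "))
  }
  df
}

#' @rdname read_dudl_table
#' @param dudl data.frame in the dU/dlambda schema (a `ti_dataset`'s `dudl`
#'   element is accepted directly).
#' @export
write_dudl_table <- function(dudl, path) {
  if (inherits(dudl, "ti_dataset")) dudl <- dudl$dudl
  assert_columns(dudl, DUDL_SCHEMA, "TI table")
  write_table_fixed(dudl[DUDL_SCHEMA], path, c("lambda", "dudl"), ",")
}

#' Read / write compound tables (TSV)
#'
#' Schema: `compound_id, pIC50, charged {0|1}, categories (comma-joined
#' subset of 1,2,3,4), censored {0|1}`, plus optional `minor_cat3` and
#' `subgroup` columns which round-trip when present.
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(COMPOUND_SCHEMA, names(df))
  if (length(missing))
    stopf("compound TSV '%s' is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  df$pIC50 <- suppressWarnings(as.numeric(df$pIC50))
  if (anyNA(df$pIC50) && nrow(df))
    stopf("compound TSV '%s': non-numeric pIC50", path)
  df$charged <- as.logical(as.integer(df$charged))
  df$censored <- as.logical(as.integer(df$censored))
  if ("minor_cat3" %in% names(df))
    df$minor_cat3 <- as.logical(as.integer(df$minor_cat3))
  message(sprintf("[io] read %d compound(s) from %s", nrow(df), path))
  df
}

#' @rdname read_compound_table
#' @param compounds data.frame in the compound schema.
#' @export
write_compound_table <- function(compounds, path) {
  assert_columns(compounds, COMPOUND_SCHEMA, "compound table")
  keep <- c(COMPOUND_SCHEMA,
            intersect(c("minor_cat3", "subgroup"), names(compounds)))
  out <- compounds[keep]
  out$pIC50 <- fmt_num(out$pIC50)
  for (cc in names(out)) if (is.logical(out[[cc]]))
    out[[cc]] <- as.integer(out[[cc]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write transformation edge tables (TSV)
#'
#' Schema: `edge_id, ref_id, target_id, ddG_calc, se_calc, ddG_exp, tags`
#' (energies in kcal/mol; `tags` free text).
#'
#' @param path file path.
#' @return data.frame of validated records.
#' @export
read_edge_table <- function(path) {
  df <- read_table_checked(path, EDGE_SCHEMA,
                           c("ddG_calc", "se_calc", "ddG_exp"), "\t",
                           "edge TSV")
  df
}

#' @rdname read_edge_table
#' @param edges data.frame in the edge schema.
#' @export
write_edge_table <- function(edges, path) {
  assert_columns(edges, EDGE_SCHEMA, "edge table")
  write_table_fixed(edges[EDGE_SCHEMA], path,
                    c("ddG_calc", "se_calc", "ddG_exp"), "\t")
}
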