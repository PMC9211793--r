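# Compound-series evaluation: pIC50 conversion, subgrouping by modification
# position, and ranking statistics of calculated versus experimental
# binding free energies.

#' Convert pIC50 to a binding free energy
#'
#' `dG = -R T ln(10) pIC50` with R = 1.9872e-3 kcal/(mol K); at 300 K one
#' log unit is 1.3727 kcal/mol. Differences of the outputs give experimental
#' ddG values directly.
#'
#' @param pic50 numeric vector of pIC50 values (log units).
#' @param temperature kelvin (> 0; default 300).
#' @return binding free energies, kcal/mol (more negative = stronger).
#' @examples
#' pic50_to_dg(7, 300)  # about -9.61
#' @export
pic50_to_dg <- function(pic50, temperature = 300) {
  assert_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  if (!is.numeric(pic50)) stopf("'pic50' must be numeric")
  -R_KCAL * temperature * log(10) * pic50
}

#' Dynamic range of a compound series in log units
#'
#' @param x numeric vector of pIC50 values, or a compound table with a
#'   `pIC50` column.
#' @return `max - min`, log units.
#' @examples
#' pic50_span(c(5.03, 8.37))  # 3.34
#' @export
pic50_span <- function(x) {
  if (is.data.frame(x)) {
    assert_columns(x, "pIC50", "compound table")
    x <- x$pIC50
  }
  if (!is.numeric(x) || !length(x) || anyNA(x))
    stopf("'x' must be a non-empty numeric vector of pIC50 values")
  max(x) - min(x)
}

#' Subgroup code from modification categories
#'
#' Maps a compound's set of modification categories (1 = ether variation at
#' the hydrophobic position, 2 = pyridyl variation at the hinge, 3 = central
#' aryl variation at the bridge, 4 = lactam substituent variation at the
#' solvent position) to its subgroup code: `{} -> 0`, single categories map
#' to themselves, `{3,4} -> 34`, `{1,4} -> 14`, and `{1,3,4}` with the
#' `minor_cat3` flag (fluorine-for-hydrogen only) also maps to 14. Any other
#' combination returns `"unclassified"` with a warning.
#'
#' @param categories integer vector of categories, or a comma-joined string
#'   such as `"1,4"`; empty or `""` means no modification.
#' @param minor_cat3 logical: is the category-3 change a minor fluorine
#'   substitution?
#' @return subgroup code as a character scalar.
#' @examples
#' assign_subgroup(c(3, 4))            # "34"
#' assign_subgroup("1,3,4", TRUE)      # "14"
#' @export
assign_subgroup <- function(categories, minor_cat3 = FALSE) {
  if (is.character(categories)) {
    categories <- categories[nzchar(categories)]
    categories <- if (length(categories))
      as.integer(strsplit(categories, ",", fixed = TRUE)[[1L]]) else integer(0)
  }
  if (anyNA(categories) || !all(categories %in% 1:4))
    stopf("categories must be a subset of {1, 2, 3, 4}")
  key <- paste(sort(unique(categories)), collapse = ",")
  if (key == "") return("0")
  if (key %in% c("1", "2", "3", "4")) return(key)
  if (key == "3,4") return("34")
  if (key == "1,4") return("14")
  if (key == "1,3,4" && isTRUE(minor_cat3)) return("14")
  warnf("category combination {%s} has no subgroup code; returning 'unclassified'",
        key)
  "unclassified"
}

#' Ranking statistics between calculated and experimental free energies
#'
#' Pearson product-moment r, Spearman rho (mid-ranks for ties), Kendall
#' tau-b, and the sample covariance (n - 1 denominator).
#'
#' @param calc,exp numeric vectors of equal length >= 3; both must be
#'   non-constant for the correlation coefficients to be defined.
#' @return list with `pearson`, `spearman`, `kendall`, `covariance`, `n`.
#' @examples
#' ranking_stats(c(1, 2, 3, 5), c(1.1, 1.9, 3.2, 4.8))
#' @export
ranking_stats <- function(calc, exp) {
  if (!is.numeric(calc) || !is.numeric(exp))
    stopf("'calc' and 'exp' must be numeric")
  if (length(calc) != length(exp))
    stopf("'calc' (n = %d) and 'exp' (n = %d) differ in length",
          length(calc), length(exp))
  if (length(calc) < 3L) stopf("need at least 3 pairs")
  if (anyNA(calc) || anyNA(exp)) stopf("missing values are not allowed")
  if (stats::sd(calc) == 0 || stats::sd(exp) == 0)
    stopf("correlation undefined for a constant series")
  list(pearson = stats::cor(calc, exp, method = "pearson"),
       spearman = stats::cor(calc, exp, method = "spearman"),
       kendall = stats::cor(calc, exp, method = "kendall"),
       covariance = stats::cov(calc, exp),
       n = length(calc))
}

stratum_members <- function(compounds, stratum) {
  sub <- if ("subgroup" %in% names(compounds)) compounds$subgroup
  else vapply(seq_len(nrow(compounds)), function(i)
    assign_subgroup(compounds$categories[i],
                    isTRUE(compounds$minor_cat3[i])), character(1L))
  switch(stratum,
         all = rep(TRUE, nrow(compounds)),
         charged = compounds$charged,
         neutral = !compounds$charged,
         `1+14` = !compounds$charged & sub %in% c("1", "14"),
         !compounds$charged & !is.na(sub) & sub == stratum)
}

#' Evaluate calculated affinities against experiment across strata
#'
#' For each stratum (all compounds, charge classes, modification subgroups),
#' computes [ranking_stats()] between the calculated binding free energies
#' and the experimental ones obtained from pIC50 via [pic50_to_dg()].
#' Censored compounds (assay floor) are included in the headline numbers,
#' and each stratum is additionally re-evaluated with them excluded (the
#' `*_nocens` columns) as a sensitivity check.
#'
#' @param compounds compound table (`compound_id, pIC50, charged,
#'   categories, censored`, optional `minor_cat3`, `subgroup`).
#' @param estimates data.frame with `compound_id` and `dG` (kcal/mol), e.g.
#'   from [esmacs_series()].
#' @param strata character vector of stratum labels: any of `"all"`,
#'   `"charged"`, `"neutral"`, a subgroup code, or `"1+14"`. Default: all of
#'   these that are non-empty, with subgroup rows restricted to neutral
#'   compounds.
#' @param temperature kelvin for the pIC50 conversion.
#' @param min_n smallest stratum evaluated (default 3); smaller strata are
#'   reported with `note = "insufficient n"` and no coefficients.
#' @return data.frame with one row per stratum: `stratum, n, n_censored,
#'   pearson, spearman, kendall, covariance`, the censoring-sensitivity
#'   columns, and `note`.
#' @export
evaluate_series <- function(compounds, estimates, strata = NULL,
                            temperature = 300, min_n = 3L) {
  assert_columns(compounds, c("compound_id", "pIC50", "charged",
                              "censored"), "compound table")
  assert_columns(estimates, c("compound_id", "dG"), "estimate table")
  missing <- setdiff(compounds$compound_id, estimates$compound_id)
  if (length(missing))
    stopf("estimates missing for compound(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  if (is.null(strata)) {
    subs <- if ("subgroup" %in% names(compounds))
      sort(unique(stats::na.omit(compounds$subgroup))) else character(0)
    strata <- c("all", "charged", "neutral", subs,
                if (all(c("1", "14") %in% subs)) "1+14")
  }
  exp_dg <- pic50_to_dg(compounds$pIC50, temperature)
  calc_dg <- estimates$dG[match(compounds$compound_id,
                                estimates$compound_id)]

  one_row <- function(stratum) {
    keep <- stratum_members(compounds, stratum)
    n <- sum(keep)
    blank <- list(pearson = NA_real_, spearman = NA_real_,
                  kendall = NA_real_, covariance = NA_real_)
    run <- function(k) {
      if (sum(k) < min_n) return(blank)
      tryCatch(ranking_stats(calc_dg[k], exp_dg[k])[names(blank)],
               error = function(e) blank)
    }
    s <- run(keep)
    s_nc <- run(keep & !compounds$censored)
    data.frame(stratum = stratum, n = n,
               n_censored = sum(keep & compounds$censored),
               pearson = s$pearson, spearman = s$spearman,
               kendall = s$kendall, covariance = s$covariance,
               pearson_nocens = s_nc$pearson, spearman_nocens = s_nc$spearman,
               kendall_nocens = s_nc$kendall,
               covariance_nocens = s_nc$covariance,
               note = if (n < min_n) "insufficient n" else "",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(strata, one_row))
  attr(out, "temperature") <- temperature
  attr(out, "convention") <- "experimental axis: dG from pIC50 (kcal/mol)"
  out
}
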