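# Internal helpers shared across modules.

ENERGY_COMPONENTS <- c("E_vdw", "E_ele", "E_internal", "G_PB", "G_SA")

# gas constant, kcal/(mol K)
R_KCAL <- 1.9872e-3

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("'%s' must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stopf("'%s' must be a single integer", name)
  if (x < lower) stopf("'%s' must be >= %d", name, lower)
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

#' Derive a child RNG seed from a root seed and a stream key
#'
#' Independent random streams for every (compound/edge, leg, window, replica)
#' combination are derived from one root seed by hashing a string key, so
#' enlarging an ensemble (adding replicas or windows) never perturbs the
#' numbers already drawn for existing ones.
#'
#' @param root integer root seed.
#' @param ... key components (coerced to character and joined).
#' @return an integer seed in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(1, "L30>L2", "bound", 3, 2)
#' @export
child_seed <- function(root, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x),
                                                   collapse = ","),
                      character(1L)), collapse = "/")
  h <- abs(as.double(root)) %% 2147483563
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483563
  as.integer(h) + 1L
}

# mean of each replica's samples, in sorted replica order
replica_mean_vector <- function(values, replica) {
  means <- tapply(values, replica, mean)
  means[order(as.numeric(names(means)))]
}

fmt_num <- function(x) sprintf("%.6f", x)
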