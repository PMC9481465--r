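#' Canonical pair identifier
#'
#' Adhesion measurements are between unordered pairs (a cell couple or a
#' cell on a coated substrate), so `"XEN-ES"` and `"ES-XEN"` name the same
#' measurement. The canonical form sorts the two labels alphabetically and
#' joins them with `"-"`.
#'
#' @param a,b Character labels (cell type or substrate name). `b` may be
#'   omitted if `a` already contains both labels joined by `"-"`.
#' @return A length-1 character canonical pair id.
#' @examples
#' pair_id("TS", "ES")     # "ES-TS"
#' pair_id("XEN-ES")       # "ES-XEN"
#' @export
pair_id <- function(a, b = NULL) {
  if (is.null(b)) {
    parts <- strsplit(a, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("pair id must contain exactly two labels joined by '-': ", a)
    }
    a <- parts[1L]
    b <- parts[2L]
  }
  paste(sort(c(a, b)), collapse = "-")
}

#' Construct a force-distribution specification
#'
#' A spec records the published summary statistics (mean, standard
#' deviation, sample size) of a maximum-detachment-force (F_max)
#' distribution for one cell pair (or cell-substrate pair) and condition,
#' in nanonewtons. The generator treats these as the nominal parameters of
#' a normal distribution truncated at zero.
#'
#' @param pair Pair id, any order (canonicalized via [pair_id()]).
#' @param mean_nN,sd_nN Nominal mean and standard deviation in nN; both
#'   must be positive.
#' @param n_published Published sample size (number of measured pairs).
#' @param condition Condition label, e.g. `"WT"` or `"Cdh1-KD"`.
#' @return An object of class `force_spec`.
#' @export
force_spec <- function(pair, mean_nN, sd_nN, n_published, condition = "WT") {
  stopifnot(is.numeric(mean_nN), length(mean_nN) == 1L, mean_nN > 0,
            is.numeric(sd_nN), length(sd_nN) == 1L, sd_nN > 0,
            is.numeric(n_published), length(n_published) == 1L, n_published >= 1)
  structure(
    list(pair_id = pair_id(pair), mean_nN = mean_nN, sd_nN = sd_nN,
         n_published = as.integer(n_published), condition = condition),
    class = "force_spec"
  )
}

#' @export
print.force_spec <- function(x, ...) {
  cat(sprintf("<force_spec> %s [%s]: %.2f +/- %.2f nN (n = %d)\n",
              x$pair_id, x$condition, x$mean_nN, x$sd_nN, x$n_published))
  invisible(x)
}

#' Built-in adhesion-force specifications
#'
#' Returns the published F_max summary statistics used to calibrate the
#' synthetic force generator: the six wild-type cell-cell pairs among
#' ES, TS and XEN cells, the four cell-on-immobilized-cadherin substrate
#' measurements, and the E-cadherin (Cdh1) knockdown condition for ES-ES
#' couples, whose mean is a fourth of the wild-type value with the
#' standard deviation scaled proportionally. Other knockdown conditions
#' were not reported numerically and are supplied by the user through the
#' `forces:` section of the run configuration instead (see
#' [load_config()]).
#'
#' @return A named list of [force_spec()] objects keyed by
#'   `"<pair>|<condition>"`.
#' @examples
#' specs <- builtin_force_specs()
#' specs[["ES-ES|WT"]]
#' @export
builtin_force_specs <- function() {
  raw <- list(
    # wild-type cell-cell couples
    force_spec("ES-ES",   1.94, 0.54,  60),
    force_spec("TS-TS",   2.20, 0.85, 177),
    force_spec("XEN-XEN", 0.55, 0.11, 101),
    force_spec("ES-TS",   0.57, 0.36, 124),
    force_spec("XEN-TS",  0.46, 0.24, 148),
    force_spec("XEN-ES",  0.83, 0.96, 134),
    # cell on immobilized cadherin substrate
    force_spec("ES-Ecad", 2.13, 0.83, 42),
    force_spec("ES-Pcad", 1.07, 0.54, 35),
    force_spec("TS-Ecad", 2.02, 0.89, 41),
    force_spec("TS-Pcad", 2.41, 0.86, 37),
    # Cdh1 knockdown reduces ES-ES adhesion fourfold
    force_spec("ES-ES", 1.94 / 4, 0.54 / 4, 18, condition = "Cdh1-KD")
  )
  names(raw) <- vapply(raw, function(s) paste0(s$pair_id, "|", s$condition),
                       character(1))
  raw
}

#' Look up a built-in spec by pair (order-insensitive) and condition
#'
#' @inheritParams force_spec
#' @param specs A named list as returned by [builtin_force_specs()].
#' @return A `force_spec`; errors if the pair/condition is not present.
#' @export
lookup_force_spec <- function(pair, condition = "WT",
                              specs = builtin_force_specs()) {
  key <- paste0(pair_id(pair), "|", condition)
  if (is.null(specs[[key]])) {
    stop("no force spec for pair '", pair_id(pair), "' under condition '",
         condition, "'")
  }
  specs[[key]]
}

#' Draw synthetic adhesion forces from a spec
#'
#' Samples `n` forces from a normal distribution with the spec's nominal
#' mean and sd, truncated at zero (detachment forces cannot be negative;
#' for the XEN-ES pair the sd exceeds the mean, so truncation is not
#' optional). Sampling uses the inverse-CDF transform, so a given seed
#' reproduces the sample bit for bit.
#'
#' @param spec A [force_spec()].
#' @param n Number of forces to draw; defaults to the published sample
#'   size.
#' @param seed Integer seed for this draw.
#' @return An object of class `force_sample`: list with `spec`,
#'   `forces_nN` (numeric, all `>= 0`), and `seed`.
#' @export
sample_forces <- function(spec, n = spec$n_published, seed = 1L) {
  stopifnot(inherits(spec, "force_spec"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop("'n' must be a single non-negative number")
  }
  n <- as.integer(n)
  forces <- local_seed(seed, {
    if (n == 0L) numeric(0) else {
      p0 <- stats::pnorm(0, spec$mean_nN, spec$sd_nN)
      u <- stats::runif(n, p0, 1)
      stats::qnorm(u, spec$mean_nN, spec$sd_nN)
    }
  })
  structure(list(spec = spec, forces_nN = forces, seed = as.integer(seed)),
            class = "force_sample")
}

#' Summarize a force sample
#'
#' @param sample A `force_sample` or bare numeric vector of forces.
#' @return List with `mean`, `sd` (unbiased, `n - 1` denominator; `NA` for
#'   a single observation), and `n`.
#' @export
summarize_forces <- function(sample) {
  x <- if (inherits(sample, "force_sample")) sample$forces_nN else sample
  if (length(x) < 1L) stop("cannot summarize an empty force sample")
  list(mean = mean(x),
       sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
       n = length(x))
}

#' Moments of the zero-truncated normal distribution
#'
#' Mean and standard deviation of a normal(mean, sd) conditioned on being
#' non-negative, computed in closed form. These are the population moments
#' that large generated samples converge to; they sit slightly above the
#' nominal mean when the truncation removes appreciable mass.
#'
#' @param mean_nN,sd_nN Nominal (untruncated) parameters.
#' @return List with `mean` and `sd` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean_nN, sd_nN) {
  alpha <- -mean_nN / sd_nN
  z <- 1 - stats::pnorm(alpha)
  lambda <- stats::dnorm(alpha) / z   # hazard of the lower tail
  m <- mean_nN + sd_nN * lambda
  v <- sd_nN^2 * (1 + alpha * lambda - lambda^2)
  list(mean = m, sd = sqrt(v))
}

#' Relative cortical-stiffness defaults
#'
#' Cortical stiffness (Young's modulus from AFM indentation) is lower in
#' XEN cells than in ES or TS cells, and blebbistatin treatment brings ES
#' and TS down to the XEN level. No absolute values are published, so the
#' package exposes dimensionless ordinal defaults that only set ratios of
#' the perimeter-constraint coefficient lambda_P across cell types.
#'
#' @param treated If `TRUE`, emulate myosin inhibition: all types at the
#'   XEN level.
#' @return Named numeric vector of relative stiffness for ES, TS, XEN.
#' @export
stiffness_defaults <- function(treated = FALSE) {
  s <- c(ES = 2.5, TS = 2.5, XEN = 1.0)
  if (treated) s[] <- 1.0
  s
}

#' Write / read a force table as CSV
#'
#' One row per measurement with columns `pair_id`, `condition`,
#' `force_nN`, `seed`, `replicate`. Round-trip safe.
#'
#' @param samples A list of `force_sample` objects.
#' @param path Output CSV path.
#' @return `write_force_table` returns `path` invisibly;
#'   `read_force_table` returns the data frame.
#' @export
write_force_table <- function(samples, path) {
  if (inherits(samples, "force_sample")) samples <- list(samples)
  rows <- lapply(samples, function(s) {
    n <- length(s$forces_nN)
    data.frame(pair_id = rep(s$spec$pair_id, n),
               condition = rep(s$spec$condition, n),
               force_nN = s$forces_nN,
               seed = rep(s$seed, n),
               replicate = seq_len(n))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_table
#' @export
read_force_table <- function(path) {
  if (!file.exists(path)) stop("force table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# wild-type cell-cell subset of a spec list (the six pair pools the
# bootstrap resamples)
wt_cell_pair_specs <- function(specs) {
  Filter(function(s) {
    s$condition == "WT" &&
      all(strsplit(s$pair_id, "-")[[1]] %in% c("ES", "TS", "XEN"))
  }, specs)
}

#' Force specs with configuration overrides applied
#'
#' Merges the `forces:` section of a run configuration over
#' [builtin_force_specs()]. Each override entry is a list with `pair`,
#' `mean_nN`, `sd_nN`, `n` and optional `condition` (default `"WT"`),
#' and either replaces the built-in spec for that pair/condition or adds
#' a new one — the route for knockdown conditions whose statistics were
#' not published.
#'
#' @param config Configuration list (see [load_config()]).
#' @return Named list of [force_spec()] objects.
#' @export
config_force_specs <- function(config = default_config()) {
  specs <- builtin_force_specs()
  for (ov in config$forces) {
    spec <- force_spec(ov$pair, ov$mean_nN, ov$sd_nN, ov$n,
                       condition = if (is.null(ov$condition)) "WT" else
                         ov$condition)
    specs[[paste0(spec$pair_id, "|", spec$condition)]] <- spec
  }
  specs
}

#' Build per-pair force pools for bootstrap resampling
#'
#' Generates, for each wild-type cell-cell pair, a synthetic pool of the
#' published sample size from which the bootstrap draws with replacement
#' when assembling contact-energy matrices.
#'
#' @param specs Named list of specs (defaults to the wild-type cell-cell
#'   subset of [builtin_force_specs()]).
#' @param seed Integer seed.
#' @return Named list (canonical pair id) of numeric force vectors.
#' @export
build_force_pools <- function(specs = NULL, seed = 1L) {
  if (is.null(specs)) specs <- wt_cell_pair_specs(builtin_force_specs())
  pools <- vector("list", length(specs))
  names(pools) <- vapply(specs, function(s) s$pair_id, character(1))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    pools[[i]] <- sample_forces(s, s$n_published,
                                seed = derive_seed(seed, i))$forces_nN
  }
  pools
}
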