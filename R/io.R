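#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so
#' seeded package functions never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-run seed from a master seed and an index
#'
#' Runs in an ensemble each get an independent stream seeded by a counter
#' hash of `(master_seed, index)` rather than by consuming a shared RNG,
#' so individual runs can be reproduced (or distributed) in isolation.
#' Seeds stay in `[1, 2^31 - 2]`.
#'
#' @param master_seed Integer master seed.
#' @param index Run counter (1-based).
#' @return Integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(master_seed) %% m + 1) * 48271 %% m
  x <- (x + as.numeric(index) * 16807) %% m
  # one multiplicative mixing round to decorrelate consecutive indices
  x <- (x * 69621) %% m
  as.integer(x %/% 1 + 1)
}

# -- configuration ------------------------------------------------------

#' Default run configuration
#'
#' All simulation parameters in one nested list: lattice geometry,
#' Metropolis temperature, contact-energy mapping, per-type constraint
#' strengths, cell counts, and recording cadence. Units: forces nN,
#' energies in CPM energy units, lengths in lattice sites, time in Monte
#' Carlo steps (MCS; one MCS = width x height elementary copy attempts).
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    lattice = list(width = 80L, height = 80L, neighbourhood = 2L),
    temperature = 7,
    n_mcs = 10000L,
    record_every = 500L,
    cells = list(ES = 6L, TS = 14L, XEN = 5L),
    target_area = list(ES = 24, TS = 24, XEN = 36),
    target_perimeter_factor = 1.3,
    lambda_area = 1,
    lambda_perimeter_base = 0.05,
    stiffness = list(ES = 2.5, TS = 2.5, XEN = 1.0),
    energy_map = list(j_max = 16, alpha = 5, j_floor = 1),
    j_medium = list(ES = 30, TS = 30, XEN = 8),
    envelopment_threshold = 0.9,
    group_threshold = 0.05,
    forces = list()   # optional spec overrides: pair, mean_nN, sd_nN, n, condition
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key: '", full, "'")
    }
    if (is.list(defaults[[key]]) && !identical(key, "forces")) {
      if (!is.list(user[[key]])) {
        stop("config key '", full, "' must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config error: ", msg)
  # a scalar target_area applies to every type
  if (!is.list(cfg$target_area)) {
    cfg$target_area <- list(ES = cfg$target_area, TS = cfg$target_area,
                            XEN = cfg$target_area)
  }
  chk(cfg$lattice$width >= 8 && cfg$lattice$height >= 8,
      "lattice.width/height must be >= 8")
  chk(cfg$lattice$neighbourhood %in% c(1L, 2L),
      "lattice.neighbourhood must be 1 (von Neumann) or 2 (Moore)")
  chk(is.numeric(cfg$temperature) && cfg$temperature >= 0,
      "temperature must be >= 0 (0 selects the zero-temperature quench)")
  chk(cfg$n_mcs >= 0, "n_mcs must be >= 0")
  chk(cfg$record_every >= 1, "record_every must be >= 1")
  chk(all(unlist(cfg$cells) >= 0), "cells counts must be >= 0")
  chk(all(unlist(cfg$target_area) > 0), "target_area must be > 0")
  chk(cfg$lambda_area >= 0, "lambda_area must be >= 0")
  chk(cfg$lambda_perimeter_base >= 0,
      "lambda_perimeter_base must be >= 0")
  chk(all(unlist(cfg$stiffness) > 0), "stiffness values must be > 0")
  chk(cfg$energy_map$j_max > 0 && cfg$energy_map$alpha > 0,
      "energy_map.j_max and alpha must be > 0")
  chk(cfg$envelopment_threshold > 0 && cfg$envelopment_threshold <= 1,
      "envelopment_threshold must be in (0, 1]")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration file, merges it over
#' [default_config()], rejects unknown keys (typo protection) and
#' validates every constraint. An empty file yields the full defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(validate_config(default_config()))
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  validate_config(merge_config(default_config(), user))
}

#' Write a configuration back out (normalized)
#'
#' @param cfg Configuration list.
#' @param path Output path (`.yaml` or `.json` decides the format).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# -- result tables ------------------------------------------------------

#' Write / read a result table as CSV
#'
#' Lossless round trip with stable column order; errors carry the path.
#'
#' @param records A data frame.
#' @param path CSV path.
#' @return `write_results` returns `path` invisibly; `read_results` the
#'   data frame.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  tryCatch(utils::write.csv(records, path, row.names = FALSE),
           error = function(e) stop("failed writing '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("result table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# -- lattice snapshots --------------------------------------------------

#' Write / read a lattice snapshot
#'
#' The grid is stored as a plain-text integer matrix (one row per lattice
#' row, space separated) with a JSON sidecar (`<path>.json`) mapping each
#' cell id to its type. Exact round trip.
#'
#' @param lattice A `cpm_lattice`.
#' @param path Output path for the grid text file.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot` the
#'   reconstructed `cpm_lattice`.
#' @export
write_snapshot <- function(lattice, path) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  utils::write.table(lattice$grid, path, row.names = FALSE,
                     col.names = FALSE)
  side <- list(cell_type = as.list(stats::setNames(
    lattice$cell_type, seq_along(lattice$cell_type))),
    types = lattice$types)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path)
  grid <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ct <- as.integer(side$cell_type[as.character(seq_along(side$cell_type))])
  new_lattice(grid, ct, types = side$types)
}

#' Render a lattice to PNG
#'
#' Cell types use the fluorescence-channel convention: ES red, TS blue,
#' XEN green; medium is white and cell outlines dark grey.
#'
#' @param lattice A `cpm_lattice`.
#' @param path PNG output path.
#' @param scale Pixels per lattice site.
#' @return `path`, invisibly.
#' @export
render_lattice <- function(lattice, path, scale = 4L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  g <- lattice$grid
  type_of_site <- matrix(0L, nrow(g), ncol(g))
  type_of_site[g > 0L] <- lattice$cell_type[g[g > 0L]]
  cols <- c("white", "firebrick2", "royalblue3", "springgreen3")
  grDevices::png(path, width = ncol(g) * scale, height = nrow(g) * scale)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(type_of_site)[, nrow(g):1, drop = FALSE],
                  col = cols[sort(unique(as.vector(type_of_site))) + 1L],
                  axes = FALSE, useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

# -- run manifests ------------------------------------------------------

#' Build a run manifest
#'
#' A manifest records everything needed to reproduce an ensemble bit for
#' bit: the fully resolved configuration, master seed, the derived
#' per-run seeds, package version and a timestamp.
#'
#' @param config Resolved configuration list.
#' @param master_seed Integer master seed.
#' @param n_runs Number of runs in the ensemble.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, master_seed, n_runs) {
  structure(list(
    config = config,
    master_seed = as.integer(master_seed),
    run_seeds = vapply(seq_len(n_runs), function(i)
      derive_seed(master_seed, i), integer(1)),
    package_version = as.character(utils::packageVersion("etxsort")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' Write / read a run manifest as JSON
#'
#' @param manifest A `run_manifest`.
#' @param path JSON path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$run_seeds <- as.integer(m$run_seeds)
  # restore integer-typed config scalars that JSON reads back as doubles
  for (k in c("n_mcs", "record_every")) m$config[[k]] <- as.integer(m$config[[k]])
  m$config$lattice <- lapply(m$config$lattice, as.integer)
  m$config$cells <- lapply(m$config$cells, as.integer)
  if (length(m$config$forces) == 0L) m$config$forces <- list()
  structure(m, class = "run_manifest")
}
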