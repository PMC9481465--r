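#' Construct a CPM lattice object
#'
#' A lattice holds the grid of cell ids (0 = medium), the cell-to-type
#' map, and the type labels. Types are coded 1 = ES, 2 = TS, 3 = XEN.
#'
#' @param grid Integer matrix of cell ids.
#' @param cell_type Integer vector; `cell_type[id]` is the type of cell
#'   `id`.
#' @param types Character vector of type labels.
#' @return Object of class `cpm_lattice`.
#' @export
new_lattice <- function(grid, cell_type, types = c("ES", "TS", "XEN")) {
  storage.mode(grid) <- "integer"
  cell_type <- as.integer(cell_type)
  ids <- sort(unique(as.vector(grid)))
  ids <- ids[ids > 0L]
  if (length(ids) && max(ids) > length(cell_type)) {
    stop("grid contains cell ids without a type assignment")
  }
  structure(list(grid = grid, cell_type = cell_type, types = types),
            class = "cpm_lattice")
}

#' @export
print.cpm_lattice <- function(x, ...) {
  tab <- table(factor(x$cell_type, levels = seq_along(x$types),
                      labels = x$types))
  cat(sprintf("<cpm_lattice> %d x %d sites, %d cells (%s), %d medium sites\n",
              nrow(x$grid), ncol(x$grid), length(x$cell_type),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              sum(x$grid == 0L)))
  invisible(x)
}

#' Map an adhesion force to a contact energy
#'
#' Interfacial contact energies decrease affinely with the measured
#' adhesion force, `J = max(j_floor, j_max - alpha * F)`: stronger
#' adhesion means a cheaper interface. The floor keeps energies positive
#' for arbitrarily large forces.
#'
#' @param force_nN Adhesion force(s) in nN, `>= 0`. Vectorized.
#' @param j_max Intercept: contact energy at zero force.
#' @param alpha Slope in energy units per nN.
#' @param j_floor Lower clamp.
#' @return Contact energy value(s).
#' @export
force_to_contact_energy <- function(force_nN, j_max = 16, alpha = 5,
                                    j_floor = 1) {
  stopifnot(all(force_nN >= 0), j_max > 0, alpha > 0)
  pmax(j_floor, j_max - alpha * force_nN)
}

#' Build the 4x4 contact-energy matrix
#'
#' Assembles the symmetric contact-energy matrix over
#' `{ES, TS, XEN, Medium}` from per-pair adhesion forces via
#' [force_to_contact_energy()], with the cell-medium entries taken from
#' the configuration (`j_medium`). The XEN-medium energy is set below the
#' ES/TS value so a soft, weakly cohesive XEN tissue can wet the
#' aggregate surface. `J(Medium, Medium)` is 0.
#'
#' @param forces_by_pair Named numeric vector of forces (nN) with names
#'   `ES-ES`, `ES-TS`, `ES-XEN`, `TS-TS`, `TS-XEN`, `XEN-XEN` (any order
#'   convention).
#' @param config Configuration list (see [default_config()]).
#' @return 4x4 symmetric numeric matrix with dimnames.
#' @export
contact_energy_matrix <- function(forces_by_pair, config = default_config()) {
  names(forces_by_pair) <- vapply(names(forces_by_pair), pair_id,
                                  character(1))
  need <- c("ES-ES", "ES-TS", "ES-XEN", "TS-TS", "TS-XEN", "XEN-XEN")
  if (!all(need %in% names(forces_by_pair))) {
    stop("missing force entries for: ",
         paste(setdiff(need, names(forces_by_pair)), collapse = ", "))
  }
  em <- config$energy_map
  types <- c("ES", "TS", "XEN", "Medium")
  J <- matrix(0, 4, 4, dimnames = list(types, types))
  for (a in 1:3) for (b in a:3) {
    key <- pair_id(types[a], types[b])
    J[a, b] <- J[b, a] <- force_to_contact_energy(
      forces_by_pair[[key]], em$j_max, em$alpha, em$j_floor)
  }
  for (t in c("ES", "TS", "XEN")) {
    J[t, "Medium"] <- J["Medium", t] <- config$j_medium[[t]]
  }
  J
}

#' Per-type constraint parameters from a configuration
#'
#' Expands the configuration into the per-type vectors the simulator
#' needs: area- and perimeter-constraint strengths and targets for ES,
#' TS, XEN. The perimeter-constraint strength is
#' `lambda_perimeter_base * stiffness[type]`, so the relative cortical
#' stiffness of a type scales its resistance to shape change; the target
#' perimeter is `target_perimeter_factor` times the 4-neighbour edge
#' perimeter of a rasterized disc of the target area.
#'
#' @param config Configuration list.
#' @return List with `lambda_area`, `target_area`, `lambda_perimeter`,
#'   `target_perimeter` (each a length-3 vector, ES/TS/XEN order).
#' @export
cell_type_params <- function(config = default_config()) {
  config <- validate_config(config)
  ta <- unlist(config$target_area)[c("ES", "TS", "XEN")]
  st <- unlist(config$stiffness)[c("ES", "TS", "XEN")]
  list(
    lambda_area = rep(config$lambda_area, 3),
    target_area = as.numeric(ta),
    lambda_perimeter = config$lambda_perimeter_base * as.numeric(st),
    target_perimeter = config$target_perimeter_factor *
      vapply(ta, disc_perimeter, integer(1))
  )
}

#' 4-neighbour edge perimeter of a rasterized disc
#'
#' @param area Number of lattice sites.
#' @return Edge count of the most compact (distance-ordered) site set of
#'   that size.
#' @keywords internal
disc_perimeter <- function(area) {
  area <- as.integer(round(area))
  r <- ceiling(sqrt(area / pi)) + 2L
  coords <- expand.grid(i = -r:r, j = -r:r)
  d <- coords$i^2 + coords$j^2
  ord <- order(d, atan2(coords$j, coords$i))
  sel <- coords[ord[seq_len(area)], ]
  occ <- matrix(FALSE, 2L * r + 3L, 2L * r + 3L)
  occ[cbind(sel$i + r + 2L, sel$j + r + 2L)] <- TRUE
  p <- 0L
  for (k in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sh <- matrix(FALSE, nrow(occ), ncol(occ))
    ri <- (1 + max(k[1], 0)):(nrow(occ) + min(k[1], 0))
    ci <- (1 + max(k[2], 0)):(ncol(occ) + min(k[2], 0))
    sh[ri, ci] <- occ[ri - k[1], ci - k[2]]
    p <- p + sum(occ & !sh)
  }
  p
}

#' Seed a mixed aggregate of cells on the lattice
#'
#' Builds the initial condition emulating dissociated cells settling in
#' a microwell: the most compact central disc of `sum(counts) *
#' target_area` sites is partitioned into contiguous, roughly equal
#' Voronoi-like patches (k-means on site coordinates), and cell types
#' are assigned to patches by a random permutation, giving a well-mixed
#' aggregate surrounded by medium. Deterministic given `seed`.
#'
#' @param counts Named integer vector `c(ES=, TS=, XEN=)` of cell
#'   numbers.
#' @param config Configuration list (lattice size and target area).
#' @param seed Integer seed.
#' @return A `cpm_lattice`.
#' @export
initialize_aggregate <- function(counts, config = default_config(),
                                 seed = 1L) {
  counts <- counts[c("ES", "TS", "XEN")]
  counts[is.na(counts)] <- 0L
  names(counts) <- c("ES", "TS", "XEN")
  n_cells <- sum(counts)
  if (n_cells < 1L) stop("need at least one cell")
  config <- validate_config(config)
  W <- config$lattice$width
  H <- config$lattice$height
  ta <- unlist(config$target_area)[c("ES", "TS", "XEN")]
  total_area <- as.integer(round(sum(counts * ta)))
  if (total_area > W * H) stop("cells do not fit on the lattice")

  ci <- (H + 1) / 2
  cj <- (W + 1) / 2
  coords <- expand.grid(i = seq_len(H), j = seq_len(W))
  d <- (coords$i - ci)^2 + (coords$j - cj)^2
  ord <- order(d, atan2(coords$j - cj, coords$i - ci))
  sel <- coords[ord[seq_len(total_area)], ]
  if (max(sqrt(d[ord[seq_len(total_area)]])) > min(W, H) / 2 - 1) {
    stop("cells do not fit: aggregate disc reaches the lattice edge")
  }

  for (attempt in 1:5) {
    assign_id <- local_seed(derive_seed(seed, attempt), {
      if (n_cells == 1L) rep(1L, nrow(sel)) else {
        km <- stats::kmeans(as.matrix(sel), centers = n_cells,
                            iter.max = 50L, nstart = 1L)
        km$cluster
      }
    })
    grid <- matrix(0L, H, W)
    grid[cbind(sel$i, sel$j)] <- as.integer(assign_id)
    contiguous <- vapply(seq_len(n_cells), function(id) {
      lab <- cpp_label_components((grid == id) * 1L,
                                  config$lattice$neighbourhood)
      max(lab) == 1L
    }, logical(1))
    if (all(contiguous)) break
    if (attempt == 5L) stop("could not seed contiguous cell patches")
  }

  type_vec <- rep(1:3, times = counts)
  type_vec <- local_seed(derive_seed(seed, 97L), sample(type_vec))
  new_lattice(grid, type_vec)
}

#' Total configuration energy of a lattice
#'
#' The CPM Hamiltonian: boundary contact energy over unlike neighbour
#' pairs plus quadratic area and perimeter constraints for every cell
#' (medium is unconstrained),
#' \deqn{H = \sum_{\langle i,j\rangle} J(\tau_i,\tau_j)(1-\delta_{\sigma_i
#'   \sigma_j}) + \sum_c \lambda_A (a_c - A_T)^2 +
#'   \sum_c \lambda_P (p_c - P_T)^2.}
#'
#' @param lattice A `cpm_lattice`.
#' @param J 4x4 contact-energy matrix ([contact_energy_matrix()]).
#' @param params Per-type constraint list ([cell_type_params()]).
#' @param neighbourhood Interaction neighbourhood order (1 or 2).
#' @return Scalar energy.
#' @export
hamiltonian <- function(lattice, J, params, neighbourhood = 2L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  if (length(lattice$cell_type) &&
      any(!lattice$cell_type %in% seq_along(lattice$types))) {
    stop("lattice contains cells of unknown type")
  }
  cpp_hamiltonian(lattice$grid, lattice$cell_type, J,
                  params$lambda_area, params$target_area,
                  params$lambda_perimeter, params$target_perimeter,
                  as.integer(neighbourhood))
}

#' Incremental energy of a single copy attempt
#'
#' Energy change if `candidate` (a neighbouring cell id or 0 for medium)
#' were copied into site (`row`, `col`). Returns 0 for a no-op copy and
#' `NA` for a forbidden copy that would annihilate a cell's last site.
#'
#' @inheritParams hamiltonian
#' @param row,col Site coordinates (1-based).
#' @param candidate Cell id to copy in.
#' @return Scalar energy difference, or `NA` (forbidden move).
#' @export
delta_h <- function(lattice, row, col, candidate, J, params,
                    neighbourhood = 2L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  cpp_delta_h(lattice$grid, lattice$cell_type, J,
              params$lambda_area, params$target_area,
              params$lambda_perimeter, params$target_perimeter,
              as.integer(neighbourhood), as.integer(row), as.integer(col),
              as.integer(candidate))
}

#' Advance a lattice by Monte Carlo steps
#'
#' Runs `n_mcs` Monte Carlo steps (each = width x height elementary copy
#' attempts) of Metropolis dynamics at the given temperature: a random
#' site and a random neighbour are drawn; if they hold different cell
#' ids the neighbour's id is copied in with probability
#' `min(1, exp(-dH / T))`. At `temperature <= 0` the dynamics quench:
#' only strictly energy-decreasing copies are accepted.
#'
#' @inheritParams hamiltonian
#' @param n_mcs Number of Monte Carlo steps.
#' @param temperature Boltzmann temperature.
#' @param seed Integer seed.
#' @return The evolved `cpm_lattice`.
#' @export
mcs <- function(lattice, J, params, n_mcs = 1L, temperature = 10,
                neighbourhood = 2L, seed = 1L) {
  stopifnot(inherits(lattice, "cpm_lattice"))
  out <- local_seed(seed, {
    cpp_run(lattice$grid, lattice$cell_type, J,
            params$lambda_area, params$target_area,
            params$lambda_perimeter, params$target_perimeter,
            as.integer(neighbourhood), temperature, as.integer(n_mcs),
            as.integer(max(n_mcs, 1L)))
  })
  new_lattice(out$snapshots[[length(out$snapshots)]], lattice$cell_type,
              lattice$types)
}

#' Run a full CPM simulation
#'
#' Seeds an aggregate (unless an initial lattice is supplied), evolves it
#' for `config$n_mcs` Monte Carlo steps, and records snapshots and
#' energies every `config$record_every` steps (plus the initial and
#' final states).
#'
#' @param config Configuration list ([default_config()]).
#' @param J 4x4 contact-energy matrix; defaults to the matrix implied by
#'   the built-in mean wild-type forces.
#' @param seed Integer seed governing initialization and dynamics.
#' @param initial Optional `cpm_lattice` to start from.
#' @return Object of class `cpm_trajectory`: list with `snapshots` (list
#'   of `cpm_lattice`), `mcs` (recorded step indices), `energies`,
#'   `params` (full parameter record) and `seed`.
#' @export
run_simulation <- function(config = default_config(), J = NULL, seed = 1L,
                           initial = NULL) {
  config <- validate_config(config)
  if (is.null(J)) {
    specs <- builtin_force_specs()
    forces <- vapply(c("ES-ES", "ES-TS", "ES-XEN", "TS-TS", "TS-XEN",
                       "XEN-XEN"),
                     function(p) lookup_force_spec(p, specs = specs)$mean_nN,
                     numeric(1))
    J <- contact_energy_matrix(forces, config)
  }
  params <- cell_type_params(config)
  lat <- if (is.null(initial)) {
    initialize_aggregate(unlist(config$cells), config,
                         seed = derive_seed(seed, 1L))
  } else initial
  out <- local_seed(derive_seed(seed, 2L), {
    cpp_run(lat$grid, lat$cell_type, J,
            params$lambda_area, params$target_area,
            params$lambda_perimeter, params$target_perimeter,
            as.integer(config$lattice$neighbourhood), config$temperature,
            config$n_mcs, config$record_every)
  })
  structure(list(
    snapshots = lapply(out$snapshots, new_lattice,
                       cell_type = lat$cell_type, types = lat$types),
    mcs = as.integer(out$mcs),
    energies = as.numeric(out$energies),
    params = list(config = config, J = J, type_params = params),
    seed = as.integer(seed)
  ), class = "cpm_trajectory")
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cpm_trajectory> %d snapshots over %d MCS; energy %.1f -> %.1f\n",
    length(x$snapshots), max(x$mcs), x$energies[1],
    x$energies[length(x$energies)]))
  invisible(x)
}
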