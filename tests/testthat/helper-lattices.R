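# Constructed lattices with known geometry, used across test files.
# Types: 1 = ES, 2 = TS, 3 = XEN, 0 = medium.

# A filled disc of one cell centred on an n x n lattice.
disc_lattice <- function(n = 20, radius = 5, type = 1L) {
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) g[i, j] <- 1L
  }
  new_lattice(g, type)
}

# Concentric rings: cell 1 (inner, type `inner`) inside cell 2
# (ring, type `outer`).
ring_lattice <- function(n = 24, r_in = 4, r_out = 8, inner = 1L,
                         outer = 3L) {
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 <= r_in^2) g[i, j] <- 1L
    else if (d2 <= r_out^2) g[i, j] <- 2L
  }
  new_lattice(g, c(inner, outer))
}

# Well-sorted fixture: XEN ring enveloping adjacent ES and TS
# half-disc compartments (the ETX-like arrangement).
etx_lattice <- function(n = 30, r_in = 7, r_out = 10) {
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 <= r_in^2) {
      g[i, j] <- if (j < ctr) 1L else 2L     # ES left, TS right
    } else if (d2 <= r_out^2) {
      g[i, j] <- 3L
    }
  }
  new_lattice(g, c(1L, 2L, 3L))
}

# Three vertical stripes inside a medium border: a | b | c.
stripe_lattice <- function(a = 1L, mid = 3L, b = 2L, n = 24, gap = FALSE) {
  g <- matrix(0L, n, n)
  third <- (n - 8) %/% 3
  rows <- 5:(n - 4)
  g[rows, 5:(4 + third)] <- 1L
  g[rows, (5 + third):(4 + 2 * third)] <- 2L
  g[rows, (5 + 2 * third):(n - 4)] <- 3L
  new_lattice(g, c(a, mid, b))
}

# Fully nested shells: outer / middle / inner types.
onion_lattice <- function(outer = 3L, middle = 1L, inner = 2L, n = 30,
                          radii = c(5, 8, 11)) {
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 <= radii[1]^2) g[i, j] <- 1L
    else if (d2 <= radii[2]^2) g[i, j] <- 2L
    else if (d2 <= radii[3]^2) g[i, j] <- 3L
  }
  new_lattice(g, c(inner, middle, outer))
}

# Ring of `outer` type around the two remaining types; `separated`
# inserts a thick band of the outer type between them.
env_fixture <- function(outer = 3L, separated = FALSE, n = 34,
                        r_in = 8, r_out = 11) {
  inner_types <- sort(setdiff(1:3, outer))
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 <= r_out^2) {
      if (d2 > r_in^2) g[i, j] <- 3L              # ring cell
      else if (separated && abs(i - ctr) < 2.5) g[i, j] <- 3L
      else if (separated) g[i, j] <- if (i < ctr) 1L else 2L
      else g[i, j] <- if (j < ctr) 1L else 2L
    }
  }
  new_lattice(g, c(inner_types, outer))
}

# Ring of `outer` type; interior split left/right between the two
# remaining types (type order), with horizontal bands of outer tissue
# fragmenting the first, second, or both inner tissues.
env_split_fixture <- function(outer = 3L, split = c("first", "second",
                                                    "both"),
                              n = 40, r_in = 10, r_out = 13) {
  split <- match.arg(split)
  inner <- sort(setdiff(1:3, outer))
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 > r_out^2) next
    if (d2 > r_in^2) { g[i, j] <- 3L; next }
    left <- j < ctr
    band <- abs(i - ctr) < 2.5
    cut <- (band && split == "both") ||
      (band && split == "first" && left) ||
      (band && split == "second" && !left)
    g[i, j] <- if (cut) 3L else if (left) 1L else 2L
  }
  new_lattice(g, c(inner, outer))
}

# No envelope: narrow ES and TS side stripes separated by a wide
# dominant middle stripe of `mid`; `split_first` fragments the left
# stripe with a band of the middle tissue.
open_stripe_fixture <- function(mid = 3L, split_first = FALSE, n = 40) {
  g <- matrix(0L, n, n)
  rows <- 8:32
  g[rows, 5:7] <- 1L
  g[rows, 8:27] <- 2L
  g[rows, 28:30] <- 3L
  if (split_first) g[19:21, 5:7] <- 2L
  sides <- sort(setdiff(1:3, mid))
  new_lattice(g, c(sides[1], mid, sides[2]))
}

# Three wedges of a disc meeting at the centre, all reaching the medium.
triangle_lattice <- function(n = 30, radius = 11) {
  g <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) {
      ang <- atan2(j - ctr, i - ctr)
      g[i, j] <- 1L + (floor((ang + pi) / (2 * pi / 3)) %% 3)
    }
  }
  new_lattice(g, c(1L, 2L, 3L))
}

# A random multi-cell lattice for property tests: scatter cells by a
# seeded quench-free assignment (not guaranteed contiguous).
random_lattice <- function(n = 16, n_cells = 6, seed = 1) {
  set.seed(seed)
  g <- matrix(0L, n, n)
  centre <- cbind(runif(n_cells, 4, n - 3), runif(n_cells, 4, n - 3))
  for (i in 1:n) for (j in 1:n) {
    d <- (centre[, 1] - i)^2 + (centre[, 2] - j)^2
    if (min(d) < 12) g[i, j] <- which.min(d)
  }
  types <- sample(1:3, n_cells, replace = TRUE)
  new_lattice(g, types)
}

# Standard small parameter set for unit tests.
test_params <- function(lambda_a = 1, lambda_p = 0.1, target_a = 24,
                        target_p = 30) {
  list(lambda_area = rep(lambda_a, 3), target_area = rep(target_a, 3),
       lambda_perimeter = rep(lambda_p, 3),
       target_perimeter = rep(target_p, 3))
}

test_J <- function() {
  types <- c("ES", "TS", "XEN", "Medium")
  J <- matrix(c(6, 13, 12, 25,
                13, 5, 14, 25,
                12, 14, 13, 8,
                25, 25, 8, 0), 4, 4,
              dimnames = list(types, types))
  (J + t(J)) / 2
}

# Brute-force Hamiltonian oracle: direct double loop over all site
# pairs and cells, independent of the C++ implementation.
oracle_hamiltonian <- function(lattice, J, params, nbhd = 2L) {
  g <- lattice$grid
  ct <- lattice$cell_type
  nr <- nrow(g); nc <- ncol(g)
  offs <- if (nbhd == 1L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  tyof <- function(id) if (id == 0L) 4L else ct[id]
  e <- 0
  for (i in 1:nr) for (j in 1:nc) for (o in offs) {
    ii <- i + o[1]; jj <- j + o[2]
    if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
    if (g[i, j] != g[ii, jj]) {
      e <- e + J[tyof(g[i, j]), tyof(g[ii, jj])] / 2  # each pair twice
    }
  }
  ids <- sort(unique(as.vector(g))); ids <- ids[ids > 0]
  for (id in ids) {
    a <- sum(g == id)
    p <- 0
    for (i in 1:nr) for (j in 1:nc) {
      if (g[i, j] != id) next
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + o[1]; jj <- j + o[2]
        nb <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) 0L else g[ii, jj]
        if (nb != id) p <- p + 1
      }
    }
    t <- ct[id]
    e <- e + params$lambda_area[t] * (a - params$target_area[t])^2 +
      params$lambda_perimeter[t] * (p - params$target_perimeter[t])^2
  }
  e
}

# Brute-force flood fill (4- or 8-connectivity), recursive-free.
oracle_components <- function(mask, nbhd = 2L) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (nbhd == 1L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (i in 1:nr) for (j in 1:nc) {
    if (mask[i, j] == 0 || seen[i, j]) next
    ncomp <- ncomp + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in offs) {
        ii <- p[1] + o[1]; jj <- p[2] + o[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (mask[ii, jj] != 0 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}

# Brute-force pairwise type-contact census (in-lattice links only,
# unordered pairs counted once; lattice-edge links count as medium).
oracle_contacts <- function(lattice, nbhd = 2L) {
  g <- lattice$grid; ct <- lattice$cell_type
  nr <- nrow(g); nc <- ncol(g)
  offs <- if (nbhd == 1L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  tyof <- function(id) if (id == 0L) 4L else ct[id]
  m <- matrix(0, 4, 4)
  for (i in 1:nr) for (j in 1:nc) for (o in offs) {
    ii <- i + o[1]; jj <- j + o[2]
    if (ii < 1 || ii > nr || jj < 1 || jj > nc) {
      if (g[i, j] != 0L) {
        a <- tyof(g[i, j])
        m[a, 4] <- m[a, 4] + 1
        m[4, a] <- m[4, a] + 1
      }
      next
    }
    if (g[i, j] == g[ii, jj]) next
    a <- tyof(g[i, j]); b <- tyof(g[ii, jj])
    m[a, b] <- m[a, b] + 1 / 2
    m[b, a] <- m[b, a] + ifelse(a == b, 0, 1 / 2)
  }
  dimnames(m) <- list(c(lattice$types, "Medium"), c(lattice$types, "Medium"))
  m
}

rot90_lattice <- function(lattice) {
  g <- lattice$grid
  new_lattice(t(g)[ncol(g):1, , drop = FALSE], lattice$cell_type,
              lattice$types)
}

mirror_lattice <- function(lattice) {
  g <- lattice$grid
  new_lattice(g[, ncol(g):1, drop = FALSE], lattice$cell_type,
              lattice$types)
}
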