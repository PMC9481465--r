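#' Contact angle of a symmetric cell doublet at force equilibrium
#'
#' Two identical adhering cells at mechanical equilibrium satisfy the
#' Young tension balance at the contact rim,
#' \deqn{\gamma_{cc} = 2\,\gamma_{cm}\cos(\theta/2),}
#' where \eqn{\gamma_{cm}} is the cell-medium cortical tension,
#' \eqn{\gamma_{cc}} the cell-cell interface tension, and \eqn{\theta}
#' the external contact angle spanned by the junction. \eqn{\theta = 180}
#' degrees is the full-envelopment / smooth-interface limit (vanishing
#' interface tension); \eqn{\theta = 0} means no adhesion
#' (\eqn{\gamma_{cc} = 2\gamma_{cm}}). Stronger adhesion (lower
#' \eqn{\gamma_{cc}}) gives a larger angle.
#'
#' @param gamma_cm Cortical (cell-medium) tension, `> 0`. Units are
#'   arbitrary; only the ratio matters.
#' @param gamma_cc Cell-cell interface tension, in `[0, 2 * gamma_cm]`.
#' @return Contact angle in degrees, in `[0, 180]`. Vectorized.
#' @examples
#' contact_angle(1, 1)   # 120 degrees
#' contact_angle(1, 0)   # 180: smooth interface
#' @export
contact_angle <- function(gamma_cm, gamma_cc) {
  if (any(gamma_cm <= 0)) stop("gamma_cm must be > 0")
  if (any(gamma_cc < 0)) stop("gamma_cc must be >= 0")
  r <- gamma_cc / (2 * gamma_cm)
  if (any(r > 1 + 1e-12)) {
    stop("no equilibrium: gamma_cc exceeds 2 * gamma_cm")
  }
  2 * acos(pmin(r, 1)) * 180 / pi
}

#' Relative interface tension from a measured contact angle
#'
#' Inverse of [contact_angle()]: returns the ratio
#' \eqn{\gamma_{cc}/\gamma_{cm} = 2\cos(\theta/2)} implied by an observed
#' doublet contact angle.
#'
#' @param theta_deg Contact angle in degrees, in `[0, 180]`. Vectorized.
#' @return The dimensionless tension ratio in `[0, 2]`.
#' @export
relative_interface_tension <- function(theta_deg) {
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stop("theta_deg must lie in [0, 180]")
  }
  2 * cos(theta_deg / 2 * pi / 180)
}

#' Concordance between contact-angle and adhesion-force rankings
#'
#' The doublet model predicts that pairs with larger adhesion force show
#' larger contact angles, so the two per-pair rankings should agree. This
#' computes Kendall's tau between mean angles and mean forces over the
#' common set of pairs.
#'
#' @param mean_angles Named numeric vector of mean contact angles
#'   (degrees), names are pair ids in any order convention.
#' @param mean_forces Named numeric vector of mean adhesion forces (nN),
#'   same pair set.
#' @return List with `tau`, `n_pairs`, and the aligned `pairs` data
#'   frame (pair id, angle, force) ordered by decreasing force.
#' @export
angle_force_concordance <- function(mean_angles, mean_forces) {
  names(mean_angles) <- vapply(names(mean_angles), pair_id, character(1))
  names(mean_forces) <- vapply(names(mean_forces), pair_id, character(1))
  common <- intersect(names(mean_angles), names(mean_forces))
  missing_a <- setdiff(names(mean_forces), names(mean_angles))
  missing_f <- setdiff(names(mean_angles), names(mean_forces))
  if (length(missing_a) || length(missing_f)) {
    stop("pair sets differ; missing angles for [",
         paste(missing_a, collapse = ", "), "], missing forces for [",
         paste(missing_f, collapse = ", "), "]")
  }
  if (length(common) < 3L) stop("need at least 3 common pairs")
  a <- mean_angles[common]
  f <- mean_forces[common]
  tau <- stats::cor(a, f, method = "kendall")
  ord <- order(-f)
  list(tau = unname(tau), n_pairs = length(common),
       pairs = data.frame(pair_id = common[ord], mean_angle = unname(a[ord]),
                          mean_force = unname(f[ord])))
}

#' Per-pair tension ratios with bootstrap confidence intervals
#'
#' Reads a per-doublet angle table (columns `pair_id`, `theta_deg`),
#' computes each pair's mean angle and implied
#' \eqn{\gamma_{cc}/\gamma_{cm}}, with seeded percentile-bootstrap
#' confidence intervals on the ratio.
#'
#' @param angles Data frame with columns `pair_id` and `theta_deg`.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Data frame: `pair_id`, `n`, `mean_theta`, `gamma_ratio`,
#'   `ci_lo`, `ci_hi`.
#' @export
doublet_tension_table <- function(angles, n_boot = 2000L, conf = 0.95,
                                  seed = 1L) {
  stopifnot(is.data.frame(angles),
            all(c("pair_id", "theta_deg") %in% names(angles)))
  angles$pair_id <- vapply(angles$pair_id, pair_id, character(1))
  pairs <- sort(unique(angles$pair_id))
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  rows <- lapply(seq_along(pairs), function(i) {
    th <- angles$theta_deg[angles$pair_id == pairs[i]]
    ratios <- local_seed(derive_seed(seed, i), {
      vapply(seq_len(n_boot), function(b) {
        relative_interface_tension(mean(sample(th, replace = TRUE)))
      }, numeric(1))
    })
    ci <- stats::quantile(ratios, probs, names = FALSE)
    data.frame(pair_id = pairs[i], n = length(th), mean_theta = mean(th),
               gamma_ratio = relative_interface_tension(mean(th)),
               ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, rows)
}
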