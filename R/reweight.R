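#' Specification of a beta-region reweighting
#'
#' Defines the rectangle of Ramachandran space treated as beta-strand-like
#' and the enhancement factor applied to conformers inside it. The default
#' bounds are the open rectangle -180 < phi < -110, 120 < psi < 180 (degrees).
#'
#' @param epsilon_beta Positive enhancement factor; 1 means no reweighting.
#' @param phi_bounds,psi_bounds Length-2 open intervals in degrees, within
#'   (-180, 180].
#' @return An object of class `reweight_spec`.
#' @export
reweight_spec <- function(epsilon_beta = 1.2,
                          phi_bounds = c(-180, -110),
                          psi_bounds = c(120, 180)) {
  stopifnot(epsilon_beta > 0, length(phi_bounds) == 2, length(psi_bounds) == 2,
            phi_bounds[1] < phi_bounds[2], psi_bounds[1] < psi_bounds[2],
            all(phi_bounds >= -180), all(phi_bounds <= 180),
            all(psi_bounds >= -180), all(psi_bounds <= 180))
  structure(list(epsilon_beta = epsilon_beta, phi_bounds = phi_bounds,
                 psi_bounds = psi_bounds),
            class = "reweight_spec")
}

#' @export
print.reweight_spec <- function(x, ...) {
  cat("<reweight_spec> eps_beta = ", x$epsilon_beta, ", beta region ",
      x$phi_bounds[1], " < phi < ", x$phi_bounds[2], ", ",
      x$psi_bounds[1], " < psi < ", x$psi_bounds[2], " (deg)\n", sep = "")
  invisible(x)
}

#' Is a conformer in the beta-strand-like region?
#'
#' Strict open inequalities on both bounds of both angles: points exactly on
#' a boundary are outside (a measure-zero choice on continuous ensembles, but
#' it must be deterministic).
#'
#' @param phi,psi Angles in degrees, wrapped to (-180, 180].
#' @param spec A [reweight_spec()].
#' @return Logical vector.
#' @export
in_beta_region <- function(phi, psi, spec = reweight_spec()) {
  phi > spec$phi_bounds[1] & phi < spec$phi_bounds[2] &
    psi > spec$psi_bounds[1] & psi < spec$psi_bounds[2]
}

#' Reweight a crosspeak histogram toward beta-strand conformers
#'
#' Each conformer record of the residue type is weighted `epsilon_beta` if
#' its (phi, psi) lies in the beta region, and
#' `(N_T - epsilon_beta * N_beta) / (N_T - N_beta)` otherwise, so the total
#' crosspeak volume is conserved. The difference histogram
#' (reweighted - original) is then exactly proportional to
#' `epsilon_beta - 1`, so a single reference value characterises the whole
#' family. Extremes of the difference are reported as percent of the original
#' histogram's maximum.
#'
#' @inheritParams crosspeak_histogram
#' @param spec A [reweight_spec()].
#' @return A `reweight_result`: list with `original`, `reweighted`,
#'   `difference` (all `histogram2d`), `n_beta`, `n_total`, `epsilon_beta`,
#'   `nonbeta_factor`, `max_pct`, `min_pct`.
#' @export
reweight_crosspeak <- function(table, residue_type,
                               shift_pair = c("CA_CB", "CO_CA", "N_CA"),
                               spec = reweight_spec(), bin_width_ppm = 0.5,
                               ranges = NULL) {
  shift_pair <- match.arg(shift_pair)
  eps <- spec$epsilon_beta
  sel <- table$residue_type == residue_type
  nt <- sum(sel)
  if (nt == 0) stop("no records of residue type '", residue_type, "'", call. = FALSE)
  beta <- in_beta_region(table$phi, table$psi, spec) & sel
  nb <- sum(beta)
  if (nb == nt && eps != 1) {
    stop("degenerate input: every '", residue_type, "' conformer is in the ",
         "beta region, so the volume-conserving factor is undefined",
         call. = FALSE)
  }
  if (nb == 0 && eps != 1) {
    warning("no conformers of type '", residue_type,
            "' in the beta region; reweighting is a no-op")
  }
  nonbeta_factor <- if (nb < nt) (nt - eps * nb) / (nt - nb) else 1
  w <- rep(1, nrow(table))
  w[sel] <- nonbeta_factor
  w[beta] <- eps
  original <- crosspeak_histogram(table, residue_type, shift_pair,
                                  bin_width_ppm, ranges)
  edge_ranges <- list(x = range(original$x_edges), y = range(original$y_edges))
  reweighted <- crosspeak_histogram(table, residue_type, shift_pair,
                                    bin_width_ppm, edge_ranges, weights = w)
  difference <- new_histogram2d(reweighted$counts - original$counts,
                                original$x_edges, original$y_edges,
                                axis_kind = "shift", labels = original$labels)
  peak <- max(original$counts)
  structure(list(original = original, reweighted = reweighted,
                 difference = difference,
                 n_beta = nb, n_total = nt, epsilon_beta = eps,
                 nonbeta_factor = nonbeta_factor,
                 max_pct = 100 * max(difference$counts) / peak,
                 min_pct = 100 * min(difference$counts) / peak),
            class = "reweight_result")
}

#' @export
print.reweight_result <- function(x, ...) {
  cat("<reweight_result> eps_beta = ", x$epsilon_beta, ": N_beta = ", x$n_beta,
      " of N_T = ", x$n_total, " (non-beta factor ",
      format(x$nonbeta_factor, digits = 6), ")\n", sep = "")
  cat("  difference extremes: ", format(x$max_pct, digits = 3), "% / ",
      format(x$min_pct, digits = 3), "% of original crosspeak maximum\n",
      sep = "")
  invisible(x)
}

#' Tidy and summarise a reweighting result
#'
#' @param x A `reweight_result` from [reweight_crosspeak()].
#' @param ... Unused.
#' @return `tidy()`: long tibble of the difference histogram bins.
#'   `glance()`: one-row tibble of the scalar summaries.
#' @method tidy reweight_result
#' @export
tidy.reweight_result <- function(x, ...) {
  out <- tidy(x$difference)
  names(out) <- c("x_ppm", "y_ppm", "difference")
  out$original <- as.vector(x$original$counts)
  out$reweighted <- as.vector(x$reweighted$counts)
  out
}

#' @rdname tidy.reweight_result
#' @method glance reweight_result
#' @export
glance.reweight_result <- function(x, ...) {
  tibble::tibble(epsilon_beta = x$epsilon_beta, n_beta = x$n_beta,
                 n_total = x$n_total, nonbeta_factor = x$nonbeta_factor,
                 max_pct = x$max_pct, min_pct = x$min_pct)
}

#' Rescale a difference crosspeak to another enhancement factor
#'
#' Because the difference is exactly proportional to `epsilon_beta - 1`,
#' a difference computed at one factor converts to any other by
#' `(to_eps - 1) / (from_eps - 1)`.
#'
#' @param diff A difference `histogram2d`.
#' @param from_eps Factor the difference was computed at; must not be 1.
#' @param to_eps Target factor.
#' @return A `histogram2d`.
#' @export
scale_difference <- function(diff, from_eps, to_eps) {
  stopifnot(inherits(diff, "histogram2d"))
  if (from_eps == 1) {
    stop("from_eps = 1: the difference at eps = 1 is identically zero and ",
         "carries no scale", call. = FALSE)
  }
  new_histogram2d(diff$counts * (to_eps - 1) / (from_eps - 1),
                  diff$x_edges, diff$y_edges, diff$axis_kind, diff$labels)
}

#' Detectability bound on the beta-population enhancement
#'
#' Given an observed experimental difference level and the difference level
#' simulated at a reference enhancement factor, linear scaling in
#' `epsilon_beta - 1` gives the enhancement (in percent) at which the
#' simulation would match the observation:
#' `(eps_ref - 1) * observed / simulated * 100`.
#'
#' @param observed_fraction Observed difference magnitude (any consistent
#'   fractional measure).
#' @param simulated_fraction_at_eps The same measure from a simulation at
#'   `eps_ref`; must be positive.
#' @param eps_ref Reference enhancement factor (> 1).
#' @return The bounding enhancement, as percent of the beta population.
#' @export
detectability_bound <- function(observed_fraction, simulated_fraction_at_eps,
                                eps_ref) {
  stopifnot(eps_ref > 1, observed_fraction >= 0)
  if (simulated_fraction_at_eps <= 0) {
    stop("simulated fraction must be positive", call. = FALSE)
  }
  (eps_ref - 1) * observed_fraction / simulated_fraction_at_eps * 100
}
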