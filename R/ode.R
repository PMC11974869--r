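# Mass-action right-hand side of a (sub)network in a well-mixed volume of
# `n_mix` chambers: bimolecular per-pair propensities are scaled by 1/n_mix
# because a reactant pair must share a chamber.
network_ode_rhs <- function(stoich, reactant_idx, propensity, n_mix) {
  force(stoich); force(reactant_idx); force(propensity); force(n_mix)
  function(t, y, parms) {
    v <- numeric(length(propensity))
    for (j in seq_along(propensity)) {
      ri <- reactant_idx[[j]]
      v[j] <- if (length(ri) == 2L)
        propensity[j] * y[ri[1]] * y[ri[2]] / n_mix
      else propensity[j] * y[ri[1]]
    }
    list(as.numeric(stoich %*% v))
  }
}

#' Extract the deterministic activating module
#'
#' The activating (NKG2D) module in the disjoint geometry decouples from
#' inhibitory signaling; its local kinetics are described by a 14-variable
#' mass-action system (free ligand, receptor, SFK, Vav1, pVav1 and nine
#' receptor-complex states). The extraction asserts that the reconstruction
#' yields exactly 14 state variables and fails loudly otherwise.
#'
#' @param network an \code{nk_network} built with default flags.
#' @return list with \code{species} (the 14 names), \code{stoich},
#'   \code{reactant_idx}, \code{propensity}.
#' @export
activating_module <- function(network) {
  spec <- yaml::read_yaml(nk_parameter_file())
  ode_species <- vapply(spec$species, function(s)
    if (isTRUE(s$ode)) s$name else NA_character_, character(1))
  ode_species <- ode_species[!is.na(ode_species)]
  if (length(ode_species) != 14L)
    stop("activating module reconstruction yielded ",
         length(ode_species), " state variables; expected 14")
  keep_sp <- match(ode_species, network$species$name)
  in_set <- function(ri) all(ri %in% keep_sp)
  keep_rx <- vapply(seq_along(network$reactant_idx), function(j) {
    prod_sp <- which(network$stoich[, j] != 0L)
    network$reactions$kp[j] == "none" &&
      in_set(network$reactant_idx[[j]]) && in_set(prod_sp)
  }, logical(1))
  stoich <- network$stoich[keep_sp, keep_rx, drop = FALSE]
  reactant_idx <- lapply(network$reactant_idx[keep_rx],
                         function(ri) match(ri, keep_sp))
  list(species = ode_species, stoich = stoich,
       reactant_idx = reactant_idx,
       propensity = network$reactions$propensity[keep_rx])
}

#' Solve the deterministic activating-module rate equations
#'
#' Integrates the 14 coupled ODEs of the activating module for a given
#' number of initially formed NKG2D--NKG2DL complexes sharing the box with
#' the free SFK and Vav1 pools, in the well-mixed limit of the lattice
#' (bimolecular rates scaled by the number of chambers).
#'
#' @param network an \code{nk_network}.
#' @param n_complexes initial receptor--ligand complexes (state \code{RL}).
#' @param t_end integration horizon in seconds.
#' @param n_mix number of chambers in the mixing volume (defaults to the
#'   full lattice).
#' @param pools named vector overriding the free SFK / Vav1 pools (defaults
#'   from the parameter file).
#' @param rtol,atol integrator tolerances.
#' @return list with \code{times}, \code{states} (time x species matrix),
#'   \code{pvav1} (free + complex-bound), \code{ss_pvav1} (value at
#'   \code{t_end}), \code{per_complex} (ss per initial complex), and
#'   \code{t_ss} (first time within 5 percent of the final value).
#' @examples
#' \donttest{
#' sol <- solve_activating_ode(build_network(), n_complexes = 1)
#' sol$per_complex   # slightly below 0.4
#' sol$t_ss          # a few seconds
#' }
#' @export
solve_activating_ode <- function(network, n_complexes = 1, t_end = 40,
                                 n_mix = network$geom$n_chambers,
                                 pools = NULL, rtol = 1e-8, atol = 1e-10) {
  mod <- activating_module(network)
  y0 <- stats::setNames(numeric(length(mod$species)), mod$species)
  y0["RL"] <- n_complexes
  y0["SFK"] <- network$counts$SFK
  y0["Vav1"] <- network$counts$Vav1
  if (!is.null(pools)) y0[names(pools)] <- pools
  times <- seq(0, t_end, by = min(0.05, t_end / 200))
  rhs <- network_ode_rhs(mod$stoich, mod$reactant_idx, mod$propensity, n_mix)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed to converge; istate = ",
         attr(sol, "istate")[1])
  states <- sol[, -1, drop = FALSE]
  pvav1 <- states[, "pVav1"] + states[, "RLp2_pV"]
  ss <- pvav1[length(pvav1)]
  t_ss <- if (ss == 0) 0 else times[which(abs(pvav1 - ss) <= 0.05 * ss)[1]]
  list(times = times, states = states, pvav1 = pvav1,
       ss_pvav1 = ss,
       per_complex = if (n_complexes > 0) ss / n_complexes else 0,
       t_ss = t_ss)
}

#' Expected number of distinct sites visited by a lattice random walk
#'
#' For an n-step random walk on the square lattice the number of distinct
#' sites visited is well approximated by \eqn{\pi n / \ln(5.692 n)}
#' (natural logarithm).
#'
#' @param n number of steps (>= 1; vectorized).
#' @return expected distinct sites visited.
#' @export
visited_sites <- function(n) {
  if (any(n < 1)) stop("n must be at least 1")
  pi * n / log(5.692 * n)
}

#' Time for a diffusing ligand to cover its Voronoi cell
#'
#' With M ligand molecules in the box, the average Voronoi cell contains
#' \code{n_chambers / M} chambers. The time \eqn{\tau} to visit a fraction
#' of that cell solves
#' \eqn{n_v = \pi (\tau / t_{step}) / \ln(5.692 \tau / t_{step})}
#' where \eqn{t_{step}} is the mean hop time. Solved by bracketed
#' root-finding.
#'
#' @param M number of ligand molecules sharing the box (>= 1).
#' @param fraction fraction of the Voronoi cell to visit (0 < fraction <= 1).
#' @param t_step mean hop time in seconds (1/6 s for NKG2DL at
#'   D = 0.01 um^2/s on the 40 nm lattice).
#' @param geom an \code{nk_geometry}.
#' @return estimated time \eqn{\tau} in seconds.
#' @examples
#' visit_time(200)            # ~13.5 s: full cell at M = 200
#' visit_time(40, 0.5)        # ~40 s: half cell at M = 40
#' @export
visit_time <- function(M, fraction = 1, t_step = 1 / 6,
                       geom = geometry_params()) {
  stopifnot(M >= 1, fraction > 0, fraction <= 1, t_step > 0)
  n_v <- fraction * geom$n_chambers / M
  f <- function(n) visited_sites(n) - n_v
  if (f(1) > 0 || f(1e12) < 0)
    stop("no root in bracket for n_v = ", signif(n_v, 4))
  n_star <- stats::uniroot(f, c(1, 1e12), tol = 1e-10)$root
  n_star * t_step
}
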