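# Flatten the network into the arrays the C++ kernel consumes.
encode_network <- function(network) {
  stoich <- network$stoich
  n_rx <- ncol(stoich)
  r1 <- integer(n_rx); r2 <- integer(n_rx)
  for (j in seq_len(n_rx)) {
    ri <- network$reactant_idx[[j]]
    r1[j] <- ri[1] - 1L
    r2[j] <- if (length(ri) == 2L) ri[2] - 1L else -1L
  }
  s_sp <- integer(0); s_delta <- integer(0); s_off <- integer(n_rx + 1L)
  for (j in seq_len(n_rx)) {
    nz <- which(stoich[, j] != 0L)
    s_off[j + 1L] <- s_off[j] + length(nz)
    s_sp <- c(s_sp, nz - 1L)
    s_delta <- c(s_delta, stoich[nz, j])
  }
  list(r1 = r1, r2 = r2, rconst = network$reactions$propensity,
       s_off = s_off, s_sp = s_sp, s_delta = s_delta,
       hop = network$species$hop_rate,
       conf = match(network$species$confinement,
                    c("none", "nkg2d", "kir")) - 1L)
}

#' Simulate one stochastic trajectory
#'
#' Statistically exact spatial Gillespie simulation of the
#' reaction--diffusion master equation from an initial configuration:
#' same-chamber reaction events and nearest-neighbour diffusion hops
#' (total per-molecule rate \eqn{D/l_0^2}) on the periodic lattice, with
#' cluster-confined species never crossing their mask boundary.
#'
#' @param config an \code{nk_config}.
#' @param network the \code{nk_network} to simulate.
#' @param t_end end time in seconds.
#' @param sample_times increasing vector of recording times (defaults to
#'   every second from 0 to \code{t_end}).
#' @param seed integer seed; \code{NULL} continues the current RNG stream.
#' @param max_events abort guard on the number of simulated events.
#' @return An \code{nk_trajectory}: list with \code{times}, \code{totals}
#'   (samples x species matrix of box-wide copy numbers), \code{pvav1}
#'   (total phosphorylated Vav1: free plus complex-bound), the final
#'   per-chamber \code{final_counts}, and \code{n_events}.
#' @export
simulate_trajectory <- function(config, network, t_end = 20,
                                sample_times = NULL, seed = NULL,
                                max_events = 5e9) {
  stopifnot(t_end > 0)
  if (is.null(sample_times)) sample_times <- seq(0, t_end, by = 1)
  sample_times <- sort(unique(c(sample_times, t_end)))
  if (any(sample_times < 0)) stop("sample times must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  enc <- encode_network(network)
  res <- sim_kmc_cpp(config$counts, config$mask_nkg2d, config$mask_kir,
                     enc$hop, enc$conf, config$geom$n_side,
                     enc$r1, enc$r2, enc$rconst,
                     enc$s_off, enc$s_sp, enc$s_delta,
                     sample_times, max_events)
  totals <- res$totals
  colnames(totals) <- network$species$name
  pv <- pvav1_species(network)
  structure(list(times = sample_times, totals = totals,
                 pvav1 = rowSums(totals[, pv, drop = FALSE]),
                 final_counts = {
                   fc <- res$final_counts
                   colnames(fc) <- network$species$name
                   fc
                 },
                 n_events = res$n_events, mode = config$mode),
            class = "nk_trajectory")
}

#' @export
print.nk_trajectory <- function(x, ...) {
  cat(sprintf(
    "<nk_trajectory> %d samples to t=%gs, %.3g events, final pVav1 %g\n",
    length(x$times), max(x$times), x$n_events, x$pvav1[length(x$pvav1)]))
  invisible(x)
}

#' Per-sample conserved moiety totals of a trajectory
#'
#' @param traj an \code{nk_trajectory}.
#' @param network the network it was simulated with.
#' @return samples x moieties matrix; each column must be constant in time.
#' @export
moiety_totals <- function(traj, network) {
  traj$totals %*% network$moieties
}

#' Simulate an ensemble of replicate trajectories across ligand doses
#'
#' Each replicate uses a freshly generated initial configuration (new
#' cluster and molecule placements) and an independent RNG stream derived
#' from the master seed. The observable recorded is total pVav1 (free plus
#' complex-bound) at the sample times; the ensemble across replicates at a
#' fixed time is the response distribution of a clonal NK-cell population.
#'
#' @param network an \code{nk_network}.
#' @param mode geometry mode passed to [make_config()].
#' @param doses vector of NKG2DL copy numbers (the input alphabet).
#' @param hlac HLA-C level: \code{"low"}, \code{"high"} or a count.
#' @param n_reps replicates per dose (>= 2).
#' @param t_end,sample_times as in [simulate_trajectory()].
#' @param seed master seed; per-replicate seeds are drawn from it and
#'   recorded in the result.
#' @param ... further arguments to [make_config()] (cluster numbers etc.).
#' @return An \code{nk_ensemble}: list with \code{pvav1} (list over doses of
#'   replicate x time matrices), \code{doses}, \code{times}, \code{mode},
#'   \code{hlac}, and the per-replicate \code{seeds}.
#' @export
run_ensemble <- function(network, mode, doses, hlac = "low", n_reps = 30,
                         t_end = 20, sample_times = NULL, seed = 1, ...) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (length(doses) < 1) stop("at least one dose is required")
  if (is.null(sample_times)) sample_times <- seq(0, t_end, by = 1)
  sample_times <- sort(unique(c(sample_times, t_end)))
  set.seed(seed)
  seeds <- matrix(sample.int(2147483647L, length(doses) * n_reps),
                  nrow = n_reps, ncol = length(doses))
  pvav1 <- vector("list", length(doses))
  names(pvav1) <- as.character(doses)
  for (d in seq_along(doses)) {
    m <- matrix(NA_real_, nrow = n_reps, ncol = length(sample_times))
    for (r in seq_len(n_reps)) {
      set.seed(seeds[r, d])
      cfg <- make_config(mode,
                         counts = cell_counts(nkg2dl = doses[d], hlac = hlac,
                                              network = network),
                         network = network, seed = NULL, ...)
      traj <- simulate_trajectory(cfg, network, t_end = t_end,
                                  sample_times = sample_times, seed = NULL)
      m[r, ] <- traj$pvav1
    }
    pvav1[[d]] <- m
  }
  structure(list(pvav1 = pvav1, doses = doses, times = sample_times,
                 mode = mode, hlac = hlac, n_reps = n_reps, seeds = seeds),
            class = "nk_ensemble")
}

#' @export
print.nk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<nk_ensemble> mode %s, HLA-C %s: %d doses x %d replicates to t=%gs\n",
    x$mode, as.character(x$hlac), length(x$doses), x$n_reps, max(x$times)))
  invisible(x)
}

#' Summarize an ensemble as mean +/- SD pVav1 per dose and time
#'
#' @param object an \code{nk_ensemble}.
#' @param ... unused.
#' @return data.frame with dose, time, n, mean, sd, se.
#' @export
summary.nk_ensemble <- function(object, ...) {
  rows <- list()
  for (d in seq_along(object$doses)) {
    m <- object$pvav1[[d]]
    rows[[d]] <- data.frame(
      dose = object$doses[d], time = object$times, n = nrow(m),
      mean = colMeans(m), sd = apply(m, 2, stats::sd))
  }
  out <- do.call(rbind, rows)
  out$se <- out$sd / sqrt(out$n)
  rownames(out) <- NULL
  out
}

#' Extract the pVav1 response samples of an ensemble at one time
#'
#' @param ensemble an \code{nk_ensemble}.
#' @param time sample time (must be one of the recorded times).
#' @return named list over doses of numeric replicate vectors.
#' @export
responses_at <- function(ensemble, time) {
  i <- match(time, ensemble$times)
  if (is.na(i)) stop("time ", time, " was not recorded")
  lapply(ensemble$pvav1, function(m) m[, i])
}
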