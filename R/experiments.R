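#' Specify an in-silico experiment
#'
#' Bundles the study-design choices of a simulation campaign: receptor
#' geometries, ligand-dose alphabet, HLA-C levels, kinetic-proofreading
#' variant, replicate count, horizon and master seed. The \code{"fast"}
#' profile (3 doses, 30 replicates/dose) is sized to separate MI above
#' versus below 1 bit; the \code{"full"} profile (5 doses, 200
#' replicates/dose) targets distribution-level quantities such as Gamma-fit
#' KL divergences.
#'
#' @param geometries subset of disjoint / overlapping / homogeneous.
#' @param profile \code{"fast"} or \code{"full"} (sets dose set and
#'   replicate count unless given explicitly).
#' @param doses NKG2DL copy-number alphabet (overrides the profile).
#' @param hlac HLA-C levels to run (\code{"low"}, \code{"high"}).
#' @param kp_variant \code{"both"}, \code{"no-activating"},
#'   \code{"no-inhibitory"} or \code{"neither"}.
#' @param n_reps replicates per dose (>= 2; overrides the profile).
#' @param t_end simulated horizon (s).
#' @param eval_times times at which channels are evaluated.
#' @param seed master seed.
#' @param n_nkg2d_clusters,n_kir_clusters,mean_size cluster-map settings.
#' @return list of class \code{nk_experiment_spec}.
#' @export
experiment_spec <- function(geometries = c("disjoint", "overlapping",
                                           "homogeneous"),
                            profile = c("fast", "full"),
                            doses = NULL,
                            hlac = c("low", "high"),
                            kp_variant = c("both", "no-activating",
                                           "no-inhibitory", "neither"),
                            n_reps = NULL, t_end = 20, eval_times = t_end,
                            seed = 1,
                            n_nkg2d_clusters = 120, n_kir_clusters = 350,
                            mean_size = 8) {
  profile <- match.arg(profile)
  kp_variant <- match.arg(kp_variant)
  geometries <- match.arg(geometries, several.ok = TRUE)
  hlac <- match.arg(hlac, several.ok = TRUE)
  if (is.null(doses))
    doses <- if (profile == "fast") c(20, 100, 400)
             else c(20, 40, 100, 200, 400)
  if (length(doses) < 1) stop("dose list must not be empty")
  if (is.null(n_reps)) n_reps <- if (profile == "fast") 30 else 200
  if (n_reps < 2) stop("replicates must be at least 2")
  structure(list(geometries = geometries, profile = profile, doses = doses,
                 hlac = hlac, kp_variant = kp_variant, n_reps = n_reps,
                 t_end = t_end, eval_times = eval_times, seed = seed,
                 n_nkg2d_clusters = n_nkg2d_clusters,
                 n_kir_clusters = n_kir_clusters, mean_size = mean_size),
            class = "nk_experiment_spec")
}

kp_flags <- function(variant) {
  switch(variant,
         "both" = c(TRUE, TRUE),
         "no-activating" = c(FALSE, TRUE),
         "no-inhibitory" = c(TRUE, FALSE),
         "neither" = c(FALSE, FALSE))
}

# deterministic sub-seed per condition, derived from the master seed
condition_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483647L, n)
}

run_conditions <- function(spec, network) {
  combos <- expand.grid(geometry = spec$geometries, hlac = spec$hlac,
                        stringsAsFactors = FALSE)
  combos$seed <- condition_seeds(spec$seed, nrow(combos))
  ensembles <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ensembles[[i]] <- run_ensemble(
      network, combos$geometry[i], spec$doses, hlac = combos$hlac[i],
      n_reps = spec$n_reps, t_end = spec$t_end, seed = combos$seed[i],
      n_nkg2d_clusters = spec$n_nkg2d_clusters,
      n_kir_clusters = spec$n_kir_clusters, mean_size = spec$mean_size)
  }
  names(ensembles) <- paste(combos$geometry, combos$hlac, sep = ".")
  list(combos = combos, ensembles = ensembles)
}

#' Dose-response tables across geometries
#'
#' Runs the configured ensembles and tabulates mean, SD and SE of total
#' pVav1 per (geometry, HLA-C level, dose, time).
#'
#' @param spec an \code{nk_experiment_spec}.
#' @param network optional prebuilt \code{nk_network} matching the spec's
#'   KP variant.
#' @return list of class \code{nk_dose_response}: \code{table}
#'   (data.frame) and the raw \code{ensembles}.
#' @export
run_dose_response <- function(spec, network = NULL) {
  if (is.null(network)) {
    fl <- kp_flags(spec$kp_variant)
    network <- build_network(fl[1], fl[2])
  }
  rc <- run_conditions(spec, network)
  tabs <- lapply(seq_along(rc$ensembles), function(i) {
    tb <- summary(rc$ensembles[[i]])
    tb$geometry <- rc$combos$geometry[i]
    tb$hlac <- rc$combos$hlac[i]
    tb
  })
  tab <- do.call(rbind, tabs)
  structure(list(table = tab, ensembles = rc$ensembles,
                 combos = rc$combos, spec = spec),
            class = "nk_dose_response")
}

# MI and Blahut-Arimoto capacity of one ensemble at one time
info_from_ensemble <- function(ensemble, time, binwidth = 1) {
  rs <- responses_at(ensemble, time)
  ch <- suppressWarnings(build_channel(rs, binwidth))
  ba <- blahut_arimoto(ch)
  list(mi = mutual_information(ch), cc = ba$cc, q_star = ba$Q_star,
       channel = ch)
}

#' Mutual information and channel capacity across conditions
#'
#' Builds the dose-to-pVav1 channel from replicate ensembles at each
#' requested evaluation time and reports plug-in MI at uniform input
#' distribution alongside the Blahut--Arimoto capacity and its
#' capacity-achieving input distribution.
#'
#' @param spec an \code{nk_experiment_spec}.
#' @param ensembles optional precomputed list as produced by
#'   [run_dose_response()] (element \code{ensembles}) to avoid re-running
#'   the simulations; must match the spec's conditions.
#' @param network optional prebuilt network.
#' @return list of class \code{nk_info_analysis}: \code{table} (geometry,
#'   hlac, time, mi, cc), \code{q_star} (named list of capacity-achieving
#'   input distributions), and the \code{ensembles}.
#' @export
run_info_analysis <- function(spec, ensembles = NULL, network = NULL) {
  if (is.null(ensembles)) {
    if (is.null(network)) {
      fl <- kp_flags(spec$kp_variant)
      network <- build_network(fl[1], fl[2])
    }
    rc <- run_conditions(spec, network)
    ensembles <- rc$ensembles
    combos <- rc$combos
  } else {
    combos <- data.frame(
      geometry = vapply(ensembles, `[[`, "", "mode"),
      hlac = vapply(ensembles, function(e) as.character(e$hlac), ""),
      stringsAsFactors = FALSE)
  }
  if (any(vapply(ensembles, `[[`, 0, "n_reps") < 2))
    stop("insufficient replicates per dose")
  rows <- list(); qstar <- list()
  for (i in seq_along(ensembles)) {
    for (tt in spec$eval_times) {
      inf <- info_from_ensemble(ensembles[[i]], tt)
      key <- sprintf("%s.%s.t%g", combos$geometry[i], combos$hlac[i], tt)
      rows[[key]] <- data.frame(geometry = combos$geometry[i],
                                hlac = combos$hlac[i], time = tt,
                                mi = inf$mi, cc = inf$cc)
      qstar[[key]] <- stats::setNames(inf$q_star,
                                      as.character(spec$doses))
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(table = tab, q_star = qstar, ensembles = ensembles,
                 spec = spec),
            class = "nk_info_analysis")
}

#' Kinetic-proofreading ablation analysis
#'
#' Recomputes MI and channel capacity for the four KP variants (present in
#' both receptor systems, removed from activating NKG2D signaling, removed
#' from inhibitory KIR2DL1 signaling, removed from both) under the spec's
#' geometries and HLA-C levels.
#'
#' @param spec an \code{nk_experiment_spec}; its \code{kp_variant} is
#'   ignored (all four variants run).
#' @param variants subset of the four variant names.
#' @return list of class \code{nk_kp_ablation}: \code{table} with variant,
#'   geometry, hlac, mi, cc; plus per-variant analyses.
#' @export
run_kp_ablation <- function(spec,
                            variants = c("both", "no-activating",
                                         "no-inhibitory", "neither")) {
  variants <- match.arg(variants, several.ok = TRUE)
  analyses <- list(); rows <- list()
  for (v in variants) {
    fl <- kp_flags(v)
    net <- build_network(fl[1], fl[2])
    ana <- run_info_analysis(spec, network = net)
    tb <- ana$table
    tb$variant <- v
    rows[[v]] <- tb
    analyses[[v]] <- ana
  }
  structure(list(table = do.call(rbind, rows), analyses = analyses,
                 spec = spec),
            class = "nk_kp_ablation")
}
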