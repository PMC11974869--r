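# centre of mass of a cluster given its anchor and shape offsets, as a
# (row, col) chamber on the periodic lattice (rounded)
cluster_com <- function(anchor, shape, n_side) {
  com <- anchor + round(colMeans(shape))
  (com - 1L) %% n_side + 1L
}

#' Build an initial simulation configuration
#'
#' Lays out receptor cluster masks in one of the three resting-state
#' geometries and populates the chambers with molecules:
#' \describe{
#'   \item{disjoint}{NKG2D clusters are nucleated first, then KIR2DL1
#'     clusters under the constraint that clusters of the two types never
#'     overlap (same-type overlap is always forbidden).}
#'   \item{overlapping}{each NKG2D cluster receives a KIR2DL1 cluster whose
#'     (rounded) centre of mass coincides with its own; surplus KIR2DL1
#'     clusters are placed at random without touching NKG2D clusters.}
#'   \item{homogeneous}{no clusters; both masks are all-zero and receptors
#'     are placed anywhere.}
#' }
#' Receptors are placed uniformly at random over the chambers of their own
#' mask (or the whole box when homogeneous); ligands and the SFK/Vav1/SHP1
#' pools are uniform over the whole box. Clusters that acquire no receptor
#' are removed from the mask, and the removed fraction is recorded.
#'
#' @param mode \code{"disjoint"}, \code{"overlapping"} or
#'   \code{"homogeneous"}.
#' @param counts an \code{nk_counts} vector (see [cell_counts()]).
#' @param network the \code{nk_network} the configuration is for.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param n_nkg2d_clusters,n_kir_clusters cluster numbers nucleated per box
#'   (calibration constants; defaults 120 and 350).
#' @param mean_size mean cluster size in chambers (default 8).
#' @param maps optional list with elements \code{nkg2d} and \code{kir}
#'   (\code{nk_binary_map}s with cluster attributes) to use instead of
#'   freshly generated maps (disjoint mode only).
#' @return An \code{nk_config}: list with \code{counts} (chambers x species
#'   integer matrix), \code{mask_nkg2d}, \code{mask_kir} (0/1 integer
#'   vectors over chambers), \code{mode}, \code{seed},
#'   \code{pruned} (fraction of clusters removed per type), \code{coms}
#'   (cluster centres of mass), and \code{geom}.
#' @export
make_config <- function(mode = c("disjoint", "overlapping", "homogeneous"),
                        counts = cell_counts(network = network),
                        network = build_network(), seed = NULL,
                        n_nkg2d_clusters = 120, n_kir_clusters = 350,
                        mean_size = 8, maps = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  geom <- network$geom
  n_side <- geom$n_side
  n_ch <- geom$n_chambers
  sp <- network$species$name
  counts <- counts[sp]  # enforce species order
  if (anyNA(counts)) stop("counts must cover every network species")

  clusters_a <- list(); clusters_k <- list()
  coms_a <- list(); coms_k <- list()

  if (mode == "homogeneous") {
    mask_a <- integer(n_ch); mask_k <- integer(n_ch)
  } else if (!is.null(maps)) {
    if (mode != "disjoint")
      stop("user-supplied maps are supported for disjoint mode only")
    clusters_a <- attr(maps$nkg2d, "clusters")
    clusters_k <- attr(maps$kir, "clusters")
    if (is.null(clusters_a) || is.null(clusters_k))
      stop("supplied maps must carry cluster attributes")
    mask_a <- as.integer(maps$nkg2d != 0L)
    mask_k <- as.integer(maps$kir != 0L)
    if (any(mask_a & mask_k)) stop("supplied maps overlap; not disjoint")
  } else {
    sizes_a <- sort(draw_cluster_sizes(n_nkg2d_clusters, mean_size),
                    decreasing = TRUE)  # large shapes first: packable
    shapes_a <- lapply(sizes_a, grow_cluster_template)
    pa <- place_shapes(shapes_a, n_side, rep(FALSE, n_ch))
    clusters_a <- pa$clusters
    coms_a <- mapply(cluster_com, pa$anchors, shapes_a,
                     MoreArgs = list(n_side = n_side), SIMPLIFY = FALSE)

    if (mode == "disjoint") {
      sizes_k <- sort(draw_cluster_sizes(n_kir_clusters, mean_size),
                      decreasing = TRUE)
      shapes_k <- lapply(sizes_k, grow_cluster_template)
      pk <- place_shapes(shapes_k, n_side, pa$occupied)
      clusters_k <- pk$clusters
      coms_k <- mapply(cluster_com, pk$anchors, shapes_k,
                       MoreArgs = list(n_side = n_side), SIMPLIFY = FALSE)
    } else {  # overlapping
      if (n_kir_clusters < n_nkg2d_clusters)
        stop("overlapping mode needs at least as many KIR2DL1 clusters ",
             "as NKG2D clusters")
      # Full overlap: each NKG2D cluster is covered by a KIR2DL1 cluster of
      # identical footprint, so the centres of mass coincide exactly and
      # every NKG2D chamber lies inside a KIR2DL1 cluster.
      occ_k <- rep(FALSE, n_ch)
      for (i in seq_len(n_nkg2d_clusters)) {
        clusters_k[[i]] <- clusters_a[[i]]
        coms_k[[i]] <- coms_a[[i]]
        occ_k[clusters_a[[i]]] <- TRUE
      }
      n_extra <- n_kir_clusters - n_nkg2d_clusters
      if (n_extra > 0) {
        sizes_k <- sort(draw_cluster_sizes(n_extra, mean_size),
                        decreasing = TRUE)
        shapes_k <- lapply(sizes_k, grow_cluster_template)
        # surplus clusters avoid both existing KIR clusters and NKG2D ones
        pk <- place_shapes(shapes_k, n_side, occ_k | pa$occupied)
        clusters_k <- c(clusters_k, pk$clusters)
        coms_k <- c(coms_k, mapply(cluster_com, pk$anchors, shapes_k,
                                   MoreArgs = list(n_side = n_side),
                                   SIMPLIFY = FALSE))
      }
    }
    mask_a <- integer(n_ch); mask_a[unlist(clusters_a)] <- 1L
    mask_k <- integer(n_ch); mask_k[unlist(clusters_k)] <- 1L
  }

  cm <- matrix(0L, nrow = n_ch, ncol = length(sp),
               dimnames = list(NULL, sp))
  place_uniform <- function(n, chambers) {
    if (n == 0) return(integer(n_ch))
    tabulate(sample(chambers, n, replace = TRUE), nbins = n_ch)
  }
  cham_a <- if (mode == "homogeneous") seq_len(n_ch) else which(mask_a == 1L)
  cham_k <- if (mode == "homogeneous") seq_len(n_ch) else which(mask_k == 1L)
  if (counts["NKG2D"] > 0 && length(cham_a) == 0)
    stop("no NKG2D cluster chambers available for receptor placement")
  if (counts["KIR2DL1"] > 0 && length(cham_k) == 0)
    stop("no KIR2DL1 cluster chambers available for receptor placement")
  cm[, "NKG2D"] <- place_uniform(counts["NKG2D"], cham_a)
  cm[, "KIR2DL1"] <- place_uniform(counts["KIR2DL1"], cham_k)
  for (s in c("NKG2DL", "HLAC", "SFK", "Vav1", "SHP1"))
    cm[, s] <- place_uniform(counts[s], seq_len(n_ch))

  # prune clusters devoid of receptors
  prune <- function(clusters, mask, occupancy) {
    empty <- vapply(clusters, function(idx) sum(occupancy[idx]) == 0L,
                    logical(1))
    for (idx in clusters[empty]) mask[idx] <- 0L
    list(mask = mask, clusters = clusters[!empty],
         frac = if (length(clusters)) mean(empty) else NA_real_,
         keep = !empty)
  }
  pruned <- c(nkg2d = NA_real_, kir = NA_real_)
  if (mode != "homogeneous") {
    pr_a <- prune(clusters_a, mask_a, cm[, "NKG2D"])
    mask_a <- pr_a$mask; clusters_a <- pr_a$clusters
    coms_a <- coms_a[pr_a$keep]
    pruned["nkg2d"] <- pr_a$frac
    pr_k <- prune(clusters_k, mask_k, cm[, "KIR2DL1"])
    mask_k <- pr_k$mask; clusters_k <- pr_k$clusters
    coms_k <- coms_k[pr_k$keep]
    pruned["kir"] <- pr_k$frac
  }

  structure(list(counts = cm, mask_nkg2d = mask_a, mask_kir = mask_k,
                 mode = mode, seed = seed, pruned = pruned,
                 clusters = list(nkg2d = clusters_a, kir = clusters_k),
                 coms = list(nkg2d = coms_a, kir = coms_k),
                 geom = geom),
            class = "nk_config")
}

#' @export
print.nk_config <- function(x, ...) {
  cat(sprintf(
    "<nk_config> mode %s: %d NKG2D in %d clusters, %d KIR2DL1 in %d clusters\n",
    x$mode, sum(x$counts[, "NKG2D"]), length(x$clusters$nkg2d),
    sum(x$counts[, "KIR2DL1"]), length(x$clusters$kir)))
  if (!all(is.na(x$pruned)))
    cat(sprintf("  empty clusters removed: NKG2D %.1f%%, KIR2DL1 %.1f%%\n",
                100 * x$pruned["nkg2d"], 100 * x$pruned["kir"]))
  invisible(x)
}

#' Fraction of NKG2D molecules co-localized with KIR2DL1
#'
#' Co-localization is operationalized as same-chamber (40 nm) occupancy:
#' the fraction of NKG2D molecules residing in a chamber that contains at
#' least one KIR2DL1 molecule.
#'
#' @param config an \code{nk_config}.
#' @return fraction in [0, 1].
#' @examples
#' \donttest{
#' net <- build_network()
#' cfg <- make_config("homogeneous", cell_counts(network = net),
#'                    network = net, seed = 1)
#' colocalization_fraction(cfg)  # about 0.75
#' }
#' @export
colocalization_fraction <- function(config) {
  nk <- config$counts[, "NKG2D"]
  kir <- config$counts[, "KIR2DL1"]
  total <- sum(nk)
  if (total == 0) stop("configuration contains no NKG2D molecules")
  sum(nk[kir > 0]) / total
}
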