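#' @useDynLib nkrsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Grow a single connected cluster template of `size` chambers by Eden-type
# growth on the square lattice (4-connected by construction). Offsets are
# relative to the nucleation chamber.
grow_cluster_template <- function(size) {
  stopifnot(size >= 1)
  occ <- matrix(c(0L, 0L), ncol = 2)
  keys <- "0,0"
  dirs <- matrix(c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L), ncol = 2, byrow = TRUE)
  while (nrow(occ) < size) {
    i <- sample.int(nrow(occ), 1L)
    d <- dirs[sample.int(4L, 1L), ]
    cand <- occ[i, ] + d
    key <- paste0(cand[1], ",", cand[2])
    if (!(key %in% keys)) {
      occ <- rbind(occ, cand)
      keys <- c(keys, key)
    }
  }
  unname(occ)
}

# Draw cluster sizes with mean `mean_size` (geometric on 1, 2, ... so only
# the ensemble mean is fixed, matching what is known about the source maps).
draw_cluster_sizes <- function(n, mean_size = 8) {
  stopifnot(mean_size >= 1)
  if (mean_size == 1) return(rep(1L, n))
  stats::rgeom(n, prob = 1 / mean_size) + 1L
}

# Wrap (row, col) offsets around the periodic lattice; returns linear indices.
wrap_chambers <- function(anchor, offsets, n_side) {
  r <- (anchor[1] - 1L + offsets[, 1]) %% n_side
  c <- (anchor[2] - 1L + offsets[, 2]) %% n_side
  r + c * n_side + 1L
}

# Sequentially place cluster shapes uniformly at random with periodic wrap,
# rejecting positions that overlap `occupied` (logical vector over chambers).
# Returns list(clusters = chamber-index vectors, anchors, occupied = updated).
place_shapes <- function(shapes, n_side, occupied, max_attempts = 5000L,
                         fixed_anchors = NULL) {
  clusters <- vector("list", length(shapes))
  anchors <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      anchor <- if (!is.null(fixed_anchors)) fixed_anchors[[i]]
                else c(sample.int(n_side, 1L), sample.int(n_side, 1L))
      idx <- wrap_chambers(anchor, shapes[[i]], n_side)
      if (!any(occupied[idx])) {
        occupied[idx] <- TRUE
        clusters[[i]] <- idx
        anchors[[i]] <- anchor
        placed <- TRUE
        break
      }
      if (!is.null(fixed_anchors)) break  # fixed positions get one shot
    }
    if (!placed)
      stop(sprintf(
        "cluster packing infeasible after %d attempts (fill fraction %.2f)",
        max_attempts, mean(occupied)))
  }
  list(clusters = clusters, anchors = anchors, occupied = occupied)
}

#' Generate a synthetic binary cluster map
#'
#' Emulates a binarized superresolution image of one receptor type:
#' connected submicron clusters (mean size 8 chambers of 40 nm) placed
#' uniformly at random on the periodic lattice with same-type overlap
#' forbidden.
#'
#' @param n_clusters number of clusters to place.
#' @param receptor_type \code{"NKG2D"} or \code{"KIR2DL1"} (label only).
#' @param geom an \code{nk_geometry}.
#' @param seed integer seed making the map reproducible; \code{NULL} uses
#'   the current RNG state.
#' @param mean_size ensemble mean cluster size in chambers (default 8).
#' @param forbidden optional logical vector over chambers that clusters must
#'   avoid (used to keep different receptor types disjoint).
#' @param shapes optional list of offset matrices overriding the grown
#'   templates.
#' @return An \code{nk_binary_map}: 0/1 integer matrix (\code{n_side} x
#'   \code{n_side}) with attributes \code{receptor_type}, \code{provenance}
#'   (\code{"synthetic"}), \code{seed} and \code{clusters} (list of
#'   chamber-index vectors).
#' @examples
#' m <- generate_cluster_map(20, "NKG2D", seed = 1)
#' sum(m) / length(m)  # occupied fraction, about 20*8/8281
#' @export
generate_cluster_map <- function(n_clusters, receptor_type = "NKG2D",
                                 geom = geometry_params(), seed = NULL,
                                 mean_size = 8, forbidden = NULL,
                                 shapes = NULL) {
  stopifnot(n_clusters >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_side <- geom$n_side
  occupied <- if (is.null(forbidden)) rep(FALSE, geom$n_chambers)
              else as.logical(forbidden)
  stopifnot(length(occupied) == geom$n_chambers)
  if (is.null(shapes)) {
    sizes <- draw_cluster_sizes(n_clusters, mean_size)
    if (sum(sizes) >= sum(!occupied))
      stop("total cluster area exceeds available box area")
    shapes <- lapply(sizes, grow_cluster_template)
  }
  pl <- place_shapes(shapes, n_side, occupied)
  grid <- matrix(0L, n_side, n_side)
  for (idx in pl$clusters) grid[idx] <- 1L
  structure(grid, class = "nk_binary_map",
            receptor_type = receptor_type, provenance = "synthetic",
            seed = seed, clusters = pl$clusters)
}

#' Binarize an intensity image into an occupancy map
#'
#' Pixel intensities at the chamber scale are thresholded: occupancy is 1
#' where intensity >= \code{threshold}, else 0.
#'
#' @param intensity numeric matrix (or list of equal-length numeric rows) of
#'   non-negative intensities on the 40 nm pixel grid.
#' @param threshold intensity cut (default 100).
#' @param receptor_type label for the resulting map.
#' @return An \code{nk_binary_map} with provenance \code{"image"}.
#' @examples
#' binarize_image(rbind(c(100, 99), c(250, 0)))
#' @export
binarize_image <- function(intensity, threshold = 100,
                           receptor_type = "NKG2D") {
  if (is.list(intensity)) {
    lens <- lengths(intensity)
    if (length(unique(lens)) != 1L)
      stop("intensity grid is not rectangular")
    intensity <- do.call(rbind, intensity)
  }
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  grid <- matrix(as.integer(intensity >= threshold), nrow(intensity))
  structure(grid, class = "nk_binary_map",
            receptor_type = receptor_type, provenance = "image",
            seed = NULL, clusters = NULL)
}

#' @export
print.nk_binary_map <- function(x, ...) {
  cat(sprintf("<nk_binary_map> %d x %d, %s, %s, occupied fraction %.3f\n",
              nrow(x), ncol(x), attr(x, "receptor_type"),
              attr(x, "provenance"), mean(x)))
  invisible(x)
}

# 4-connected component labelling of a binary matrix (optionally periodic).
# Returns an integer matrix of labels (0 = background).
label_components <- function(grid, periodic = FALSE) {
  n_r <- nrow(grid); n_c <- ncol(grid)
  labels <- matrix(0L, n_r, n_c)
  cur <- 0L
  for (start in which(grid == 1L)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (i - 1L) %% n_r + 1L
      c <- (i - 1L) %/% n_r + 1L
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (periodic) {
          rr <- (rr - 1L) %% n_r + 1L
          cc <- (cc - 1L) %% n_c + 1L
        } else if (rr < 1L || rr > n_r || cc < 1L || cc > n_c) next
        j <- rr + (cc - 1L) * n_r
        if (grid[j] == 1L && labels[j] == 0L) {
          labels[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}
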