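#' Variance-scaled two-point correlation of a binary map
#'
#' For occupancy variables \eqn{S(x_i, y_i)} with mean \eqn{\mu} and
#' variance \eqn{\sigma^2}, computes
#' \deqn{C(r) = \langle (S(x_i) - \mu)(S(x_i + r) - \mu) \rangle}
#' averaged over all site pairs separated by exact lattice distance
#' \eqn{r = \sqrt{r_x^2 + r_y^2}}, scaled by \eqn{\sigma^2}. The value at
#' r = 0 is 1 by construction.
#'
#' @param map an \code{nk_binary_map} (or any 0/1 matrix).
#' @param r_max largest distance in chamber units (default 25, i.e. 1
#'   micrometre at 40 nm chambers).
#' @param periodic wrap pairs around the lattice edges? Defaults to TRUE
#'   for synthetic maps and FALSE for image-derived maps, where pairs
#'   extending beyond the image are omitted.
#' @return An \code{nk_corr_curve}: data.frame with \code{r},
#'   \code{value} (\eqn{C(r)/\sigma^2}) and \code{n_pairs}, plus
#'   attributes \code{mu}, \code{sigma2}, \code{n_total}.
#' @export
two_point_correlation <- function(map, r_max = 25, periodic = NULL) {
  grid <- unclass(map)
  if (!is.matrix(grid)) stop("map must be a matrix")
  if (is.null(periodic))
    periodic <- !identical(attr(map, "provenance"), "image")
  n_r <- nrow(grid); n_c <- ncol(grid)
  mu <- mean(grid)
  dev <- grid - mu
  sigma2 <- mean(dev^2)
  if (sigma2 == 0)
    stop("map variance is zero; correlation undefined")

  offs <- expand.grid(dx = -r_max:r_max, dy = -r_max:r_max)
  offs$r2 <- offs$dx^2 + offs$dy^2
  offs <- offs[offs$r2 > 0 & offs$r2 <= r_max^2, ]

  sums <- c(`0` = sum(dev^2))
  counts <- c(`0` = length(dev))
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    if (periodic) {
      shifted <- dev[(seq_len(n_r) - 1 + dx) %% n_r + 1,
                     (seq_len(n_c) - 1 + dy) %% n_c + 1, drop = FALSE]
      s <- sum(dev * shifted)
      n <- length(dev)
    } else {
      rs <- max(1, 1 + dx):min(n_r, n_r + dx)
      cs <- max(1, 1 + dy):min(n_c, n_c + dy)
      if (length(rs) < 1 || length(cs) < 1) next
      s <- sum(dev[rs, cs, drop = FALSE] *
               dev[rs - dx, cs - dy, drop = FALSE])
      n <- length(rs) * length(cs)
    }
    key <- as.character(offs$r2[i])
    sums[key] <- (if (key %in% names(sums)) sums[key] else 0) + s
    counts[key] <- (if (key %in% names(counts)) counts[key] else 0) + n
  }
  r2 <- as.numeric(names(sums))
  ord <- order(r2)
  out <- data.frame(r = sqrt(r2[ord]),
                    value = (sums[ord] / counts[ord]) / sigma2,
                    n_pairs = counts[ord], row.names = NULL)
  structure(out, class = c("nk_corr_curve", "data.frame"),
            mu = mu, sigma2 = sigma2, n_total = length(grid))
}

#' Randomize the cluster positions of a binary map
#'
#' Decomposes the map into 4-connected clusters and re-places the same
#' multiset of cluster shapes at uniformly random positions, forbidding
#' same-type overlap. The occupied-site count and the cluster-size
#' histogram are preserved exactly.
#'
#' @param map an \code{nk_binary_map}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param max_attempts placement attempts per cluster before giving up.
#' @return an \code{nk_binary_map} of equal size with provenance
#'   \code{"synthetic"}.
#' @export
randomize_clusters <- function(map, seed = NULL, max_attempts = 5000L) {
  if (!is.null(seed)) set.seed(seed)
  grid <- unclass(map)
  periodic <- !identical(attr(map, "provenance"), "image")
  if (nrow(grid) != ncol(grid))
    stop("cluster randomization requires a square map")
  labels <- label_components(grid, periodic = periodic)
  n_cl <- max(labels)
  if (n_cl == 0) stop("map contains no clusters")
  shapes <- vector("list", n_cl)
  for (k in seq_len(n_cl)) {
    idx <- which(labels == k)
    r <- (idx - 1L) %% nrow(grid)
    c <- (idx - 1L) %/% nrow(grid)
    # unwrap periodic clusters relative to their first cell so the shape is
    # contiguous in offset space
    if (periodic) {
      n <- nrow(grid)
      r <- (r - r[1] + n %/% 2) %% n - n %/% 2
      c <- (c - c[1] + n %/% 2) %% n - n %/% 2
      shapes[[k]] <- cbind(r, c)
    } else {
      shapes[[k]] <- cbind(r - r[1], c - c[1])
    }
  }
  pl <- place_shapes(shapes[order(-vapply(shapes, nrow, 1L))],
                     nrow(grid), rep(FALSE, length(grid)),
                     max_attempts = max_attempts)
  out <- matrix(0L, nrow(grid), ncol(grid))
  for (idx in pl$clusters) out[idx] <- 1L
  structure(out, class = "nk_binary_map",
            receptor_type = attr(map, "receptor_type"),
            provenance = "synthetic", seed = seed, clusters = pl$clusters)
}

#' Overlap report between two correlation curves
#'
#' Quantifies the agreement of two variance-scaled correlation curves on a
#' common distance grid: the fraction of distances r > 0 at which the
#' curves lie within each other's confidence band.
#'
#' @param curve_a,curve_b \code{nk_corr_curve}s on the same r grid.
#' @param band half-width of the confidence band, recycled along r.
#' @return list with \code{overlap} (fraction in [0, 1]) and \code{n_r}.
#' @export
curve_overlap <- function(curve_a, curve_b, band) {
  if (length(curve_a$r) != length(curve_b$r) ||
      any(abs(curve_a$r - curve_b$r) > 1e-9))
    stop("correlation curves are on different r grids")
  keep <- curve_a$r > 0
  band <- rep_len(band, length(curve_a$r))[keep]
  within <- abs(curve_a$value[keep] - curve_b$value[keep]) <= band
  list(overlap = mean(within), n_r = sum(keep))
}
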