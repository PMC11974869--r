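#' Build a discrete dose-response channel from replicate ensembles
#'
#' The input alphabet is the set of ligand doses; the output alphabet is
#' binned total-pVav1 copy number. Conditional rows P(o|s) are empirical
#' histograms of the replicate responses (default bin width 1 molecule), or
#' Gamma-fit smoothed histograms.
#'
#' @param responses named list (one element per dose) of numeric response
#'   samples, e.g. from [responses_at()].
#' @param binwidth output bin width in molecules (default 1).
#' @param smooth \code{"none"} for raw histograms or \code{"gamma"} to
#'   smooth each row with its maximum-likelihood Gamma fit.
#' @return An \code{nk_channel}: list with \code{P} (inputs x outputs
#'   conditional matrix, rows summing to 1), \code{doses}, \code{breaks}.
#' @export
build_channel <- function(responses, binwidth = 1,
                          smooth = c("none", "gamma")) {
  smooth <- match.arg(smooth)
  if (length(responses) < 2)
    stop("at least two doses are required to build a channel")
  if (any(vapply(responses, length, 1L) == 0))
    stop("every dose needs at least one response sample")
  if (any(vapply(responses, length, 1L) < 20))
    warning("fewer than 20 replicates for some dose; ",
            "plug-in MI will be strongly biased")
  hi <- max(unlist(responses))
  breaks <- seq(-binwidth / 2, hi + binwidth, by = binwidth)
  P <- t(vapply(responses, function(x) {
    if (smooth == "none") {
      h <- tabulate(findInterval(x, breaks), nbins = length(breaks) - 1)
      h / sum(h)
    } else {
      fit <- fit_gamma(x)
      p <- diff(stats::pgamma(pmax(breaks - fit$offset, 0),
                              shape = fit$shape, scale = fit$scale))
      p / sum(p)
    }
  }, numeric(length(breaks) - 1)))
  structure(list(P = P, doses = names(responses), breaks = breaks),
            class = "nk_channel")
}

#' Mutual information of a dose-response channel
#'
#' \deqn{MI(o;s) = \sum_s \sum_o P(o,s) \log_2 \frac{P(o,s)}{R(o) Q(s)}}
#' with joint P(o,s) = P(o|s) Q(s) and output marginal R(o). The default
#' input distribution is uniform over the doses. The identity
#' MI = H(s) - H(s|o) holds to numerical precision.
#'
#' @param channel an \code{nk_channel} (or a conditional matrix with one
#'   row per input).
#' @param Q input distribution over doses (default uniform).
#' @return mutual information in bits.
#' @export
mutual_information <- function(channel, Q = NULL) {
  P <- if (inherits(channel, "nk_channel")) channel$P else as.matrix(channel)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("conditional matrix rows must be non-negative and sum to 1")
  ns <- nrow(P)
  if (is.null(Q)) Q <- rep(1 / ns, ns)
  if (length(Q) != ns || any(Q < 0) || abs(sum(Q) - 1) > 1e-8)
    stop("Q must be a distribution over the ", ns, " inputs")
  R <- colSums(Q * P)
  terms <- Q * P * log2(sweep(P, 2, R, "/"))
  sum(terms[P > 0 & Q > 0])
}

#' Blahut--Arimoto channel capacity
#'
#' Alternating maximization of mutual information over the input
#' distribution Q(s) for a fixed conditional P(o|s). Iterates until the
#' standard capacity gap bound (max over inputs of the per-input divergence
#' minus the current lower bound) falls below \code{tol}.
#'
#' @param channel an \code{nk_channel} or conditional matrix.
#' @param tol capacity gap tolerance in bits.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last gap.
#' @return list of class \code{nk_info}: \code{cc} (bits), \code{Q_star},
#'   \code{iterations}, \code{gap}, and \code{trace} (lower bound per
#'   iteration, non-decreasing).
#' @examples
#' # binary symmetric channel, crossover 0.1: capacity 1 - H2(0.1)
#' P <- rbind(c(0.9, 0.1), c(0.1, 0.9))
#' blahut_arimoto(P)$cc
#' @export
blahut_arimoto <- function(channel, tol = 1e-9, max_iter = 10000L) {
  P <- if (inherits(channel, "nk_channel")) channel$P else as.matrix(channel)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("conditional matrix rows must be non-negative and sum to 1")
  ns <- nrow(P)
  Q <- rep(1 / ns, ns)
  trace <- numeric(0)
  gap <- Inf
  for (it in seq_len(max_iter)) {
    R <- colSums(Q * P)
    # per-input divergence D(P(.|s) || R), bits
    lg <- log2(sweep(P, 2, R, "/"))
    lg[P == 0] <- 0
    D <- rowSums(P * lg)
    lower <- sum(Q * D)
    upper <- max(D)
    trace <- c(trace, lower)
    gap <- upper - lower
    if (gap < tol)
      return(structure(list(cc = lower, Q_star = Q, iterations = it,
                            gap = gap, trace = trace),
                       class = "nk_info"))
    Q <- Q * 2^D
    Q <- Q / sum(Q)
  }
  stop("Blahut-Arimoto did not converge in ", max_iter,
       " iterations; last gap = ", signif(gap, 4), " bits")
}

#' @export
print.nk_info <- function(x, ...) {
  cat(sprintf("<nk_info> CC = %.4f bits (%d iterations, gap %.2g)\n",
              x$cc, x$iterations, x$gap))
  invisible(x)
}

#' Maximum-likelihood Gamma fit of a response distribution
#'
#' Copy-number samples are fitted with a Gamma(shape, scale) distribution.
#' Because the Gamma support excludes zero, samples containing zeros are
#' shifted by +0.5 before fitting; the offset is recorded in the fit.
#'
#' @param samples numeric vector (>= 10 values, positive variance).
#' @return list of class \code{nk_gamma_fit}: \code{shape}, \code{scale},
#'   \code{offset}, \code{loglik}.
#' @export
fit_gamma <- function(samples) {
  if (length(samples) < 10)
    stop("at least 10 samples are required for a Gamma fit")
  if (stats::var(samples) == 0)
    stop("degenerate samples: zero variance")
  if (any(samples < 0)) stop("samples must be non-negative")
  offset <- if (any(samples == 0)) 0.5 else 0
  x <- samples + offset
  fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  structure(list(shape = unname(fit$estimate["shape"]),
                 scale = 1 / unname(fit$estimate["rate"]),
                 offset = offset, loglik = fit$loglik),
            class = "nk_gamma_fit")
}

#' Kullback--Leibler divergence between two Gamma fits
#'
#' Closed form for KL(p || q) between Gamma(shape k, scale theta)
#' densities:
#' \deqn{(k_p - k_q)\psi(k_p) - \ln\Gamma(k_p) + \ln\Gamma(k_q)
#'   + k_q \ln(\theta_q/\theta_p) + k_p(\theta_p - \theta_q)/\theta_q}
#' Non-negative; zero iff the parameters coincide. Reported in bits by
#' default (the divergence of the source analysis is compared across
#' conditions, so the base is a convention; both are available).
#'
#' @param fit_p,fit_q \code{nk_gamma_fit}s (or lists with shape/scale).
#' @param base \code{"bits"} or \code{"nats"}.
#' @return KL divergence (scalar).
#' @export
kl_gamma <- function(fit_p, fit_q, base = c("bits", "nats")) {
  base <- match.arg(base)
  kp <- fit_p$shape; tp <- fit_p$scale
  kq <- fit_q$shape; tq <- fit_q$scale
  if (any(c(kp, tp, kq, tq) <= 0) || anyNA(c(kp, tp, kq, tq)))
    stop("invalid Gamma parameters")
  nats <- (kp - kq) * digamma(kp) - lgamma(kp) + lgamma(kq) +
    kq * log(tq / tp) + kp * (tp - tq) / tq
  if (base == "bits") nats / log(2) else nats
}

#' Bootstrap standard error of plug-in mutual information
#'
#' Resamples replicates within each dose and recomputes the plug-in MI at
#' uniform input distribution.
#'
#' @param responses named list over doses of response samples.
#' @param n_boot bootstrap resamples.
#' @param binwidth histogram bin width.
#' @return list with \code{mi} (point estimate) and \code{se}.
#' @export
mi_bootstrap <- function(responses, n_boot = 200, binwidth = 1) {
  mi_of <- function(rs) mutual_information(build_channel(rs, binwidth))
  point <- suppressWarnings(mi_of(responses))
  boots <- vapply(seq_len(n_boot), function(i) {
    rs <- lapply(responses, function(x) sample(x, replace = TRUE))
    suppressWarnings(mi_of(rs))
  }, numeric(1))
  list(mi = point, se = stats::sd(boots))
}
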