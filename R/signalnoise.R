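#' Phylogenetic informativeness profile
#'
#' Per-site informativeness over time for a site evolving at rate lambda:
#' \eqn{\rho(t; \lambda) = 16 \lambda t e^{-4 \lambda t}} (four-state
#' convention). The form depends on rate and depth only through their product,
#' so a site is maximally informative for an internode at depth
#' \eqn{t = 1/(4\lambda)}, and conversely the optimal rate for a fixed depth
#' is \eqn{\lambda = 1/(4t)}. The dataset profile is the sum over sites;
#' a height-standardized profile (peak scaled to 1) is also returned for
#' comparing the temporal dynamics of datasets with different sizes or rates.
#'
#' @param rates non-negative per-site rates (per unit time, e.g. per Ma).
#' @param times increasing time grid starting at 0 (same units).
#' @param per_site also return the sites-by-times matrix.
#' @return list of class \code{pi_profile}: \code{times},
#'   \code{informativeness} (dataset sum), \code{standardized},
#'   \code{peak_time} (\code{NA} for an all-zero profile) and optionally
#'   \code{per_site}.
#' @export
pi_profile <- function(rates, times, per_site = FALSE) {
  if (any(rates < 0)) stop("rates must be non-negative")
  if (is.unsorted(times) || any(times < 0))
    stop("'times' must be a non-decreasing grid starting at or above 0")
  m <- outer(rates, times, function(l, t) 16 * l * t * exp(-4 * l * t))
  prof <- colSums(m)
  pk <- if (all(prof == 0)) NA_real_ else times[which.max(prof)]
  std <- if (all(prof == 0)) prof else prof / max(prof)
  out <- list(times = times, informativeness = prof, standardized = std,
              peak_time = pk)
  if (per_site) out$per_site <- m
  structure(out, class = "pi_profile")
}

#' @export
print.pi_profile <- function(x, ...) {
  cat(sprintf("pi_profile: %d time points; peak at %s\n",
              length(x$times),
              if (is.na(x$peak_time)) "none (flat zero)"
              else format(x$peak_time)))
  invisible(x)
}

#' Quartet geometry of one backbone internode
#'
#' @param t0 internode length (time units, > 0 unless the internode has
#'   collapsed, in which case 0 is accepted).
#' @param subtending lengths of the four subtending branches (time units,
#'   all > 0), in the order tip1, tip2 (one side) then tip3, tip4.
#' @return list of class \code{quartet_geometry}.
#' @export
quartet_geometry <- function(t0, subtending) {
  if (length(subtending) != 4L || any(subtending <= 0))
    stop("need 4 positive subtending branch lengths")
  if (t0 < 0) stop("internode length cannot be negative")
  structure(list(t0 = t0, subtending = as.numeric(subtending)),
            class = "quartet_geometry")
}

# Exact probabilities that one site, evolving at rate lambda on the quartet
# ((1,2),(3,4)) with internode t0, produces a parsimony-informative pattern
# supporting the true split (12|34), or either wrong split (13|24, 14|23),
# under a k-state symmetric model. Summation over the two internal states.
#' @noRd
.quartet_site_probs <- function(lambda, geom, n_states = 4L) {
  k <- n_states
  pii <- function(b) 1 / k + (1 - 1 / k) * exp(-b * k / (k - 1))
  pij <- function(b) 1 / k - (1 / k) * exp(-b * k / (k - 1))
  pmat <- function(b) {
    m <- matrix(pij(b), k, k)
    diag(m) <- pii(b)
    m
  }
  P0 <- pmat(lambda * geom$t0)
  P <- lapply(geom$subtending, function(Tt) pmat(lambda * Tt))
  M12 <- P[[1]] * P[[2]]     # [u, x]: both tips 1,2 end in x from u
  M34 <- P[[3]] * P[[4]]
  pi0 <- 1 / k
  p_true <- 0; p_w13 <- 0; p_w14 <- 0
  for (u in seq_len(k)) for (v in seq_len(k)) {
    w <- pi0 * P0[u, v]
    # true split: 1==2 = x, 3==4 = y, x != y
    p_true <- p_true + w * sum(M12[u, ] * (sum(M34[v, ]) - M34[v, ]))
    # wrong split 13|24: 1==3 = x, 2==4 = y, x != y
    a13 <- P[[1]][u, ] * P[[3]][v, ]
    a24 <- P[[2]][u, ] * P[[4]][v, ]
    p_w13 <- p_w13 + w * sum(a13 * (sum(a24) - a24))
    # wrong split 14|23
    a14 <- P[[1]][u, ] * P[[4]][v, ]
    a23 <- P[[2]][u, ] * P[[3]][v, ]
    p_w14 <- p_w14 + w * sum(a14 * (sum(a23) - a23))
  }
  c(true = p_true, wrong13 = p_w13, wrong14 = p_w14)
}

#' Quartet internode resolution probabilities (signal and noise)
#'
#' Probability that the parsimony-informative site patterns accumulated over
#' a gene's sites favour the true resolution of a backbone internode (QIRP),
#' either incorrect resolution (QIHP, summed over both wrong quartets), or
#' produce a tie / no informative signal (QIPP). Per-site probabilities of
#' supporting each quartet are computed exactly under a k-state symmetric
#' model from the internode length and the four subtending branch lengths;
#' the winner over sites is then evaluated by resampling the multinomial
#' support counts. Any tie for the largest count -- including the no-signal
#' case of zero counts everywhere -- is scored as a polytomy.
#'
#' @param rates per-site substitution rates (per unit time); one value is
#'   recycled over \code{n_sites}.
#' @param geometry a [quartet_geometry()].
#' @param n_states number of character states (4 for DNA).
#' @param n_sites number of sites (defaults to \code{length(rates)}).
#' @param n_draws multinomial resampling draws used to evaluate the winner
#'   probabilities.
#' @return list of class \code{quartet_signal} with components \code{qirp},
#'   \code{qihp}, \code{qipp} (summing to 1) and \code{site_probs} (the mean
#'   per-site support probabilities).
#' @export
quartet_probabilities <- function(rates, geometry, n_states = 4L,
                                  n_sites = length(rates),
                                  n_draws = 100000L) {
  if (any(rates < 0)) stop("rates must be non-negative")
  if (length(rates) == 1L) rates <- rep(rates, n_sites)
  if (length(rates) != n_sites)
    stop("length(rates) must be 1 or n_sites")
  ur <- unique(rates)
  counts <- matrix(0, 4, n_draws)
  mean_probs <- c(0, 0, 0)
  for (r in ur) {
    n_g <- sum(rates == r)
    p3 <- .quartet_site_probs(r, geometry, n_states)
    p3 <- pmin(pmax(p3, 0), 1)
    mean_probs <- mean_probs + n_g * p3 / n_sites
    p4 <- c(p3, max(0, 1 - sum(p3)))
    counts <- counts + stats::rmultinom(n_draws, n_g, p4)
  }
  n_true <- counts[1, ]; n_w1 <- counts[2, ]; n_w2 <- counts[3, ]
  qirp <- mean(n_true > pmax(n_w1, n_w2))
  qihp <- mean(n_w1 > pmax(n_true, n_w2)) + mean(n_w2 > pmax(n_true, n_w1))
  structure(list(qirp = qirp, qihp = qihp, qipp = 1 - qirp - qihp,
                 site_probs = stats::setNames(mean_probs,
                                              c("true", "wrong13", "wrong14"))),
            class = "quartet_signal")
}

#' @export
print.quartet_signal <- function(x, ...) {
  cat(sprintf("quartet_signal: QIRP %.4f  QIHP %.4f  QIPP %.4f\n",
              x$qirp, x$qihp, x$qipp))
  invisible(x)
}

#' Joint probability that a nested clade reflects true signal
#'
#' A clade requiring several backbone internodes to be simultaneously
#' resolved correctly has joint signal probability equal to the product of
#' the per-internode correct-resolution probabilities (internodes treated as
#' independent).
#'
#' @param qirps numeric vector of per-internode QIRP values in [0, 1].
#' @return their product; 1 for an empty vector.
#' @export
joint_signal_probability <- function(qirps) {
  if (any(qirps < 0 | qirps > 1)) stop("QIRP values must lie in [0, 1]")
  prod(qirps)
}

#' Excess of incorrect over correct resolution probability per internode
#'
#' Summarizes a table of per-gene, per-internode quartet signals: for each
#' internode, the mean QIRP and QIHP over genes and the excess ratio
#' mean(QIHP)/mean(QIRP) - 1 (how much more likely an incorrect resolution
#' is than a correct one; infinite when mean QIRP is 0).
#'
#' @param signals data frame with columns \code{internode}, \code{qirp},
#'   \code{qihp} (one row per gene x internode).
#' @return data frame with one row per internode: \code{mean_qirp},
#'   \code{mean_qihp}, \code{excess}, \code{excess_infinite}.
#' @export
qirp_qihp_excess <- function(signals) {
  stopifnot(all(c("internode", "qirp", "qihp") %in% names(signals)))
  sp <- split(signals, signals$internode)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    mr <- mean(sp[[id]]$qirp)
    mh <- mean(sp[[id]]$qihp)
    data.frame(internode = id, mean_qirp = mr, mean_qihp = mh,
               excess = if (mr > 0) mh / mr - 1 else Inf,
               excess_infinite = mr == 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
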