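#' Reversible substitution models
#'
#' Builds a time-reversible rate matrix from exchangeabilities and equilibrium
#' frequencies, scaled so the mean substitution rate at equilibrium is 1
#' (branch lengths are then expected substitutions per site). Supported
#' families: JC, K80/HKY (via \code{kappa}), GTR (six exchangeabilities in the
#' order AC, AG, AT, CG, CT, GT), and the symmetric k-state Mk model for
#' discrete characters. Among-site rate variation uses a discrete gamma with
#' \code{n_cat} equal-probability categories (category means, Yang's method)
#' and an optional proportion of invariant sites; variable-category rates are
#' rescaled so the overall mean rate stays 1.
#'
#' @param type one of \code{"JC"}, \code{"HKY"}, \code{"GTR"}, \code{"Mk"}.
#' @param frequencies equilibrium frequencies (must sum to 1); default uniform.
#' @param exchangeabilities for GTR, the six rates AC, AG, AT, CG, CT, GT.
#' @param kappa transition/transversion rate ratio for HKY.
#' @param gamma_shape gamma shape alpha (> 0) or \code{NULL} for a single rate.
#' @param prop_invariant proportion of invariant sites in [0, 1) or \code{NULL}.
#' @param n_cat number of gamma categories (default 4).
#' @param n_states number of states for Mk (>= 2).
#' @return an object of class \code{subst_model} holding the scaled rate
#'   matrix, its eigen system, the state labels and the rate-category layout.
#' @export
substitution_model <- function(type = c("JC", "HKY", "GTR", "Mk"),
                               frequencies = NULL, exchangeabilities = NULL,
                               kappa = 2, gamma_shape = NULL,
                               prop_invariant = NULL, n_cat = 4L,
                               n_states = 4L) {
  type <- match.arg(type)
  if (type == "Mk") {
    if (n_states < 2L) stop("Mk needs at least 2 states")
    k <- as.integer(n_states)
    states <- as.character(seq_len(k) - 1L)
    frequencies <- rep(1 / k, k)
    R <- matrix(1, k, k)
  } else {
    k <- 4L
    states <- c("A", "C", "G", "T")
    if (is.null(frequencies) || type == "JC") {
      if (type != "JC" && is.null(frequencies)) frequencies <- rep(0.25, 4)
      if (type == "JC") frequencies <- rep(0.25, 4)
    }
    R <- switch(type,
      JC = matrix(1, 4, 4),
      HKY = {
        m <- matrix(1, 4, 4)
        m[1, 3] <- m[3, 1] <- kappa   # A<->G
        m[2, 4] <- m[4, 2] <- kappa   # C<->T
        m
      },
      GTR = {
        if (is.null(exchangeabilities) || length(exchangeabilities) != 6L)
          stop("GTR needs 6 exchangeabilities (AC, AG, AT, CG, CT, GT)")
        e <- exchangeabilities
        m <- matrix(0, 4, 4)
        m[1, 2] <- e[1]; m[1, 3] <- e[2]; m[1, 4] <- e[3]
        m[2, 3] <- e[4]; m[2, 4] <- e[5]; m[3, 4] <- e[6]
        m + t(m)
      })
  }
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != k || any(frequencies <= 0) ||
      abs(sum(frequencies) - 1) > 1e-8)
    stop("frequencies must be ", k, " positive numbers summing to 1")
  if (!is.null(prop_invariant) &&
      (prop_invariant < 0 || prop_invariant >= 1))
    stop("prop_invariant must lie in [0, 1)")
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")

  Q <- R %*% diag(frequencies)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(frequencies * diag(Q))
  Q <- Q / mu
  # symmetric eigen decomposition of the reversible generator
  sp <- sqrt(frequencies)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eg$vectors
  Uinv <- t(eg$vectors) %*% diag(sp)

  pinv <- if (is.null(prop_invariant)) 0 else prop_invariant
  if (is.null(gamma_shape)) {
    cat_rates <- 1
  } else {
    cat_rates <- .discrete_gamma(gamma_shape, n_cat)
  }
  if (pinv > 0) cat_rates <- cat_rates / (1 - pinv)

  structure(list(type = type, states = states, k = k,
                 frequencies = frequencies, Q = Q,
                 eigen = list(values = eg$values, U = U, Uinv = Uinv),
                 gamma_shape = gamma_shape, prop_invariant = pinv,
                 cat_rates = cat_rates, kappa = kappa,
                 exchangeabilities = exchangeabilities),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %s, %d states", x$type, x$k))
  if (!is.null(x$gamma_shape))
    cat(sprintf(", +G(alpha=%.4g, %d cat)", x$gamma_shape,
                length(x$cat_rates)))
  if (x$prop_invariant > 0) cat(sprintf(", +I(%.3g)", x$prop_invariant))
  cat("\n")
  invisible(x)
}

# equal-probability discrete gamma, category means (mean rate exactly 1)
.discrete_gamma <- function(alpha, k) {
  if (k == 1L) return(1)
  b <- c(0, stats::qgamma(seq_len(k - 1) / k, alpha, alpha), Inf)
  k * diff(stats::pgamma(b, alpha + 1, alpha))
}

# transition probability matrix P(t) from the cached eigen system
.pmat <- function(model, t) {
  e <- model$eigen
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  P[P < 0] <- 0
  P
}

# tip partial-likelihood matrix (k x n_patterns) for one taxon's states
.tip_partials <- function(states, model) {
  k <- model$k
  out <- matrix(0, k, length(states))
  if (model$type == "Mk") {
    amb <- states %in% c("-", "?")
    out[, amb] <- 1
    idx <- match(states[!amb], model$states)
    if (anyNA(idx)) stop("state outside the Mk alphabet")
    out[cbind(idx, which(!amb))] <- 1
  } else {
    for (j in seq_along(states)) {
      comp <- .dna_ambiguity[[states[j]]]
      if (is.null(comp)) stop("unknown DNA state code: ", states[j])
      out[match(comp, model$states), j] <- 1
    }
  }
  out
}
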