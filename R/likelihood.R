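#' @keywords internal
#' @noRd
.prepare_lik <- function(alignment, tree, model) {
  labs <- tree$tip.label
  miss <- setdiff(labs, rownames(alignment$matrix))
  if (length(miss))
    stop("taxa missing from the alignment: ", paste(miss, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  tr <- stats::reorder(tree, "postorder")
  m <- alignment$matrix[labs, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "")
  first <- !duplicated(key)
  map <- match(key, key[first])
  w <- tabulate(map, nbins = sum(first))
  pat <- m[, first, drop = FALSE]
  tips <- lapply(seq_len(nrow(pat)),
                 function(i) .tip_partials(pat[i, ], model))
  # product of tip partials over all taxa: zero-rate likelihood per pattern
  prod_tips <- Reduce("*", tips)
  l0 <- colSums(model$frequencies * prod_tips)
  list(tree = tr, tips = tips, map = map, weights = w,
       npat = sum(first), l0 = l0)
}

# per-pattern log-likelihood via Felsenstein pruning with per-node scaling
#' @noRd
.loglik_patterns <- function(prep, model, edge_lengths = NULL) {
  tr <- prep$tree
  if (is.null(edge_lengths)) edge_lengths <- tr$edge.length
  n <- length(tr$tip.label)
  npat <- prep$npat
  k <- model$k
  pinv <- model$prop_invariant
  wcat <- (1 - pinv) / length(model$cat_rates)
  terms <- matrix(-Inf, length(model$cat_rates) + 1L, npat)
  if (pinv > 0) terms[1L, ] <- log(pinv) + log(prep$l0)
  root <- tr$edge[nrow(tr$edge), 1L]
  for (ci in seq_along(model$cat_rates)) {
    r <- model$cat_rates[ci]
    part <- vector("list", n + tr$Nnode)
    part[seq_len(n)] <- prep$tips
    logscale <- numeric(npat)
    done <- logical(n + tr$Nnode)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      P <- .pmat(model, r * edge_lengths[e])
      contrib <- P %*% part[[ch]]
      part[[p]] <- if (is.null(part[[p]])) contrib else part[[p]] * contrib
      done[p] <- TRUE
      # scale once the last edge into p has been processed
      if (e == nrow(tr$edge) || tr$edge[e + 1L, 1L] != p) {
        pp <- part[[p]]
        mx <- pp[1L, ]
        for (r2 in 2:k) mx <- pmax(mx, pp[r2, ])
        mx[mx <= 0] <- .Machine$double.xmin
        part[[p]] <- pp * rep(1 / mx, each = k)
        logscale <- logscale + log(mx)
      }
    }
    lc <- colSums(model$frequencies * part[[root]])
    terms[ci + 1L, ] <- log(wcat) + log(lc) + logscale
  }
  mx <- apply(terms, 2, max)
  mx[!is.finite(mx)] <- 0
  mx + log(colSums(exp(terms - rep(mx, each = nrow(terms)))))
}

#' Per-site log-likelihoods under a fixed tree and model
#'
#' Felsenstein pruning with a gamma-rate mixture and optional invariant
#' class. Gaps and ambiguity codes enter as partial likelihood 1 over their
#' compatible states; per-node rescaling prevents underflow, so data made of
#' observed states never return -Inf.
#'
#' @param alignment a [rad_alignment()] covering the tree's leaves.
#' @param tree a \code{phylo} with branch lengths (expected substitutions per
#'   site).
#' @param model a [substitution_model()].
#' @return numeric vector of per-site log-likelihoods with attributes
#'   \code{"total"} (their sum) and \code{"n_patterns"}.
#' @export
site_log_likelihoods <- function(alignment, tree, model) {
  prep <- .prepare_lik(alignment, tree, model)
  lp <- .loglik_patterns(prep, model)
  out <- lp[prep$map]
  attr(out, "total") <- sum(lp * prep$weights)
  attr(out, "n_patterns") <- prep$npat
  out
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimization of each branch in turn, iterated until
#' the total log-likelihood improves by less than \code{tol} or
#' \code{max_rounds} is reached. The log-likelihood never decreases: a
#' proposed branch length is kept only if it improves the current value.
#'
#' @param alignment a [rad_alignment()].
#' @param tree a \code{phylo}; existing branch lengths are the start point
#'   (branches are created at \code{init} if absent).
#' @param model a [substitution_model()].
#' @param max_rounds maximum full sweeps over the branches.
#' @param tol convergence tolerance on the total log-likelihood.
#' @param bounds numeric lower/upper bounds on a branch length.
#' @param init starting length for trees without branch lengths.
#' @return the tree with optimized \code{edge.length} and attribute
#'   \code{"logL"}.
#' @export
optimize_branch_lengths <- function(alignment, tree, model, max_rounds = 20L,
                                    tol = 1e-6, bounds = c(1e-8, 10),
                                    init = 0.1, brent_tol = 1e-7) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, bounds[1]), bounds[2])
  prep <- .prepare_lik(alignment, tree, model)
  el <- prep$tree$edge.length
  w <- prep$weights
  total <- function(v) sum(.loglik_patterns(prep, model, v) * w)
  cur <- total(el)
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    prev <- cur
    for (i in seq_along(el)) {
      g <- function(x) { v <- el; v[i] <- x; total(v) }
      op <- stats::optimize(g, interval = bounds, maximum = TRUE,
                            tol = brent_tol)
      if (op$objective > cur) {
        el[i] <- op$maximum
        cur <- op$objective
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("branch-length optimization stopped after ", max_rounds,
            " rounds without full convergence; returning best so far")
  # map the optimized lengths back onto the caller's edge ordering
  out <- tree
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_po <- paste(prep$tree$edge[, 1], prep$tree$edge[, 2])
  out$edge.length <- el[match(key_in, key_po)]
  attr(out, "logL") <- cur
  out
}

#' Per-site maximum-likelihood rates on a fixed chronogram
#'
#' For every site, a single rate multiplier scaling all branch durations of
#' the chronogram is estimated by bounded one-dimensional ML. Sites
#' compatible with a single state across all scored taxa need no change and
#' get rate 0. Rates are per site per unit of tree time: doubling all node
#' depths halves every estimate.
#'
#' @param alignment a [rad_alignment()].
#' @param chronogram an ultrametric \code{phylo} whose leaves cover (or are
#'   pruned to) the alignment's taxa.
#' @param model a [substitution_model()]; a single-rate model is the usual
#'   choice since the per-site rate itself is the free parameter.
#' @param r_max upper bound of the rate search (substitutions per site per
#'   unit time).
#' @return numeric vector of per-site rate estimates.
#' @export
per_site_rates <- function(alignment, chronogram, model, r_max = 20) {
  shared <- intersect(chronogram$tip.label, rownames(alignment$matrix))
  if (length(shared) < 2L) stop("fewer than 2 taxa shared with the chronogram")
  if (length(shared) < length(chronogram$tip.label))
    chronogram <- ape::keep.tip(chronogram, shared)
  alignment <- subset_alignment(alignment, taxa = shared)
  prep <- .prepare_lik(alignment, chronogram, model)
  dur <- prep$tree$edge.length
  rates_pat <- numeric(prep$npat)
  for (j in seq_len(prep$npat)) {
    sub <- prep
    sub$tips <- lapply(prep$tips, function(tp) tp[, j, drop = FALSE])
    sub$l0 <- prep$l0[j]
    sub$npat <- 1L
    if (sub$l0 > 0) { rates_pat[j] <- 0; next }   # invariant-compatible
    f <- function(r) .loglik_patterns(sub, model, r * dur)
    # the objective has a narrow peak and a long saturation plateau: bracket
    # on a log grid first, then refine by Brent within the bracket
    grid <- c(0, exp(seq(log(1e-5), log(r_max), length.out = 40)))
    vals <- vapply(grid, f, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    op <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                          tol = 1e-8)
    rates_pat[j] <- if (op$objective >= vals[i]) op$maximum else grid[i]
  }
  rates_pat[prep$map]
}

#' Graft fixed within-clade subtrees onto a clade-level backbone
#'
#' Replaces every clade label of a backbone newick string by the newick of
#' that clade's subtree (or its single terminal). Labels are matched only
#' where delimited by newick punctuation, so clade labels may not be
#' substrings of one another.
#'
#' @param backbone newick string on clade labels (no branch lengths).
#' @param subtrees named character vector or list: clade label to subtree
#'   newick (without trailing semicolon) or terminal name.
#' @return a \code{phylo} at the terminal level, without branch lengths.
#' @export
graft_backbone <- function(backbone, subtrees) {
  s <- backbone
  for (lab in names(subtrees)) {
    rep <- gsub("([\\\\])", "\\\\\\1", as.character(subtrees[[lab]]))
    s2 <- gsub(paste0("(?<=[(,])", lab, "(?=[,):;])"), rep, s, perl = TRUE)
    if (identical(s2, s))
      stop("clade label '", lab, "' not found in the backbone")
    s <- s2
  }
  ape::read.tree(text = s)
}

#' Best tree within a backbone constraint class
#'
#' Grafts the fixed within-clade subtrees onto every backbone topology of a
#' class, optimizes branch lengths on each resulting terminal-level tree, and
#' returns the class maximum. This is the exhaustive desk-scale counterpart
#' of a constrained heuristic search: exact within its search space because
#' every enumerated backbone is scored.
#'
#' @param alignment a [rad_alignment()].
#' @param backbones character vector of backbone newick strings (one class).
#' @param subtrees named list as in [graft_backbone()].
#' @param model a [substitution_model()].
#' @param ... passed to [optimize_branch_lengths()].
#' @return list with \code{tree} (optimized \code{phylo}), \code{logL},
#'   \code{index} (which backbone won) and \code{logLs} (all class members).
#' @export
best_tree_in_class <- function(alignment, backbones, subtrees, model, ...) {
  if (!length(backbones)) stop("empty backbone class")
  logLs <- numeric(length(backbones))
  best <- NULL
  for (i in seq_along(backbones)) {
    tr <- graft_backbone(backbones[i], subtrees)
    fit <- optimize_branch_lengths(alignment, tr, model, ...)
    logLs[i] <- attr(fit, "logL")
    if (is.null(best) || logLs[i] > attr(best, "logL")) best <- fit
  }
  list(tree = best, logL = max(logLs), index = which.max(logLs),
       logLs = logLs)
}

#' Choose a substitution model by BIC
#'
#' Fits a small fixed menu -- JC, HKY, GTR, each with gamma rates and
#' optionally an invariant class -- on a fixed topology, alternating branch
#' length optimization with numeric optimization of the model parameters, and
#' ranks the fits by BIC (parameter count includes the branch lengths).
#'
#' @param alignment a [rad_alignment()].
#' @param tree a \code{phylo} (topology; branch lengths re-estimated).
#' @param with_invariant also try the +I variants.
#' @return list with \code{best} (a fitted [substitution_model()]),
#'   \code{tree} (branch lengths under the best model) and \code{table}
#'   (data frame of model, logL, n_par, BIC).
#' @export
select_model <- function(alignment, tree, with_invariant = TRUE) {
  m <- alignment$matrix[tree$tip.label, , drop = FALSE]
  obs <- table(factor(m[.is_observed(m, alignment$alphabet)],
                      levels = c("A", "C", "G", "T")))
  freq <- as.numeric(obs) / sum(obs)
  freq[freq <= 0] <- 1e-6
  freq <- freq / sum(freq)
  nsit <- ncol(m)
  menu <- expand.grid(type = c("JC", "HKY", "GTR"),
                      inv = if (with_invariant) c(FALSE, TRUE) else FALSE,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(menu))
  for (i in seq_len(nrow(menu))) {
    type <- menu$type[i]; inv <- menu$inv[i]
    build <- function(par) {
      alpha <- exp(par[1])
      pinv <- if (inv) stats::plogis(par[2]) * 0.99 else NULL
      extra <- if (inv) par[-(1:2)] else par[-1]
      switch(type,
        JC = substitution_model("JC", gamma_shape = alpha,
                                prop_invariant = pinv),
        HKY = substitution_model("HKY", frequencies = freq,
                                 kappa = exp(extra[1]), gamma_shape = alpha,
                                 prop_invariant = pinv),
        GTR = substitution_model("GTR", frequencies = freq,
                                 exchangeabilities = c(exp(extra), 1),
                                 gamma_shape = alpha, prop_invariant = pinv))
    }
    npar_model <- switch(type, JC = 1, HKY = 2 + 3, GTR = 6 + 3) +
      if (inv) 1 else 0
    par0 <- c(0, if (inv) -1, switch(type, JC = NULL, HKY = log(2),
                                     GTR = rep(0, 5)))
    fit_tree <- tree
    cur <- NULL
    for (round in 1:2) {
      fit_tree <- optimize_branch_lengths(alignment, fit_tree, build(par0),
                                          max_rounds = 5L)
      obj <- function(par) {
        md <- tryCatch(build(par), error = function(e) NULL)
        if (is.null(md)) return(1e10)
        -attr(site_log_likelihoods(alignment, fit_tree, md), "total")
      }
      op <- stats::optim(par0, obj, method = "Nelder-Mead",
                         control = list(maxit = 200))
      par0 <- op$par
      cur <- -op$value
    }
    npar <- npar_model + nrow(tree$edge)
    fits[[i]] <- list(name = paste0(type, "+G", if (inv) "+I"),
                      model = build(par0), tree = fit_tree, logL = cur,
                      n_par = npar, bic = -2 * cur + npar * log(nsit))
  }
  tab <- data.frame(model = vapply(fits, `[[`, "", "name"),
                    logL = vapply(fits, `[[`, 0, "logL"),
                    n_par = vapply(fits, `[[`, 0, "n_par"),
                    BIC = vapply(fits, `[[`, 0, "bic"))
  best <- fits[[which.min(tab$BIC)]]
  list(best = best$model, tree = best$tree, table = tab)
}
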