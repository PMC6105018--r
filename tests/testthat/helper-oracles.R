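# Independent oracles and small generators used across the suite.
# Everything here is deliberately written by a different route than the
# package code it checks (brute-force enumeration, naive resampling,
# direct simulation).

# random binary tree as a plain phylo, unique labels
random_tree <- function(n, labels = paste0("t", seq_len(n)), rooted = TRUE) {
  stopifnot(length(labels) == n)
  tr <- ape::rtree(n, rooted = rooted)
  tr$tip.label <- sample(labels)
  tr
}

# brute-force split set of a tree: for every internal edge, bipartition by
# dropping the edge; computed via ape::prop.part on an unrooted view
oracle_split_keys <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  pp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(pp, "labels")
  universe <- sort(labs)
  ref <- universe[1]
  keys <- vapply(pp, function(idx) {
    side <- labs[idx]
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    if (ref %in% side) side <- setdiff(universe, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "\x1f")
  }, character(1))
  unique(keys[!is.na(keys)])
}

oracle_rf <- function(t1, t2, normalized = TRUE) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  t1 <- ape::keep.tip(t1, shared); t2 <- ape::keep.tip(t2, shared)
  k1 <- oracle_split_keys(t1); k2 <- oracle_split_keys(t2)
  d <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  if (!normalized) return(d)
  if (length(k1) + length(k2) == 0) 0 else d / (length(k1) + length(k2))
}

# exhaustive-summation log-likelihood: enumerate the states of EVERY node
# (tips included, to handle ambiguity) and sum path probabilities
oracle_loglik <- function(aln, tree, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  k <- model$k
  m <- aln$matrix[tr$tip.label, , drop = FALSE]
  P_edge <- function(rate) lapply(seq_len(nrow(tr$edge)), function(e)
    radsignal:::.pmat(model, rate * tr$edge.length[e]))
  site_lik <- function(j, Ps) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
    tipok <- sapply(seq_len(n), function(i) {
      comp <- if (model$type == "Mk") {
        if (m[i, j] %in% c("-", "?")) model$states else m[i, j]
      } else radsignal:::.dna_ambiguity[[m[i, j]]]
      grid[, i] %in% match(comp, model$states)
    })
    ok <- rowSums(tipok) == n
    pr <- model$frequencies[grid[, root]]
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      pr <- pr * Ps[[e]][cbind(grid[, p], grid[, ch])]
    }
    sum(pr[ok])
  }
  vapply(seq_len(ncol(m)), function(j) {
    parts <- vapply(model$cat_rates, function(r)
      site_lik(j, P_edge(r)), numeric(1))
    li <- (1 - model$prop_invariant) * mean(parts)
    if (model$prop_invariant > 0)
      li <- li + model$prop_invariant * site_lik(j, P_edge(0))
    log(li)
  }, numeric(1))
}

# naive RELL at one scale: per-replicate index resampling, no multinomial
oracle_rell_scale1 <- function(L, replicates, seed) {
  set.seed(seed)
  ntop <- nrow(L); nsit <- ncol(L)
  wins <- numeric(ntop)
  for (b in seq_len(replicates)) {
    idx <- sample.int(nsit, nsit, replace = TRUE)
    tot <- rowSums(L[, idx, drop = FALSE])
    w <- which(tot == max(tot))
    wins[w] <- wins[w] + 1 / length(w)
  }
  wins / replicates
}

# JC simulation of an alignment on a tree whose branch lengths are expected
# substitutions per site (direct per-branch transition draws)
sim_jc_alignment <- function(tree, nsites, k = 4) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  st <- matrix(NA_integer_, n + tr$Nnode, nsites)
  st[root, ] <- sample.int(k, nsites, replace = TRUE)
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    b <- tr$edge.length[e]
    p_same <- 1 / k + (1 - 1 / k) * exp(-b * k / (k - 1))
    same <- stats::runif(nsites) < p_same
    new <- st[p, ]
    if (any(!same)) {
      shift <- sample.int(k - 1, sum(!same), replace = TRUE)
      new[!same] <- 1 + (st[p, !same] - 1 + shift) %% k
    }
    st[ch, ] <- new
  }
  m <- matrix(c("A", "C", "G", "T")[st[seq_len(n), ]], n, nsites,
              dimnames = list(tr$tip.label, NULL))
  rad_alignment(m)
}

# Monte-Carlo quartet resolution frequencies by direct character simulation
# on the quartet ((1,2),(3,4)): internode t0, subtending branches T1..T4,
# rate lambda; counts parsimony-informative winners per replicate gene
oracle_quartet_mc <- function(lambda, t0, subtending, n_sites, n_rep,
                              k = 4, chunk = 4000) {
  draw_child <- function(parent, b) {
    p_same <- 1 / k + (1 - 1 / k) * exp(-b * k / (k - 1))
    nn <- length(parent)
    same <- stats::runif(nn) < p_same
    out <- parent
    ns <- sum(!same)
    if (ns) out[!same] <- 1 + (parent[!same] - 1 +
                               sample.int(k - 1, ns, TRUE)) %% k
    out
  }
  wins <- c(true = 0, wrong = 0, poly = 0)
  done <- 0
  while (done < n_rep) {
    nb <- min(chunk, n_rep - done)
    tot <- nb * n_sites
    u <- sample.int(k, tot, replace = TRUE)
    v <- draw_child(u, lambda * t0)
    x1 <- draw_child(u, lambda * subtending[1])
    x2 <- draw_child(u, lambda * subtending[2])
    x3 <- draw_child(v, lambda * subtending[3])
    x4 <- draw_child(v, lambda * subtending[4])
    s_true <- x1 == x2 & x3 == x4 & x1 != x3
    s_w1 <- x1 == x3 & x2 == x4 & x1 != x2
    s_w2 <- x1 == x4 & x2 == x3 & x1 != x2
    grp <- rep(seq_len(nb), each = n_sites)
    n1 <- tapply(s_true, grp, sum)
    n2 <- tapply(s_w1, grp, sum)
    n3 <- tapply(s_w2, grp, sum)
    t_win <- n1 > pmax(n2, n3)
    w_win <- (n2 > pmax(n1, n3)) | (n3 > pmax(n1, n2))
    wins["true"] <- wins["true"] + sum(t_win)
    wins["wrong"] <- wins["wrong"] + sum(w_win)
    wins["poly"] <- wins["poly"] + sum(!t_win & !w_win)
    done <- done + nb
  }
  wins / n_rep
}

# tiny deterministic DNA alignment builder
aln_from_strings <- function(..., taxa = NULL) {
  s <- c(...)
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- if (is.null(taxa)) paste0("t", seq_along(s)) else taxa
  rad_alignment(m)
}
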