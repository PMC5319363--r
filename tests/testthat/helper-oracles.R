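# Independent oracles and fixture builders used across the test suite.
# These deliberately re-derive quantities through different routes than the
# package implementation (fine-grid RK4 on the raw extinction/flow ODEs,
# exhaustive state enumeration, brute-force pairwise loops, closed-form
# textbook formulas).

# --- birth--death likelihood oracles ---------------------------------------

# Fine-grid RK4 integration of the raw E(t) (no sampled descendants) and
# log Q(t) (exactly-one-reconstructed-lineage) ODEs, assembled into the
# crown-conditioned log-likelihood. Independent of the package's closed-form
# F/R formulation and of deSolve.
oracle_bd_loglik <- function(bt, lam_fun, mu_fun, rho, nstep = 20000L) {
  T1 <- bt[1L]
  ts <- seq(0, T1, length.out = nstep + 1L)
  h <- ts[2L] - ts[1L]
  E <- 1 - rho; logQ <- log(rho)
  Es <- numeric(length(ts)); Qs <- numeric(length(ts))
  Es[1L] <- E; Qs[1L] <- logQ
  fE <- function(t, E) mu_fun(t) - (lam_fun(t) + mu_fun(t)) * E + lam_fun(t) * E^2
  g <- function(t, E) -(lam_fun(t) + mu_fun(t) - 2 * lam_fun(t) * E)
  for (i in seq_along(ts)[-1L]) {
    t0 <- ts[i - 1L]
    k1 <- fE(t0, E); k2 <- fE(t0 + h / 2, E + h / 2 * k1)
    k3 <- fE(t0 + h / 2, E + h / 2 * k2); k4 <- fE(t0 + h, E + h * k3)
    q1 <- g(t0, E); q2 <- g(t0 + h / 2, E + h / 2 * k1)
    q3 <- g(t0 + h / 2, E + h / 2 * k2); q4 <- g(t0 + h, E + h * k3)
    E <- E + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    logQ <- logQ + h / 6 * (q1 + 2 * q2 + 2 * q3 + q4)
    Es[i] <- E; Qs[i] <- logQ
  }
  Ef <- approxfun(ts, Es); Qf <- approxfun(ts, Qs)
  sum(log(lam_fun(bt[-1L]))) + sum(Qf(bt[-1L])) + 2 * Qf(bt[1L]) -
    2 * log(1 - Ef(bt[1L]))
}

# Closed-form crown-conditioned Yule log-likelihood: (n-2) log(lambda) minus
# lambda times the total branch length.
oracle_yule_loglik <- function(tree, lambda) {
  n <- ape::Ntip(tree)
  (n - 2) * log(lambda) - lambda * sum(tree$edge.length)
}

# Closed-form constant-rate birth--death likelihood with sampling, written
# from the textbook p0/p1 formulas (probability of zero / exactly one
# sampled descendant for a lineage of age t).
oracle_crbd_loglik <- function(bt, lambda, mu, rho) {
  r <- lambda - mu
  denom <- function(t) rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t)
  p0 <- function(t) 1 - rho * r / denom(t)
  p1 <- function(t) rho * r^2 * exp(-r * t) / denom(t)^2
  sum(log(lambda) + log(p1(bt[-1L]))) + 2 * log(p1(bt[1L])) -
    2 * log(1 - p0(bt[1L]))
}

# --- discrete-character oracle ---------------------------------------------

# Exhaustive sum over all internal-node state assignments (uniform root
# prior), giving exact marginal ancestral-state probabilities for trees small
# enough to enumerate.
oracle_mk_marginals <- function(tree, tip_state, Q) {
  states <- rownames(Q)
  nn <- tree$Nnode
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e) {
    P <- ape::matexpo(Q * tree$edge.length[e])
    dimnames(P) <- dimnames(Q)
    P
  })
  grid <- expand.grid(rep(list(states), nn), stringsAsFactors = FALSE)
  lik <- apply(grid, 1L, function(g) {
    st <- c(tip_state[tree$tip.label], as.character(g))
    p <- 1 / length(states)
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Pm[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
    p
  })
  out <- sapply(seq_len(nn), function(i)
    sapply(states, function(s) sum(lik[grid[[i]] == s])) / sum(lik))
  t(out)
}

# --- misc brute-force oracles ----------------------------------------------

# Patristic distances by explicit root-to-tip path bookkeeping.
oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  paths <- lapply(seq_len(n), function(tip) {
    nodes <- tip
    cur <- tip
    repeat {
      e <- match(cur, tree$edge[, 2L])
      if (is.na(e)) break
      cur <- tree$edge[e, 1L]
      nodes <- c(nodes, cur)
    }
    nodes
  })
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    anc <- intersect(paths[[i]], paths[[j]])
    mrca <- anc[which.max(depth[anc])]
    D[i, j] <- D[j, i] <- (depth[i] - depth[mrca]) + (depth[j] - depth[mrca])
  }
  D
}

# Gower dissimilarity by an explicit per-pair, per-variable double loop.
oracle_gower <- function(data) {
  n <- nrow(data)
  D <- matrix(0, n, n, dimnames = list(rownames(data), rownames(data)))
  ranges <- lapply(data, function(v) if (is.numeric(v)) diff(range(v)))
  keep <- vapply(data, function(v) !is.numeric(v) || diff(range(v)) > 0, TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0; used <- 0L
    for (k in seq_along(data)) {
      if (!keep[k]) next
      v <- data[[k]]
      acc <- acc + if (is.numeric(v)) abs(v[i] - v[j]) / ranges[[k]]
                   else as.numeric(as.character(v[i]) != as.character(v[j]))
      used <- used + 1L
    }
    D[i, j] <- acc / used
  }
  D
}

# --- fixture builders -------------------------------------------------------

# Paint an entire tree with a single state.
one_state_paint <- function(tree, state = "a") {
  regime_paint(tree, lapply(tree$edge.length, function(l) setNames(l, state)),
               source = "manual")
}

# Paint the clades below the given nodes with `derived`, the rest with
# `background`.
clade_paint <- function(tree, nodes, background = "a", derived = "b") {
  desc <- radiate:::edge_descendants(tree)
  inreg <- unique(unlist(lapply(nodes, function(nd)
    desc[[match(nd, tree$edge[, 2L])]])))
  maps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    l <- tree$edge.length[e]
    setNames(l, if (e %in% inreg) derived else background)
  })
  regime_paint(tree, maps, source = "manual")
}

# Choose up to `k` disjoint clades of intermediate size, oldest first.
pick_disjoint_clades <- function(tree, k = 3L, min_tips = 10L, max_tips = 30L) {
  n <- ape::Ntip(tree)
  ids <- (n + 2L):(n + tree$Nnode)      # internal nodes except the root
  sizes <- vapply(ids, function(nd) length(ape::extract.clade(tree, nd)$tip.label), 0L)
  ages <- tree$node_age[ids]
  desc <- radiate:::edge_descendants(tree)
  chosen <- integer(0L); used <- integer(0L)
  for (nd in ids[order(-ages)]) {
    sz <- sizes[match(nd, ids)]
    if (sz < min_tips || sz > max_tips) next
    tips <- intersect(unique(tree$edge[desc[[match(nd, tree$edge[, 2L])]], 2L]),
                      seq_len(n))
    if (length(intersect(tips, used))) next
    chosen <- c(chosen, nd); used <- c(used, tips)
    if (length(chosen) == k) break
  }
  chosen
}

# Replace tip `tip` of `host` with clade `sub` (crown age < tip stem length),
# keeping the tree ultrametric: a planted-rate-shift fixture.
plant_clade <- function(host, tip, sub) {
  stopifnot(sub$crown_age < host$crown_age)
  e <- match(match(tip, host$tip.label), host$edge[, 2L])
  stem_top <- host$node_age[host$edge[e, 1L]]
  stopifnot(sub$crown_age < stem_top)
  sub_txt <- sub(";$", "", ape::write.tree(sub))
  host_txt <- ape::write.tree(host)
  pat <- paste0("([(,])", tip, ":([0-9.eE+-]+)")
  m <- regmatches(host_txt, regexec(pat, host_txt))[[1L]]
  stem_len <- as.numeric(m[3L])
  new_piece <- paste0("\\1", sub_txt, ":",
                      format(stem_len - sub$crown_age, digits = 15))
  as_dated_tree(ape::read.tree(text = sub(pat, new_piece, host_txt)))
}
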