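# Seeded synthetic-data generators: birth--death trees (constant or
# time-varying rates, optional instantaneous mass-extinction event), Mk niche
# characters with their true histories, regime-dependent OU/BM traits, and a
# complete scenario bundle emulating a two-clade radiation.

#' Simulate a reconstructed birth--death tree
#'
#' Forward-time birth--death simulation with extinct lineages pruned.
#' Constant-rate simulations stopped on a taxon count use the standard
#' conditioned simulator ([ape::rphylo()]); age-stopped simulations (which
#' also support time-varying rates and an instantaneous mass-extinction
#' event) run a forward Gillespie algorithm started from two crown lineages
#' and conditioned on both surviving to the present, resimulating up to
#' `max_retry` times.
#'
#' @param lambda speciation rate: a positive number or a vectorized function
#'   of age (My before present).
#' @param mu extinction rate, number or function of age.
#' @param stop "taxa" (constant rates only) or "age".
#' @param n number of extant tips (for `stop = "taxa"`).
#' @param age crown age in My (for `stop = "age"`).
#' @param event optional `list(age =, survival =)`: at that age every living
#'   lineage survives with the given probability (forward in time this is an
#'   instantaneous mass extinction).
#' @param seed optional integer seed.
#' @param max_retry resimulation cap for age-stopped trees whose crown does
#'   not survive.
#' @return a `dated_tree`.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, stop = c("taxa", "age"), n = NULL,
                             age = NULL, event = NULL, seed = NULL,
                             max_retry = 1000L) {
  stop <- match.arg(stop)
  with_seed(seed, {
    if (stop == "taxa") {
      if (is.function(lambda) || is.function(mu))
        stop("taxa-stopped simulation supports constant rates only; use stop = \"age\"")
      if (!is.null(event))
        stop("mass-extinction events require stop = \"age\"")
      if (is.null(n) || n < 2L) stop("supply n >= 2 for stop = \"taxa\"")
      phy <- ape::rphylo(n, birth = lambda, death = mu, fossils = FALSE)
      return(as_dated_tree(phy))
    }
    if (is.null(age) || age <= 0) stop("supply a positive crown `age` for stop = \"age\"")
    lam_fun <- if (is.function(lambda)) lambda else function(t) rep_len(lambda, length(t))
    mu_fun <- if (is.function(mu)) mu else function(t) rep_len(mu, length(t))
    for (i in seq_len(max_retry)) {
      phy <- sim_bd_forward(lam_fun, mu_fun, age, event)
      if (!is.null(phy)) return(as_dated_tree(phy))
    }
    stop("crown survival not achieved in ", max_retry, " attempts; ",
         "rates may imply near-certain extinction")
  })
}

# Forward Gillespie simulation over forward time s in [0, age]; age(s) = age - s.
# Returns NULL when the crown does not survive (either side dies out).
sim_bd_forward <- function(lam_fun, mu_fun, age, event = NULL, max_lineages = 1e5L) {
  grid <- seq(0, age, length.out = 257L)
  rate_max <- max(lam_fun(grid) + mu_fun(grid)) * 1.05 + 1e-9
  # lineage records
  start <- c(0, 0); end <- c(NA_real_, NA_real_)
  child1 <- c(NA_integer_, NA_integer_); child2 <- c(NA_integer_, NA_integer_)
  fate <- c("", "")   # "split", "death", "extant"
  alive <- c(1L, 2L)
  s <- 0
  ev_s <- if (!is.null(event)) age - event$age else Inf
  ev_done <- FALSE
  repeat {
    N <- length(alive)
    if (N == 0L) break
    wait <- rexp(1L, N * rate_max)
    s_next <- s + wait
    if (!ev_done && s_next >= ev_s) {
      s <- ev_s; ev_done <- TRUE
      kill <- alive[runif(N) > event$survival]
      for (k in kill) { end[k] <- s; fate[k] <- "death" }
      alive <- setdiff(alive, kill)
      next
    }
    if (s_next >= age) break
    s <- s_next
    a <- age - s
    lam <- lam_fun(a); mu <- mu_fun(a)
    u <- runif(1L)
    p_birth <- lam / rate_max; p_death <- mu / rate_max
    i <- alive[sample.int(length(alive), 1L)]
    if (u < p_birth) {
      m <- length(start)
      if (m + 2L > max_lineages) stop("simulation exceeded lineage cap")
      start <- c(start, s, s); end <- c(end, NA_real_, NA_real_)
      child1 <- c(child1, NA_integer_, NA_integer_)
      child2 <- c(child2, NA_integer_, NA_integer_)
      fate <- c(fate, "", "")
      end[i] <- s; fate[i] <- "split"
      child1[i] <- m + 1L; child2[i] <- m + 2L
      alive <- c(setdiff(alive, i), m + 1L, m + 2L)
    } else if (u < p_birth + p_death) {
      end[i] <- s; fate[i] <- "death"
      alive <- setdiff(alive, i)
    } # else: thinning no-op
  }
  for (i in alive) { end[i] <- age; fate[i] <- "extant" }
  # does each crown lineage have extant descendants?
  has_extant <- function(i) {
    stack <- i
    while (length(stack)) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (fate[j] == "extant") return(TRUE)
      if (fate[j] == "split") stack <- c(stack, child1[j], child2[j])
    }
    FALSE
  }
  if (!has_extant(1L) || !has_extant(2L)) return(NULL)
  tip_ct <- 0L
  nwk <- function(i) {
    len <- end[i] - start[i]
    if (fate[i] == "split")
      paste0("(", nwk(child1[i]), ",", nwk(child2[i]), "):", format(len, digits = 15))
    else {
      tip_ct <<- tip_ct + 1L
      paste0(if (fate[i] == "extant") "t" else "x", tip_ct, ":",
             format(len, digits = 15))
    }
  }
  txt <- paste0("(", nwk(1L), ",", nwk(2L), ");")
  phy <- ape::read.tree(text = txt)
  dead <- grep("^x", phy$tip.label, value = TRUE)
  if (length(dead)) phy <- ape::drop.tip(phy, dead)
  if (is.null(phy) || ape::Ntip(phy) < 2L) return(NULL)
  phy
}

#' Equal-rates or symmetric Mk rate matrix
#'
#' @param states character vector of state names.
#' @param rate transition rate (single value for "ER"; for "SYM" a vector for
#'   the upper triangle, recycled).
#' @param model "ER" (all transitions share one rate) or "SYM" (symmetric).
#' @return a rate matrix Q with rows summing to zero.
#' @export
mk_q <- function(states, rate = 0.01, model = c("ER", "SYM")) {
  model <- match.arg(model)
  k <- length(states)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (model == "ER") Q[] <- rate
  else {
    up <- which(upper.tri(Q))
    Q[up] <- rep_len(rate, length(up))
    Q <- Q + t(Q)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Simulate a discrete niche character on a tree
#'
#' Continuous-time Markov (Mk) simulation along branches, retaining the true
#' per-branch history as a regime painting for validating ancestral-state
#' methods.
#'
#' @param tree a `dated_tree`.
#' @param Q rate matrix with named states (rows summing to 0), e.g. from
#'   [mk_q()].
#' @param root_state state at the root (default: drawn uniformly).
#' @param seed optional integer seed.
#' @return list with `tip_state` (named character vector), `node_state`
#'   (true internal states, ape numbering) and `paint` (a
#'   [regime_paint()] holding the true history).
#' @export
simulate_niche <- function(tree, Q, root_state = NULL, seed = NULL) {
  tree <- as_dated_tree(tree)
  states <- rownames(Q)
  stopifnot(!is.null(states), all(abs(rowSums(Q)) < 1e-10))
  with_seed(seed, {
    if (is.null(root_state)) root_state <- sample(states, 1L)
    n <- ape::Ntip(tree)
    nnode <- tree$Nnode
    st <- character(n + nnode)
    root <- n + 1L
    st[root] <- root_state
    maps <- vector("list", nrow(tree$edge))
    ord <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder edges
    idx <- match(paste(ord[, 1L], ord[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (e in seq_len(nrow(tree$edge))) {
      row <- idx[e]
      par <- tree$edge[row, 1L]; chd <- tree$edge[row, 2L]
      len <- tree$edge.length[row]
      cur <- st[par]; left <- len
      seg <- numeric(0L); seg_st <- character(0L)
      repeat {
        out_rate <- -Q[cur, cur]
        wait <- if (out_rate > 0) rexp(1L, out_rate) else Inf
        if (wait >= left) { seg <- c(seg, left); seg_st <- c(seg_st, cur); break }
        seg <- c(seg, wait); seg_st <- c(seg_st, cur)
        left <- left - wait
        p <- Q[cur, ]; p[cur] <- 0
        cur <- sample(states, 1L, prob = p[states])
      }
      maps[[row]] <- setNames(seg, seg_st)
      st[chd] <- cur
    }
    tip_state <- setNames(st[seq_len(n)], tree$tip.label)
    paint <- regime_paint(tree, maps, source = "true-history",
                          node_state = st[(n + 1L):(n + nnode)])
    list(tip_state = tip_state, node_state = st[(n + 1L):(n + nnode)],
         paint = paint)
  })
}

#' Simulate a continuous trait under regime-dependent OU (or BM)
#'
#' Exact Ornstein--Uhlenbeck transition sampling segment by segment along a
#' regime painting; `alpha = 0` gives Brownian motion.
#'
#' @param paint a [regime_paint()] (carries the tree).
#' @param theta named vector of optima per state (trait units, e.g. ln g).
#' @param alpha selection strength (/My): scalar or named per state.
#' @param sigma2 diffusion variance (per My): scalar or named per state.
#' @param x0 root value; default is the optimum of the root segment's state.
#' @param seed optional integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_trait <- function(paint, theta, alpha, sigma2, x0 = NULL, seed = NULL) {
  tree <- paint$tree
  states <- paint$states
  th <- expand_by_state(theta, states)
  al <- expand_by_state(alpha, states)
  s2 <- expand_by_state(sigma2, states)
  with_seed(seed, {
    n <- ape::Ntip(tree)
    x <- numeric(n + tree$Nnode)
    root <- n + 1L
    root_edge <- which(tree$edge[, 1L] == root)[1L]
    root_state <- names(paint$maps[[root_edge]])[1L]
    x[root] <- if (is.null(x0)) th[root_state] else x0
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    idx <- match(paste(ord[, 1L], ord[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (e in seq_len(nrow(tree$edge))) {
      row <- idx[e]
      par <- tree$edge[row, 1L]; chd <- tree$edge[row, 2L]
      v <- x[par]
      seg <- paint$maps[[row]]
      for (k in seq_along(seg)) {
        stt <- names(seg)[k]; len <- seg[[k]]
        a <- al[stt]; s <- s2[stt]; t0 <- th[stt]
        if (a > 0) {
          m <- t0 + (v - t0) * exp(-a * len)
          vv <- s * (1 - exp(-2 * a * len)) / (2 * a)
        } else {
          m <- v; vv <- s * len
        }
        v <- rnorm(1L, m, sqrt(vv))
      }
      x[chd] <- v
    }
    setNames(x[seq_len(n)], tree$tip.label)
  })
}

expand_by_state <- function(x, states) {
  if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, length(states)), states))
  if (!all(states %in% names(x)))
    stop("missing state(s) in parameter vector: ",
         paste(setdiff(states, names(x)), collapse = ", "))
  x[states]
}

#' Posterior-like tree set by branch-length jitter
#'
#' Surrogate for a Bayesian posterior sample: internal node ages receive
#' multiplicative lognormal jitter (sd on the log scale), ultrametricity and
#' parent-older-than-child ordering are re-enforced, and edge lengths are
#' rebuilt from the jittered ages.
#'
#' @param tree a `dated_tree`.
#' @param n number of trees.
#' @param sdlog lognormal jitter sd (default 0.1).
#' @param seed optional integer seed.
#' @return list of `dated_tree` objects.
#' @export
posterior_trees <- function(tree, n = 100L, sdlog = 0.1, seed = NULL) {
  tree <- as_dated_tree(tree)
  ntip <- ape::Ntip(tree)
  ages <- tree$node_age
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  with_seed(seed, lapply(seq_len(n), function(i) {
    a <- ages
    jit <- exp(rnorm(tree$Nnode, 0, sdlog))
    a[(ntip + 1L):(ntip + tree$Nnode)] <- a[(ntip + 1L):(ntip + tree$Nnode)] * jit
    # enforce parent strictly older than child, preorder
    for (e in seq_len(nrow(pre))) {
      par <- pre[e, 1L]; chd <- pre[e, 2L]
      if (chd > ntip && a[chd] >= a[par]) a[chd] <- a[par] * 0.999
    }
    out <- tree
    out$edge.length <- a[out$edge[, 1L]] - a[out$edge[, 2L]]
    out$node_age <- NULL; out$crown_age <- NULL
    class(out) <- "phylo"
    as_dated_tree(out)
  }))
}

#' Build a complete synthetic scenario bundle
#'
#' Generates a two-clade ultrametric tree (default clade sizes 101 and 19
#' joined at a 50 My crown, speciation 0.15 vs 0.08 lineages/My), a
#' diet-by-activity niche character under an Mk process, ln body mass under
#' regime-specific OU, a genus-style richness table, a Cenozoic-like
#' temperature covariate, extinct-species flags, and a posterior-like tree
#' set -- everything the analysis pipeline consumes, with true parameters
#' recorded.
#'
#' @param seed integer seed (the whole bundle is reproducible from it).
#' @param n_clade1,n_clade2 extant tip counts of the two crown clades.
#' @param lambda1,mu1,lambda2,mu2 clade birth--death rates (lineages/My).
#' @param crown_age root crown age in My.
#' @param states niche state alphabet (default 6 diet-by-activity levels).
#' @param q Mk transition rate (/My) between niche states (equal-rates).
#' @param theta,alpha,sigma2 OU parameters of ln body mass per niche state
#'   (theta named per state; alpha and sigma2 scalar or named).
#' @param n_posterior size of the posterior-like tree set.
#' @param n_extinct number of (largest-bodied) species flagged extinct.
#' @param missing_mass number of species whose body mass is dropped from the
#'   trait table (emulating incomplete trait data).
#' @param dir optional directory; when given, all pieces are written as
#'   plain-text files (Newick, CSV, JSON truth file).
#' @return list with `tree`, `clades` (tip labels per clade), `niche`
#'   (tip states), `paint` (true niche history), `mass` (named ln-gram
#'   values), `extinct` (named logical), `richness` (data frame),
#'   `covariate` (a [covariate_curve()]), `posterior` (list of trees) and
#'   `truth` (all generating parameters).
#' @export
make_scenario <- function(seed = 42L,
                          n_clade1 = 101L, n_clade2 = 19L,
                          lambda1 = 0.15, mu1 = 0.05,
                          lambda2 = 0.08, mu2 = 0.0,
                          crown_age = 50,
                          states = c("nocturnal-folivore", "nocturnal-frugivore",
                                     "nocturnal-omnivore", "diurnal-folivore",
                                     "diurnal-frugivore", "diurnal-omnivore"),
                          q = 0.003,
                          theta = c("nocturnal-folivore" = 6.0,
                                    "nocturnal-frugivore" = 5.5,
                                    "nocturnal-omnivore" = 5.0,
                                    "diurnal-folivore" = 8.5,
                                    "diurnal-frugivore" = 8.0,
                                    "diurnal-omnivore" = 7.5),
                          alpha = 0.055, sigma2 = 0.055,
                          n_posterior = 100L, n_extinct = 17L,
                          missing_mass = 1L, dir = NULL) {
  seeds <- child_seeds(seed, 8L)
  # clade trees conditioned to be younger than the root crown age
  sim_clade <- function(n, lam, mu, sd) {
    for (k in seq_len(200L)) {
      tr <- simulate_bd_tree(lam, mu, stop = "taxa", n = n, seed = sd + k - 1L)
      if (tr$crown_age < crown_age * 0.98) return(tr)
    }
    stop("could not simulate a clade younger than the root crown age")
  }
  cl1 <- sim_clade(n_clade1, lambda1, mu1, seeds[[1L]])
  cl2 <- sim_clade(n_clade2, lambda2, mu2, seeds[[2L]])
  cl1$tip.label <- sprintf("M%03d", seq_len(n_clade1))  # island radiation
  cl2$tip.label <- sprintf("L%03d", seq_len(n_clade2))  # mainland sister clade
  tree <- join_clades(cl1, cl2, crown_age)
  # niche and trait
  Q <- mk_q(states, rate = q, model = "ER")
  niche_sim <- simulate_niche(tree, Q, root_state = "nocturnal-frugivore",
                              seed = seeds[[3L]])
  mass <- simulate_trait(niche_sim$paint, theta = theta, alpha = alpha,
                         sigma2 = sigma2, seed = seeds[[4L]])
  # extinct flags: the largest-bodied island-clade species (subfossil analogue)
  island <- grep("^M", tree$tip.label, value = TRUE)
  extinct_sp <- island[order(mass[island], decreasing = TRUE)][seq_len(n_extinct)]
  extinct <- setNames(tree$tip.label %in% extinct_sp, tree$tip.label)
  # genus-style richness: a handful of tips stand for unsampled species
  rich <- with_seed(seeds[[5L]], {
    m <- setNames(rep(1L, ape::Ntip(tree)), tree$tip.label)
    lucky <- sample(island, 6L)
    m[lucky] <- sample(2:4, 6L, replace = TRUE)
    data.frame(tip_label = names(m), n_species = as.integer(m),
               row.names = NULL)
  })
  # Cenozoic-like cooling curve: warm early, cooling toward the present
  cov_age <- seq(crown_age + 10, 0, by = -1)
  cov_val <- 12 + 10 * cov_age / (crown_age + 10) +
    3 * exp(-((cov_age - crown_age * 0.7) / 5)^2)
  covariate <- covariate_curve(cov_age, cov_val, method = "linear")
  posterior <- posterior_trees(tree, n = n_posterior, sdlog = 0.1,
                               seed = seeds[[6L]])
  mass_tab <- mass
  if (missing_mass > 0L) {
    drop <- with_seed(seeds[[7L]], sample(names(mass), missing_mass))
    mass_tab <- mass[setdiff(names(mass), drop)]
  }
  truth <- list(seed = seed, lambda = c(clade1 = lambda1, clade2 = lambda2),
                mu = c(clade1 = mu1, clade2 = mu2), crown_age = crown_age,
                q = q, theta = theta, alpha = alpha, sigma2 = sigma2,
                root_state = "nocturnal-frugivore",
                node_state = niche_sim$node_state)
  bundle <- list(tree = tree,
                 clades = list(clade1 = cl1$tip.label, clade2 = cl2$tip.label),
                 niche = niche_sim$tip_state, paint = niche_sim$paint,
                 mass = mass_tab, extinct = extinct, richness = rich,
                 covariate = covariate, posterior = posterior, truth = truth)
  if (!is.null(dir)) write_scenario(bundle, dir)
  bundle
}

# Join two clade trees below a common root of the given crown age.
join_clades <- function(cl1, cl2, crown_age) {
  stem1 <- crown_age - cl1$crown_age
  stem2 <- crown_age - cl2$crown_age
  t1 <- ape::write.tree(cl1); t2 <- ape::write.tree(cl2)
  txt <- paste0("(", sub(";$", "", t1), ":", format(stem1, digits = 15), ",",
                sub(";$", "", t2), ":", format(stem2, digits = 15), ");")
  as_dated_tree(ape::read.tree(text = txt))
}

# Write a scenario bundle as plain-text files.
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tree(bundle$tree, file.path(dir, "tree.nwk"))
  ape::write.tree(do.call(c, lapply(bundle$posterior, function(x) {
    class(x) <- "phylo"; x
  })), file.path(dir, "posterior.nwk"))
  niche_parts <- do.call(rbind, strsplit(unname(bundle$niche), "-"))
  traits <- data.frame(species = bundle$tree$tip.label,
                       ln_mass_g = unname(bundle$mass[bundle$tree$tip.label]),
                       activity = niche_parts[, 1L], diet = niche_parts[, 2L],
                       extinct = unname(bundle$extinct))
  write.csv(traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(bundle$richness, file.path(dir, "richness.csv"), row.names = FALSE)
  write.csv(data.frame(age_my = bundle$covariate$age,
                       value = bundle$covariate$value),
            file.path(dir, "covariate.csv"), row.names = FALSE)
  writeLines(cat_json(bundle$truth[setdiff(names(bundle$truth), "node_state")]),
             file.path(dir, "truth.json"))
  writeLines(c(paste("clade1:", paste(bundle$clades$clade1, collapse = ",")),
               paste("clade2:", paste(bundle$clades$clade2, collapse = ","))),
             file.path(dir, "clades.txt"))
  invisible(dir)
}

cat_json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
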