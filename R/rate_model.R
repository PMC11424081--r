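# State-dependent rates of multivariate Brownian motion: pruning likelihood,
# random-local-clock tip rates, a joint MCMC over discrete histories /
# background rates / state multipliers with a state-dependence indicator,
# and robust phylogenetic regression of tip rates on latitude.

# ---- likelihood ------------------------------------------------------------

# Precomputed tree context shared by likelihood and samplers.
tree_context <- function(tree, traits) {
  traits <- as.matrix(traits)
  sp <- tree$tip.label
  if (!is.null(rownames(traits))) traits <- traits[sp, , drop = FALSE]
  stopifnot(nrow(traits) == length(sp))
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  n <- length(sp)
  ne <- nrow(tree$edge)
  # descendant edges of each edge (edges whose path to root passes through it)
  kids_of <- split(seq_len(ne), tree$edge[, 1])
  desc <- vector("list", ne)
  # bottom-up over postorder edge order: children edges resolved first
  for (i in idx) {
    v <- tree$edge[i, 2]
    below <- kids_of[[as.character(v)]]
    desc[[i]] <- if (is.null(below)) integer(0)
    else c(below, unlist(desc[below]))
  }
  terminal <- match(seq_len(n), tree$edge[, 2])
  list(tree = tree, traits = traits, n = n, ne = ne, p = ncol(traits),
       post_edge = tree$edge[idx, , drop = FALSE], post_idx = idx,
       edge_len = tree$edge.length, desc = desc, terminal = terminal,
       n_nodes = n + tree$Nnode)
}

bm_loglik_ctx <- function(ctx, edge_var, root_mean = NULL) {
  bm_prune_cpp(ctx$post_edge, edge_var[ctx$post_idx, , drop = FALSE],
               ctx$traits, ctx$n, ctx$n_nodes, root_mean)
}

#' State-dependent Brownian motion log-likelihood
#'
#' Independent-trait BM likelihood in which the variance contributed by an
#' edge for trait j is
#' `prop_j * sigma2_0 * multiplier(edge) * sum_segments zeta(state) * duration`.
#' Computed by the pruning (contrast) algorithm; the root value is the GLS
#' mean per trait, so the result equals the dense multivariate-normal density
#' with covariance built from shared weighted path lengths.
#'
#' @param tree `ape::phylo`.
#' @param traits n x p matrix of size-corrected traits (rownames = species).
#' @param history `latgrad_history` covering every branch (states index
#'   `zeta`).
#' @param sigma2_0 global rate scale (trait variance per Myr).
#' @param branch_multipliers background rate multiplier per edge (default 1).
#' @param zeta state-dependent rate multipliers.
#' @param trait_props relative per-trait rates (default all 1).
#' @return log-likelihood.
#' @export
sdbm_loglik <- function(tree, traits, history, sigma2_0,
                        branch_multipliers = NULL, zeta = NULL,
                        trait_props = NULL) {
  ctx <- tree_context(tree, traits)
  if (is.null(branch_multipliers)) branch_multipliers <- rep(1, ctx$ne)
  if (is.null(zeta)) zeta <- rep(1, 4)
  if (is.null(trait_props)) trait_props <- rep(1, ctx$p)
  if (sigma2_0 <= 0 || any(branch_multipliers <= 0) || any(zeta <= 0) ||
      any(trait_props <= 0))
    stop("rates must be positive", call. = FALSE)
  obs <- attr(history, "obs") %||% seq_along(zeta)
  w <- vapply(history$maps, function(m)
    sum(zeta[obs[as.integer(names(m))]] * m), 0)
  ev <- (branch_multipliers * w) %o% (trait_props * sigma2_0)
  bm_loglik_ctx(ctx, ev)$loglik
}

# state-duration matrix (ne x K) from a history, hidden classes collapsed
# onto their observed state
state_durations <- function(history, K, edges = NULL) {
  obs <- attr(history, "obs") %||% seq_len(K)
  maps <- if (is.null(edges)) history$maps else history$maps[edges]
  t(vapply(maps, function(m) {
    out <- numeric(K)
    st <- obs[as.integer(names(m))]
    for (j in seq_along(m)) out[st[j]] <- out[st[j]] + m[j]
    out
  }, numeric(K)))
}

# ---- MCMC core -------------------------------------------------------------

# Joint sampler over log sigma2_0, random-local-clock background shifts,
# per-trait proportions, and (optionally) state multipliers zeta with a
# state-dependence indicator delta and simmap history redraws.
sdbm_mcmc <- function(ctx, iters, burnin, prior_shifts, seed,
                      state_dependent = FALSE, mk_model = NULL,
                      tip_states = NULL, init_history = NULL,
                      likelihood = TRUE, thin = NULL,
                      shift_sd = 0.5, K = 4) {
  set.seed(seed)
  ne <- ctx$ne; p <- ctx$p
  pz <- min(0.9, prior_shifts / ne)
  thin <- thin %||% max(1L, ceiling(iters / 10000))
  # state
  ls2 <- log(init_sigma2(ctx))
  z <- rep(FALSE, ne); phi <- numeric(ne); logb <- numeric(ne)
  wprop <- rep(1 / p, p)                      # trait proportion simplex
  wzeta <- rep(1 / K, K)                      # zeta simplex
  delta <- state_dependent
  if (state_dependent) {
    pr <- mk_prune(ctx$tree, tip_states, mk_model)
    hist_cur <- init_history
    unif <- uniformization_tables(mk_model$Q)
    D <- state_durations(hist_cur, K)
  } else {
    D <- matrix(ctx$edge_len, ne, 1)
  }
  edge_w <- function() {
    if (!state_dependent) return(drop(D))
    zet <- if (delta) K * wzeta else rep(1, K)
    drop(D %*% zet)
  }
  cur_w <- edge_w()
  loglik <- function(ls2v, logbv, wv, wpv) {
    if (!likelihood) return(0)
    ev <- (exp(logbv) * wv) %o% (p * wpv * exp(ls2v))
    bm_loglik_ctx(ctx, ev)$loglik
  }
  cur_ll <- loglik(ls2, logb, cur_w, wprop)
  lprior_ls2 <- function(x) dnorm(x, 0, 10, log = TRUE)
  n_keep <- floor(iters / thin)
  out <- matrix(NA_real_, n_keep, 3 + K + p,
                dimnames = list(NULL, c("sigma2_0", "delta", "n_shifts",
                                        paste0("zeta", seq_len(K)),
                                        paste0("prop", seq_len(p)))))
  bsum <- numeric(ne); bn <- 0
  kept <- 0L
  move_probs <- if (state_dependent)
    c(s2 = 0.18, prop = 0.12, shift = 0.18, mag = 0.10,
      zeta = 0.22, delta = 0.08, hist = 0.12)
  else c(s2 = 0.3, prop = 0.2, shift = 0.3, mag = 0.2)
  mv_names <- names(move_probs)
  keep_from <- ceiling(burnin * iters)
  for (it in seq_len(iters)) {
    mv <- sample(mv_names, 1, prob = move_probs)
    if (mv == "s2") {
      prop_ls2 <- ls2 + runif(1, -0.4, 0.4)
      ll <- loglik(prop_ls2, logb, cur_w, wprop)
      if (log(runif(1)) < ll - cur_ll + lprior_ls2(prop_ls2) - lprior_ls2(ls2)) {
        ls2 <- prop_ls2; cur_ll <- ll
      }
    } else if (mv == "prop" && p > 1) {
      nw <- simplex_step(wprop)
      if (!is.null(nw)) {
        ll <- loglik(ls2, logb, cur_w, nw)
        if (log(runif(1)) < ll - cur_ll) { wprop <- nw; cur_ll <- ll }
      }
    } else if (mv == "shift") {
      e <- sample.int(ne, 1)
      if (!z[e]) {
        newphi <- rnorm(1, 0, shift_sd)
        nlogb <- logb
        ids <- c(e, ctx$desc[[e]])
        nlogb[ids] <- nlogb[ids] + newphi
        ll <- loglik(ls2, nlogb, cur_w, wprop)
        if (log(runif(1)) < ll - cur_ll + log(pz) - log(1 - pz)) {
          z[e] <- TRUE; phi[e] <- newphi; logb <- nlogb; cur_ll <- ll
        }
      } else {
        nlogb <- logb
        ids <- c(e, ctx$desc[[e]])
        nlogb[ids] <- nlogb[ids] - phi[e]
        ll <- loglik(ls2, nlogb, cur_w, wprop)
        if (log(runif(1)) < ll - cur_ll + log(1 - pz) - log(pz)) {
          z[e] <- FALSE; phi[e] <- 0; logb <- nlogb; cur_ll <- ll
        }
      }
    } else if (mv == "mag") {
      act <- which(z)
      if (length(act)) {
        e <- act[sample.int(length(act), 1)]
        newphi <- phi[e] + rnorm(1, 0, 0.25)
        nlogb <- logb
        ids <- c(e, ctx$desc[[e]])
        nlogb[ids] <- nlogb[ids] + (newphi - phi[e])
        ll <- loglik(ls2, nlogb, cur_w, wprop)
        lpr <- dnorm(newphi, 0, shift_sd, TRUE) - dnorm(phi[e], 0, shift_sd, TRUE)
        if (log(runif(1)) < ll - cur_ll + lpr) {
          phi[e] <- newphi; logb <- nlogb; cur_ll <- ll
        }
      }
    } else if (mv == "zeta") {
      nw <- simplex_step(wzeta)
      if (!is.null(nw)) {
        old <- wzeta; wzeta <- nw
        nwv <- edge_w()
        ll <- if (delta) loglik(ls2, logb, nwv, wprop) else cur_ll
        if (log(runif(1)) < ll - cur_ll) { cur_w <- nwv; cur_ll <- ll }
        else wzeta <- old
      }
    } else if (mv == "delta") {
      old <- delta; delta <- !delta
      nwv <- edge_w()
      ll <- loglik(ls2, logb, nwv, wprop)
      if (log(runif(1)) < ll - cur_ll) { cur_w <- nwv; cur_ll <- ll }
      else delta <- old
    } else if (mv == "hist") {
      nh <- redraw_history_subtree(hist_cur, ctx$tree, mk_model, pr, unif)
      nD <- D
      nD[nh$edges, ] <- state_durations(nh$history, K, nh$edges)
      oldD <- D; D <- nD
      oldh <- hist_cur; hist_cur <- nh$history
      nwv <- edge_w()
      ll <- loglik(ls2, logb, nwv, wprop)
      if (log(runif(1)) < ll - cur_ll) { cur_w <- nwv; cur_ll <- ll }
      else { D <- oldD; hist_cur <- oldh }
    }
    if (it > keep_from) {
      bsum <- bsum + exp(logb); bn <- bn + 1
      if (it %% thin == 0 && kept < n_keep) {
        kept <- kept + 1L
        out[kept, ] <- c(exp(ls2), as.numeric(delta), sum(z),
                         K * wzeta, p * wprop)
      }
    }
  }
  out <- out[seq_len(kept), , drop = FALSE]
  list(samples = out, branch_rate_mean = if (bn > 0) bsum / bn else rep(1, ne),
       history = if (state_dependent) hist_cur else NULL)
}

# symmetric two-coordinate transfer move on a simplex
simplex_step <- function(w, step = 0.08) {
  k <- length(w)
  ab <- sample.int(k, 2)
  u <- runif(1, -step, step)
  w2 <- w
  w2[ab[1]] <- w[ab[1]] + u
  w2[ab[2]] <- w[ab[2]] - u
  if (any(w2 <= 1e-6)) return(NULL)
  w2
}

init_sigma2 <- function(ctx) {
  # crude moment estimate: mean squared contrast rate across traits
  v <- mean(apply(ctx$traits, 2, stats::var))
  depth <- mean(node_depths(ctx$tree)[seq_len(ctx$n)])
  max(v / depth, 1e-8)
}

# Redraw the discrete history below a random edge, conditioned on the state
# at the edge's parent node and the tip data (exact conditional draw under
# the fixed Mk model; the trait-likelihood Metropolis ratio is applied by the
# caller).
redraw_history_subtree <- function(history, tree, model, pr, unif,
                                   max_jumps = 1e6) {
  ne <- nrow(tree$edge)
  e0 <- sample.int(ne, 1)
  todo <- e0
  kids_of <- split(seq_len(ne), tree$edge[, 1])
  node_states <- history$node_states
  maps <- history$maps
  touched <- integer(0)
  while (length(todo)) {
    i <- todo[1]; todo <- todo[-1]
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    a <- node_states[u]
    wv <- pr$P[[i]][a, ] * pr$partial[v, ]
    b <- sample.int(length(wv), 1, prob = wv)
    node_states[v] <- b
    maps[[i]] <- sample_ctmc_bridge(a, b, tree$edge.length[i], model$Q, unif,
                                    pr$P[[i]][a, b], max_jumps, i)
    touched <- c(touched, i)
    below <- kids_of[[as.character(v)]]
    if (!is.null(below)) todo <- c(todo, below)
  }
  h <- history
  h$maps <- maps
  h$node_states <- node_states
  h$tip_states <- stats::setNames(node_states[seq_along(tree$tip.label)],
                                  tree$tip.label)
  list(history = h, edges = touched)
}

# ---- user-facing samplers --------------------------------------------------

#' Tip rates under a random-local-clock multivariate BM
#'
#' MCMC over shift placements (per-branch inclusion probability chosen so the
#' prior mean shift count equals `prior_n_shifts` after scaling by tree
#' size), lognormal shift magnitudes, a global rate scale, and per-trait
#' proportions. The tip rate of a species is the posterior mean of
#' `sigma2_0 x background multiplier` on its terminal branch.
#'
#' @param tree `ape::phylo`; @param traits n x p size-corrected traits.
#' @param prior_n_shifts prior expected shift count on the reference tree
#'   scale (rescaled by `n_branches / 6364`).
#' @param iters MCMC iterations; @param burnin fraction discarded.
#' @param seed seed; @param likelihood set `FALSE` for prior-only sampling.
#' @return list of class `latgrad_tiprates`: `tip_rates` (data.frame with
#'   posterior mean and 90% interval), `branch_rate_mean`, `samples`,
#'   `ess_sigma2`, `low_ess` flag.
#' @export
rlc_tip_rates <- function(tree, traits, prior_n_shifts = 500, iters = 300000,
                          burnin = 0.1, seed = 1, likelihood = TRUE) {
  ctx <- tree_context(tree, traits)
  eff_shifts <- prior_n_shifts * ctx$ne / 6364
  res <- sdbm_mcmc(ctx, iters, burnin, eff_shifts, seed,
                   state_dependent = FALSE, likelihood = likelihood)
  s2 <- res$samples[, "sigma2_0"]
  es <- ess(s2)
  if (es < 200) warning("sigma2_0 effective sample size below 200")
  tipr <- mean(s2) * res$branch_rate_mean[ctx$terminal]
  tr <- data.frame(species = tree$tip.label, rate = tipr)
  structure(list(tip_rates = tr, branch_rate_mean = res$branch_rate_mean,
                 samples = res$samples, sigma2_mean = mean(s2),
                 ess_sigma2 = es, low_ess = es < 200),
            class = "latgrad_tiprates")
}

#' Joint MCMC for state-dependent rates of multivariate BM
#'
#' Jointly samples the discrete character history (simmap redraws on random
#' subtrees under Mk parameters fixed at their ML estimates), background
#' branch rates (random local clock), the global scale, per-trait
#' proportions, state multipliers `zeta` (arithmetic mean 1), and a
#' state-dependence indicator `delta` with a Bernoulli(0.5) prior
#' (spike-and-slab: `delta = 0` forces `zeta == 1` in the likelihood).
#'
#' @inheritParams rlc_tip_rates
#' @param tip_states observed quartile states (1..4) named by tip label.
#' @param mk_model optional fitted `latgrad_mk`; by default an ER 1-class
#'   model is fitted by ML.
#' @return list of class `latgrad_ratepost`: `samples` (includes
#'   `sigma2_0`, `delta`, `zeta1..4`, `prop*`, `n_shifts`), `p_delta`
#'   (posterior P(state dependence)), `state_rates` (posterior mean
#'   `sigma2_0 * zeta_k`), `branch_rate_mean`, `ess_sigma2`, `low_ess`.
#' @export
musscrat_mcmc <- function(tree, traits, tip_states, prior_n_shifts = 500,
                          iters = 300000, burnin = 0.1, seed = 1,
                          mk_model = NULL, likelihood = TRUE) {
  ctx <- tree_context(tree, traits)
  K <- 4
  if (is.null(mk_model)) {
    fits <- fit_mk_models(tree, tip_states, tyings = "ER", n_classes = 1,
                          n_observed = K, n_starts = 3, seed = seed)
    mk_model <- fits[[1]]$model
  }
  init <- sample_stochastic_maps(tree, tip_states, mk_model, n_maps = 1,
                                 seed = seed + 1)[[1]]
  eff_shifts <- prior_n_shifts * ctx$ne / 6364
  res <- sdbm_mcmc(ctx, iters, burnin, eff_shifts, seed,
                   state_dependent = TRUE, mk_model = mk_model,
                   tip_states = tip_states, init_history = init,
                   likelihood = likelihood, K = K)
  s2 <- res$samples[, "sigma2_0"]
  es <- ess(s2)
  if (es < 200) warning("sigma2_0 effective sample size below 200")
  zeta <- res$samples[, paste0("zeta", 1:K), drop = FALSE]
  structure(list(samples = res$samples,
                 p_delta = mean(res$samples[, "delta"]),
                 state_rates = colMeans(zeta * s2),
                 branch_rate_mean = res$branch_rate_mean,
                 mk_model = mk_model, ess_sigma2 = es, low_ess = es < 200),
            class = "latgrad_ratepost")
}

#' Pairwise state-rate fold-differences
#'
#' Posterior distribution of `zeta_a / zeta_b` for every ordered state pair,
#' summarized as the posterior mean and central 95% credible interval.
#'
#' @param posterior `latgrad_ratepost` (or a samples matrix with `zeta*`
#'   columns).
#' @return data.frame: `a`, `b`, `mean`, `lo`, `hi`.
#' @export
state_rate_ratios <- function(posterior) {
  samples <- if (is.list(posterior) && !is.null(posterior$samples))
    posterior$samples else posterior
  zc <- grep("^zeta", colnames(samples), value = TRUE)
  if (!length(zc) || nrow(samples) == 0) stop("empty posterior", call. = FALSE)
  K <- length(zc)
  rows <- list()
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    r <- samples[, zc[a]] / samples[, zc[b]]
    rows[[length(rows) + 1L]] <- data.frame(
      a = a, b = b, mean = mean(r),
      lo = unname(quantile(r, 0.025)), hi = unname(quantile(r, 0.975)))
  }
  do.call(rbind, rows)
}

# ---- robust phylogenetic regression ---------------------------------------

#' Robust phylogenetic regression (Huber M-estimation)
#'
#' Whitens response and design by the inverse Cholesky factor of the BM
#' covariance, then fits by iteratively reweighted least squares with the
#' Huber loss (k = 1.345). The robust R^2 is
#' `1 - sum(rho(residual)) / sum(rho(centered response))` on the whitened
#' scale, with the centering itself a robust intercept-only fit; the slope
#' p-value uses the standard M-estimation covariance with a small-sample
#' correction.
#'
#' @param tree `ape::phylo`; @param y response named by species (e.g. log tip
#'   rates); @param x predictor named by species (latitude or |latitude|).
#' @param huber_k tuning constant.
#' @return list of class `latgrad_robustfit`: `slope`, `intercept`, `r2`,
#'   `p_value`, `se_slope`.
#' @export
robust_phylo_regression <- function(tree, y, x, huber_k = 1.345) {
  sp <- tree$tip.label
  if (!is.null(names(y))) y <- y[sp]
  if (!is.null(names(x))) x <- x[sp]
  n <- length(sp)
  C <- ape::vcv(tree)[sp, sp]
  U <- chol(C)                       # C = t(U) %*% U
  W <- backsolve(U, diag(n), transpose = TRUE)  # W = t(U)^{-1}
  ys <- W %*% y
  Xs <- W %*% cbind(1, x)
  if (qr(Xs)$rank < 2) stop("singular design", call. = FALSE)
  fit <- huber_irls(Xs, ys, huber_k)
  fit0 <- huber_irls(W %*% matrix(1, n, 1), ys, huber_k)
  rho <- function(r, s) {
    u <- r / s
    ifelse(abs(u) <= huber_k, 0.5 * u^2, huber_k * abs(u) - 0.5 * huber_k^2)
  }
  s <- fit$scale
  if (s < 1e-12) {
    r2 <- 1
  } else {
    num <- sum(rho(fit$residuals, s))
    den <- sum(rho(fit0$residuals, s))
    r2 <- if (den <= 0) 1 else max(0, min(1, 1 - num / den))
  }
  # M-estimator covariance (Huber 1973 correction, as in standard rlm output)
  u <- fit$residuals / max(s, 1e-12)
  psi <- pmax(-huber_k, pmin(huber_k, u))
  dpsi <- as.numeric(abs(u) <= huber_k)
  pdim <- 2
  kcorr <- 1 + pdim / n * stats::var(dpsi) / mean(dpsi)^2
  vhat <- kcorr^2 * (s^2 * sum(psi^2) / (n - pdim)) / mean(dpsi)^2
  XtXi <- solve(crossprod(Xs))
  se <- sqrt(vhat * diag(XtXi))
  tval <- fit$coef[2] / se[2]
  pval <- 2 * stats::pt(-abs(tval), df = n - pdim)
  structure(list(slope = unname(fit$coef[2]), intercept = unname(fit$coef[1]),
                 r2 = r2, p_value = pval, se_slope = unname(se[2]),
                 scale = s),
            class = "latgrad_robustfit")
}

huber_irls <- function(X, y, k, max_iter = 100, tol = 1e-10) {
  beta <- qr.solve(X, y)
  for (it in seq_len(max_iter)) {
    r <- drop(y - X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-12) break
    w <- pmin(1, k / pmax(abs(r) / s, 1e-300))
    Xw <- X * w
    beta_new <- solve(crossprod(Xw, X), crossprod(Xw, y))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  r <- drop(y - X %*% beta)
  list(coef = drop(beta), residuals = r,
       scale = max(stats::mad(r, center = 0), 0))
}
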