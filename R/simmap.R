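# Stochastic character maps by backward sampling plus endpoint-conditioned
# path sampling via uniformization, and the occupancy-through-time profile.

#' Sample stochastic character maps
#'
#' Node states are drawn from their joint conditional distribution by
#' backward sampling from the pruning tables; within-branch histories are
#' then drawn conditioned on the branch endpoints by uniformization with
#' dominating rate `1.05 * max |Q_ii|`. Maps are exact draws from the
#' posterior distribution of histories given the model parameters.
#'
#' @inheritParams mk_loglik
#' @param n_maps number of maps.
#' @param seed integer seed.
#' @param max_jumps cap on dominating-process jumps per branch.
#' @return list of `latgrad_history` objects (states on the expanded scale;
#'   the observed-state map is attached as `attr(, "obs")`).
#' @export
sample_stochastic_maps <- function(tree, tip_states, model, n_maps = 1000,
                                   seed = 1, max_jumps = 1e6) {
  set.seed(seed)
  pr <- mk_prune(tree, tip_states, model)
  if (sum(root_prior(model) * pr$partial[length(tree$tip.label) + 1L, ]) <= 0)
    stop("tip data impossible under this model", call. = FALSE)
  unif <- uniformization_tables(model$Q)
  lapply(seq_len(n_maps), function(m)
    draw_one_map(tree, model, pr, unif, max_jumps))
}

uniformization_tables <- function(Q) {
  omega <- 1.05 * max(-diag(Q))
  R <- if (omega > 0) diag(nrow(Q)) + Q / omega else diag(nrow(Q))
  env <- new.env(parent = emptyenv())
  env$pow <- list(diag(nrow(Q)), R)   # R^0, R^1
  env$omega <- omega
  env$R <- R
  env
}

r_power <- function(unif, k) {
  while (length(unif$pow) < k + 1L)
    unif$pow[[length(unif$pow) + 1L]] <-
      unif$pow[[length(unif$pow)]] %*% unif$R
  unif$pow[[k + 1L]]
}

draw_one_map <- function(tree, model, pr, unif, max_jumps) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  root <- n + 1L
  node_states <- integer(nn)
  w <- root_prior(model) * pr$partial[root, ]
  node_states[root] <- sample.int(length(w), 1, prob = w)
  maps <- vector("list", nrow(tree$edge))
  for (i in rev(pr$post)) {   # preorder
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    a <- node_states[u]
    wv <- pr$P[[i]][a, ] * pr$partial[v, ]
    b <- sample.int(length(wv), 1, prob = wv)
    node_states[v] <- b
    maps[[i]] <- sample_ctmc_bridge(a, b, tree$edge.length[i], model$Q,
                                    unif, pr$P[[i]][a, b], max_jumps, i)
  }
  tips <- node_states[seq_len(n)]
  names(tips) <- tree$tip.label
  structure(list(tree = tree, maps = maps, node_states = node_states,
                 tip_states = tips),
            class = "latgrad_history", obs = model$obs)
}

# Endpoint-conditioned CTMC path on one branch via uniformization.
sample_ctmc_bridge <- function(a, b, len, Q, unif, pab, max_jumps, edge_id) {
  if (unif$omega == 0 || len == 0) {
    if (a != b) stop("impossible endpoints on zero-rate branch", call. = FALSE)
    out <- len; names(out) <- as.character(a)
    return(out)
  }
  # N | endpoints:  P(N = k) prop to dpois(k, omega * len) * R^k[a, b]
  mu <- unif$omega * len
  u <- runif(1)
  cum <- 0; k <- -1L
  target <- u * pab * exp(mu)   # sum_k mu^k/k! R^k[a,b] = e^mu * P[a,b]
  term <- 1                      # mu^k / k!
  repeat {
    k <- k + 1L
    if (k > 0) term <- term * mu / k
    cum <- cum + term * r_power(unif, k)[a, b]
    if (cum >= target || k >= max_jumps) break
  }
  if (k >= max_jumps)
    stop(sprintf("uniformization cap exceeded on edge %d", edge_id), call. = FALSE)
  if (k == 0L) {
    out <- len; names(out) <- as.character(a)
    return(out)
  }
  # intermediate states of the dominating chain
  states <- integer(k + 1L)
  states[1] <- a
  if (k > 1L) for (j in 2:k) {
    p <- unif$R[states[j - 1L], ] * r_power(unif, k - j + 1L)[, b]
    states[j] <- sample.int(length(p), 1, prob = p)
  }
  states[k + 1L] <- b
  times <- c(0, sort(runif(k, 0, len)), len)
  # drop virtual (self) jumps
  segs <- numeric(0); sts <- integer(0)
  cur <- states[1]; start <- 0
  for (j in seq_len(k)) {
    if (states[j + 1L] != cur) {
      segs <- c(segs, times[j + 1L] - start); sts <- c(sts, cur)
      start <- times[j + 1L]; cur <- states[j + 1L]
    }
  }
  segs <- c(segs, len - start); sts <- c(sts, cur)
  names(segs) <- as.character(sts)
  segs
}

#' Number of state changes in a history
#' @param history `latgrad_history`.
#' @param observed count only changes of the observed state (default counts
#'   expanded-state changes).
#' @export
history_change_count <- function(history, observed = FALSE) {
  obs <- attr(history, "obs")
  sum(vapply(history$maps, function(m) {
    st <- as.integer(names(m))
    if (observed && !is.null(obs)) st <- obs[st]
    sum(diff(st) != 0)
  }, 0))
}

#' State occupancy through time from stochastic maps
#'
#' Time is measured backward from the present (the maximum tip depth). Within
#' each bin, the lineage-time spent in each observed state (summing over
#' hidden classes) is divided by the total lineage-time in that bin; the
#' profile is averaged over maps with 5% and 95% quantiles.
#'
#' @param maps list of `latgrad_history` sharing one tree.
#' @param bin_width bin width in Myr.
#' @param n_observed number of observed states (inferred from the maps'
#'   `obs` attribute when present).
#' @return data.frame (`bin_start`, `bin_end`, `state`, `mean`, `q05`,
#'   `q95`); `bin_start`/`bin_end` are times before present, bins with zero
#'   lineage-time are absent.
#' @export
occupancy_through_time <- function(maps, bin_width = 1, n_observed = NULL) {
  if (!length(maps)) stop("empty map list", call. = FALSE)
  tree <- maps[[1]]$tree
  obs <- attr(maps[[1]], "obs")
  if (is.null(obs)) obs <- seq_len(max(vapply(maps[[1]]$maps, function(m)
    max(as.integer(names(m))), 0L)))
  if (is.null(n_observed)) n_observed <- max(obs)
  d <- node_depths(tree)
  ra <- max(d[seq_along(tree$tip.label)])
  nb <- ceiling(ra / bin_width - 1e-9)
  per_map <- lapply(maps, function(h) {
    occ <- matrix(0, nb, n_observed)
    for (i in seq_len(nrow(h$tree$edge))) {
      pos <- d[h$tree$edge[i, 1]]
      m <- h$maps[[i]]
      st <- obs[as.integer(names(m))]
      for (j in seq_along(m)) {
        t_old <- ra - pos              # time before present, older end
        pos <- pos + m[j]
        t_new <- ra - pos
        if (m[j] <= 0) next
        # segment spans [t_new, t_old] backward times
        lo <- max(0, t_new); hi <- min(nb * bin_width, t_old)
        if (hi <= lo) next
        b0 <- floor(lo / bin_width + 1e-12)
        b1 <- min(nb - 1L, floor((hi - 1e-12) / bin_width))
        for (b in b0:b1) {
          ov <- min(hi, (b + 1) * bin_width) - max(lo, b * bin_width)
          if (ov > 0) occ[b + 1L, st[j]] <- occ[b + 1L, st[j]] + ov
        }
      }
    }
    tot <- rowSums(occ)
    prop <- occ / ifelse(tot > 0, tot, NA)
    prop
  })
  arr <- simplify2array(per_map)      # nb x states x maps
  keep <- which(apply(!is.na(arr[, 1, , drop = FALSE]), 1, all))
  rows <- list()
  for (b in keep) for (s in seq_len(n_observed)) {
    x <- arr[b, s, ]
    rows[[length(rows) + 1L]] <- data.frame(
      bin_start = (b - 1) * bin_width, bin_end = b * bin_width, state = s,
      mean = mean(x), q05 = unname(quantile(x, 0.05)),
      q95 = unname(quantile(x, 0.95)))
  }
  do.call(rbind, rows)
}

#' Write a stochastic map as simmap-extended Newick
#'
#' Uses the phytools dialect: each branch carries
#' `{state,duration:state,duration}` annotations ordered rootward to tipward.
#'
#' @param history `latgrad_history`; @param path optional output file.
#' @return the Newick string, invisibly if written to file.
#' @export
write_simmap <- function(history, path = NULL) {
  tree <- history$tree
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- function(v) if (v <= n) tree$tip.label[v] else ""
  rec <- function(v) {
    ks <- kids[[as.character(v)]]
    core <- if (is.null(ks)) lab(v)
    else paste0("(", paste(vapply(ks, function(i) {
      m <- history$maps[[i]]
      ann <- paste(sprintf("%s,%.8g", names(m), m), collapse = ":")
      paste0(rec(tree$edge[i, 2]), ":{", ann, "}")
    }, ""), collapse = ","), ")")
    core
  }
  s <- paste0(rec(n + 1L), ";")
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}
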