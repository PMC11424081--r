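# Mk models with hidden rate classes: generator construction, pruning
# likelihood, ML fitting over an ER/ARD x 1-4 class grid, AICc/AICw model
# comparison, and joint (max-product) ancestral state reconstruction.

#' Build an Mk generator with optional hidden rate classes
#'
#' The expanded state space has `n_observed * n_classes` states, indexed
#' `(class - 1) * n_observed + observed`. Transitions between observed states
#' occur only within a class (ER: one rate per class; ARD: one rate per
#' ordered pair, row-major `1->2, 1->3, ..., 2->1, 2->3, ...`). Class
#' switches preserve the observed state and share a single rate across all
#' class pairs.
#'
#' @param tying `"ER"` or `"ARD"`.
#' @param n_classes 1 to 4 hidden rate classes.
#' @param params numeric vector: within-class rates (1 or
#'   `n_observed*(n_observed-1)` per class, classes in order), followed by one
#'   class-switch rate when `n_classes > 1`.
#' @param n_observed number of observed states (default 4 latitude quartiles).
#' @param root root treatment for likelihoods: `"flat"` (default) or
#'   `"stationary"`.
#' @return object of class `latgrad_mk` with the expanded generator `Q` and
#'   the observed-state map `obs`.
#' @export
build_mk_generator <- function(tying = c("ER", "ARD"), n_classes = 1, params,
                               n_observed = 4, root = c("flat", "stationary")) {
  tying <- match.arg(tying)
  root <- match.arg(root)
  stopifnot(n_classes >= 1, n_classes <= 4)
  r <- if (tying == "ER") 1L else n_observed * (n_observed - 1L)
  np <- r * n_classes + (n_classes > 1)
  if (length(params) != np)
    stop(sprintf("expected %d parameters for %s with %d class(es), got %d",
                 np, tying, n_classes, length(params)), call. = FALSE)
  if (any(params < 0)) stop("rates must be non-negative", call. = FALSE)
  s <- n_observed * n_classes
  Q <- matrix(0, s, s)
  for (cl in seq_len(n_classes)) {
    rates <- params[((cl - 1) * r + 1):(cl * r)]
    block <- matrix(0, n_observed, n_observed)
    if (tying == "ER") {
      block[] <- rates
    } else {
      k <- 1L
      for (i in seq_len(n_observed)) for (j in seq_len(n_observed)) {
        if (i != j) { block[i, j] <- rates[k]; k <- k + 1L }
      }
    }
    diag(block) <- 0
    idx <- (cl - 1) * n_observed + seq_len(n_observed)
    Q[idx, idx] <- block
  }
  if (n_classes > 1) {
    sw <- params[np]
    for (a in seq_len(n_classes)) for (b in seq_len(n_classes)) {
      if (a != b) {
        ia <- (a - 1) * n_observed + seq_len(n_observed)
        ib <- (b - 1) * n_observed + seq_len(n_observed)
        Q[cbind(ia, ib)] <- sw
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  structure(list(tying = tying, n_classes = n_classes, params = params,
                 n_observed = n_observed, Q = Q,
                 obs = rep(seq_len(n_observed), times = n_classes),
                 k = np, root = root),
            class = "latgrad_mk")
}

root_prior <- function(model) {
  s <- nrow(model$Q)
  if (identical(model$root, "stationary")) {
    A <- rbind(t(model$Q), rep(1, s))
    pi <- tryCatch(drop(qr.solve(A, c(rep(0, s), 1))),
                   error = function(e) rep(1 / s, s))
    pi[pi < 0] <- 0
    pi / sum(pi)
  } else rep(1 / s, s)
}

# tip_states: named integer/character/factor over observed states; NA = fully
# ambiguous.  Returns n x s likelihood matrix over expanded states.
tip_partials <- function(tree, tip_states, model) {
  n <- length(tree$tip.label)
  s <- nrow(model$Q)
  st <- tip_states
  if (is.factor(st)) st <- as.integer(st)
  if (is.character(st)) st <- as.integer(st)
  if (!is.null(names(tip_states))) st <- st[match(tree$tip.label, names(tip_states))]
  if (length(st) != n) stop("tip_states must cover every tip", call. = FALSE)
  L <- matrix(0, n, s)
  for (i in seq_len(n)) {
    if (is.na(st[i])) L[i, ] <- 1
    else {
      if (st[i] < 1 || st[i] > model$n_observed)
        stop("tip state out of range", call. = FALSE)
      L[i, model$obs == st[i]] <- 1
    }
  }
  L
}

# Pruning pass.  Returns list: partials (nn x s, rescaled), logscale (sum of
# log scalers), P (per-edge transition matrices), order (postorder edge idx).
mk_prune <- function(tree, tip_states, model) {
  Q <- model$Q
  s <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  decomp <- decompose_generator(Q)
  post <- postorder_edge_idx(tree)
  P <- vector("list", nrow(tree$edge))
  partial <- matrix(1, nn, s)
  partial[seq_len(n), ] <- tip_partials(tree, tip_states, model)
  logscale <- 0
  for (i in post) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    P[[i]] <- expm_from_decomp(decomp, tree$edge.length[i])
    contrib <- drop(P[[i]] %*% partial[v, ])
    partial[u, ] <- partial[u, ] * contrib
    m <- max(partial[u, ])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      partial[u, ] <- partial[u, ] / m
      logscale <- logscale + log(m)
    }
  }
  # final rescale of root for numerical reporting
  list(partial = partial, logscale = logscale, P = P, post = post)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' Hidden classes enter as tip ambiguity: a tip is compatible with every
#' hidden class of its observed state. The root is handled per the model's
#' root treatment (flat prior over expanded states by default).
#'
#' @param tree `ape::phylo`.
#' @param tip_states observed states (1..n_observed), named by tip label.
#' @param model `latgrad_mk`.
#' @return log-likelihood (`-Inf` for impossible data).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  pr <- mk_prune(tree, tip_states, model)
  root <- length(tree$tip.label) + 1L
  lik <- sum(root_prior(model) * pr$partial[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, with `n` the number of tips.
#'
#' @param lnL maximized log-likelihood; @param k free parameter count;
#' @param n sample size (tips).
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#' @param aicc_values numeric vector.
#' @return weights summing to 1.
#' @export
aic_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit a grid of Mk / hidden-rates models by maximum likelihood
#'
#' Each model is optimized by multi-start bounded maximization on log rates
#' (bounds `[1e-9, 100]` per Myr). Models whose best start fails to converge
#' are flagged and excluded from the Akaike weights with a warning.
#'
#' @param tree `ape::phylo`; @param tip_states observed states named by tip.
#' @param tyings subset of `c("ER", "ARD")`.
#' @param n_classes integer vector within 1..4.
#' @param n_observed observed state count.
#' @param n_starts optimizer restarts per model.
#' @param root root treatment passed to [build_mk_generator()].
#' @param seed seed for the random restarts.
#' @return list of class `latgrad_mkfits`, one element per model, sorted by
#'   AICc; each has `model`, `lnL`, `k`, `AICc`, `AICw`, `converged`.
#' @export
fit_mk_models <- function(tree, tip_states, tyings = c("ER", "ARD"),
                          n_classes = 1:4, n_observed = 4, n_starts = 10,
                          root = "flat", seed = 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  fits <- list()
  for (ty in tyings) for (nc in n_classes) {
    r <- if (ty == "ER") 1L else n_observed * (n_observed - 1L)
    np <- r * nc + (nc > 1)
    if (n - np - 1 <= 0) next  # AICc undefined at this sample size
    nll <- function(logp) {
      m <- build_mk_generator(ty, nc, exp(logp), n_observed, root)
      ll <- mk_loglik(tree, tip_states, m)
      if (!is.finite(ll)) 1e10 else -ll
    }
    # crude scale guess: one change per total tree length
    guess <- log(max(1 / sum(tree$edge.length), 1e-6))
    best <- NULL
    for (st in seq_len(n_starts)) {
      init <- if (st == 1) rep(guess, np) else runif(np, guess - 3, guess + 3)
      o <- tryCatch(
        stats::optim(init, nll, method = "L-BFGS-B",
                     lower = log(1e-9), upper = log(100),
                     control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) next
    model <- build_mk_generator(ty, nc, exp(best$par), n_observed, root)
    fits[[paste0(ty, nc)]] <- list(
      name = sprintf("%s-%d", ty, nc), model = model, lnL = -best$value,
      k = np, AICc = aicc(-best$value, np, n),
      converged = best$convergence == 0)
  }
  if (!length(fits)) stop("no model could be fitted", call. = FALSE)
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (any(!conv))
    warning("excluded from AICw (non-convergence): ",
            paste(names(fits)[!conv], collapse = ", "))
  w <- rep(NA_real_, length(fits))
  w[conv] <- aic_weights(vapply(fits[conv], `[[`, 0, "AICc"))
  for (i in seq_along(fits)) fits[[i]]$AICw <- w[i]
  fits <- fits[order(vapply(fits, `[[`, 0, "AICc"))]
  class(fits) <- "latgrad_mkfits"
  fits
}

#' @export
print.latgrad_mkfits <- function(x, ...) {
  df <- data.frame(model = vapply(x, `[[`, "", "name"),
                   lnL = vapply(x, `[[`, 0, "lnL"),
                   k = vapply(x, `[[`, 0L, "k"),
                   AICc = vapply(x, `[[`, 0, "AICc"),
                   AICw = vapply(x, `[[`, 0, "AICw"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Joint (maximum a posteriori) ancestral states
#'
#' Max-product dynamic program over the tree (the Viterbi analogue): returns
#' the single jointly most probable assignment of expanded states to internal
#' nodes, reported on the observed scale. Ties break toward the lowest state
#' index.
#'
#' @inheritParams mk_loglik
#' @return integer vector of observed states for nodes `n+1 .. n+Nnode`;
#'   expanded states in `attr(, "expanded")`.
#' @export
joint_ancestral_states <- function(tree, tip_states, model) {
  Q <- model$Q; s <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  decomp <- decompose_generator(Q)
  tp <- tip_partials(tree, tip_states, model)
  logtip <- log(tp)
  M <- matrix(0, nn, s)
  M[seq_len(n), ] <- logtip
  post <- postorder_edge_idx(tree)
  back <- vector("list", nrow(tree$edge))
  logP <- vector("list", nrow(tree$edge))
  for (i in post) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    lP <- log(pmax(expm_from_decomp(decomp, tree$edge.length[i]), 0))
    logP[[i]] <- lP
    sc <- sweep(lP, 2, M[v, ], "+")        # sc[a, b] = log P(a->b) + M_v(b)
    back[[i]] <- max.col(sc, ties.method = "first")
    M[u, ] <- M[u, ] + sc[cbind(seq_len(s), back[[i]])]
  }
  root <- n + 1L
  sc <- log(root_prior(model)) + M[root, ]
  assign <- integer(nn)
  assign[root] <- which.max(sc)
  for (i in rev(post)) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    assign[v] <- back[[i]][assign[u]]
  }
  out <- model$obs[assign[(n + 1L):nn]]
  attr(out, "expanded") <- assign[(n + 1L):nn]
  out
}
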