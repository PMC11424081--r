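# Independent oracles used across tests.  These deliberately avoid the
# package's own computational routes: matrix exponentials by series
# summation, likelihoods by exhaustive enumeration or dense multivariate
# normals, hulls by brute-force facet enumeration.

# matrix exponential by scaled Taylor series (independent of the package's
# eigen/Pade route)
expm_series <- function(A, t = 1) {
  A <- A * t
  s <- max(0L, ceiling(log2(max(sum(abs(A)), 1))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:40) {
    term <- term %*% A / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# exhaustive-enumeration Mk likelihood: sum over all internal-node expanded
# state assignments of prod(root prior, transition probabilities, tip
# compatibility).  Trees small (<= 5 tips).
mk_loglik_enum <- function(tree, tip_states, model) {
  Q <- model$Q
  s <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    expm_series(Q, tree$edge.length[i]))
  st <- tip_states[tree$tip.label]
  internal <- (n + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
  pi0 <- latgrad:::root_prior(model)
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[internal] <- grid[g, ]
    lik <- pi0[assign[n + 1L]]
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      if (v <= n) {
        # tip: sum transition prob over compatible expanded states
        comp <- which(model$obs == st[v])
        lik <- lik * sum(P[[i]][assign[u], comp])
      } else {
        lik <- lik * P[[i]][assign[u], assign[v]]
      }
    }
    tot <- tot + lik
  }
  if (tot <= 0) -Inf else log(tot)
}

# exhaustive joint reconstruction: argmax over internal assignments, each tip
# taking its best compatible expanded state within the product
joint_enum <- function(tree, tip_states, model) {
  Q <- model$Q
  s <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    expm_series(Q, tree$edge.length[i]))
  st <- tip_states[tree$tip.label]
  internal <- (n + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
  pi0 <- latgrad:::root_prior(model)
  best <- -Inf; best_g <- NULL
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[internal] <- grid[g, ]
    lik <- pi0[assign[n + 1L]]
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      if (v <= n) {
        comp <- which(model$obs == st[v])
        lik <- lik * max(P[[i]][assign[u], comp])
      } else {
        lik <- lik * P[[i]][assign[u], assign[v]]
      }
    }
    if (lik > best + 1e-15) { best <- lik; best_g <- grid[g, ] }
  }
  model$obs[best_g]
}

# exact marginal ancestral probabilities by enumeration (small trees)
marginal_enum <- function(tree, tip_states, model, node) {
  Q <- model$Q
  s <- nrow(Q)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(i)
    expm_series(Q, tree$edge.length[i]))
  st <- tip_states[tree$tip.label]
  internal <- (n + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
  pi0 <- latgrad:::root_prior(model)
  marg <- numeric(s)
  for (g in seq_len(nrow(grid))) {
    assign <- integer(nn)
    assign[internal] <- grid[g, ]
    lik <- pi0[assign[n + 1L]]
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      if (v <= n) {
        comp <- which(model$obs == st[v])
        lik <- lik * sum(P[[i]][assign[u], comp])
      } else lik <- lik * P[[i]][assign[u], assign[v]]
    }
    marg[assign[node]] <- marg[assign[node]] + lik
  }
  marg / sum(marg)
}

# dense multivariate-normal BM oracle with GLS root mean, per trait
bm_mvn_oracle <- function(tree, tips, edge_var_per_trait) {
  sp <- tree$tip.label
  n <- length(sp)
  total <- 0
  for (j in seq_len(ncol(tips))) {
    tr2 <- tree
    tr2$edge.length <- edge_var_per_trait[, j]
    C <- ape::vcv(tr2)[sp, sp]
    x <- tips[sp, j]
    Ci <- solve(C)
    one <- rep(1, n)
    mu <- drop(crossprod(one, Ci %*% x) / crossprod(one, Ci %*% one))
    r <- x - mu
    total <- total - 0.5 * (n * log(2 * pi) +
                              as.numeric(determinant(C)$modulus) +
                              drop(crossprod(r, Ci %*% r)))
  }
  total
}

# closed-form GLS estimator (generic inverse route)
gls_oracle <- function(C, x, y) {
  X <- cbind(1, x)
  Ci <- solve(C)
  drop(solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y))
}

# brute-force 3-D convex hull volume: enumerate facets (3-subsets with all
# points on one side), decompose into tetrahedra from the centroid
hull3d_bruteforce <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- crossprod_3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    if (sum(nrm^2) < 1e-20) next
    d <- as.vector((pts - matrix(pts[i, ], n, 3, byrow = TRUE)) %*% nrm)
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      V <- rbind(pts[i, ] - ctr, pts[j, ] - ctr, pts[k, ] - ctr)
      vol <- vol + abs(det(V)) / 6
    }
  }
  vol
}

crossprod_3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                a[3] * b[1] - a[1] * b[3],
                                a[1] * b[2] - a[2] * b[1])

# expected number of changes on one branch conditioned on endpoints, by
# numerical integration of P(0,s) q P(s,t) / P(0,t)
expected_changes_oracle <- function(Q, t, a, b, ngrid = 2000) {
  s_grid <- seq(0, t, length.out = ngrid + 1)
  h <- t / ngrid
  Pt <- expm_series(Q, t)
  tot <- 0
  states <- seq_len(nrow(Q))
  for (m in seq_len(ngrid)) {
    s <- (s_grid[m] + s_grid[m + 1]) / 2
    P1 <- expm_series(Q, s); P2 <- expm_series(Q, t - s)
    for (i in states) for (j in states) {
      if (i != j) tot <- tot + P1[a, i] * Q[i, j] * P2[j, b] * h
    }
  }
  tot / Pt[a, b]
}

# random ultrametric tree helper
yule_tree <- function(n, seed) latgrad::simulate_bd_tree(n, 1, 0, seed = seed)

rand_states <- function(tree, K, seed) {
  set.seed(seed)
  stats::setNames(sample.int(K, length(tree$tip.label), replace = TRUE),
                  tree$tip.label)
}
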