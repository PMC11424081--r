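test_that("generator construction: ER, hidden classes, ARD order", {
  m <- build_mk_generator("ER", 1, 0.3)
  expect_equal(dim(m$Q), c(4L, 4L))
  expect_true(all(m$Q[row(m$Q) != col(m$Q)] == 0.3))
  expect_equal(unname(diag(m$Q)), rep(-0.9, 4))

  m2 <- build_mk_generator("ER", 2, c(0.1, 1.0, 0.05))
  expect_equal(dim(m2$Q), c(8L, 8L))
  expect_equal(max(abs(rowSums(m2$Q))), 0, tolerance = 1e-12)
  expect_equal(m2$Q[1, 2], 0.1)   # class 1 block
  expect_equal(m2$Q[5, 6], 1.0)   # class 2 block
  expect_equal(m2$Q[1, 5], 0.05)  # class switch keeps observed state
  expect_equal(m2$Q[1, 6], 0)     # no simultaneous switch + transition

  rates <- seq(0.01, 0.12, by = 0.01)
  m3 <- build_mk_generator("ARD", 1, rates)
  expect_equal(m3$Q[1, 2], rates[1])
  expect_equal(m3$Q[1, 4], rates[3])
  expect_equal(m3$Q[2, 1], rates[4])
  expect_equal(m3$Q[4, 3], rates[12])
  expect_error(build_mk_generator("ER", 1, -1), "non-negative")
  expect_error(build_mk_generator("ARD", 1, rates[1:5]), "expected 12")
})

test_that("mk_loglik degenerate cases", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  m0 <- build_mk_generator("ER", 1, 0)
  expect_equal(mk_loglik(cherry, c(A = 2L, B = 2L), m0), log(1 / 4))
  expect_identical(mk_loglik(cherry, c(A = 1L, B = 2L), m0), -Inf)
})

test_that("mk_loglik matches exhaustive enumeration on small trees", {
  trees <- list(
    ape::read.tree(text = "((A:0.6,B:0.6):0.9,(C:1,D:1):0.5);"),
    ape::read.tree(text = "(((A:0.3,B:0.3):0.4,C:0.7):0.8,(D:1,E:1):0.5);"),
    yule_tree(5, seed = 31))
  set.seed(42)
  for (tr in trees) {
    for (rep in 1:3) {
      nobs <- sample(2:3, 1)
      ty <- sample(c("ER", "ARD"), 1)
      r <- if (ty == "ER") 1 else nobs * (nobs - 1)
      m <- build_mk_generator(ty, 1, runif(r, 0.05, 1.5), n_observed = nobs)
      st <- rand_states(tr, nobs, seed = rep * 7 + 1)
      expect_equal(mk_loglik(tr, st, m), mk_loglik_enum(tr, st, m),
                   tolerance = 1e-10)
    }
    # hidden classes
    m2 <- build_mk_generator("ER", 2, c(0.1, 0.9, 0.07), n_observed = 2)
    st <- rand_states(tr, 2, seed = 99)
    expect_equal(mk_loglik(tr, st, m2), mk_loglik_enum(tr, st, m2),
                 tolerance = 1e-10)
  }
})

test_that("hidden-class expansion with tied rates and zero switch collapses", {
  tr <- yule_tree(12, seed = 8)
  st <- rand_states(tr, 4, seed = 9)
  m1 <- build_mk_generator("ER", 1, 0.2)
  m2 <- build_mk_generator("ER", 2, c(0.2, 0.2, 0))
  expect_equal(mk_loglik(tr, st, m1), mk_loglik(tr, st, m2), tolerance = 1e-10)
})

test_that("likelihood invariant to tip order and rerooting (reversible model)", {
  tr <- yule_tree(8, seed = 13)
  st <- rand_states(tr, 3, seed = 14)
  m <- build_mk_generator("ER", 1, 0.4, n_observed = 3)
  l1 <- mk_loglik(tr, st, m)
  expect_equal(mk_loglik(tr, st[sample(names(st))], m), l1, tolerance = 1e-12)
  rt <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[5],
                  resolve.root = TRUE)
  expect_equal(mk_loglik(rt, st, m), l1, tolerance = 1e-8)
})

test_that("AICc formula and Akaike weights", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "undefined")
  w <- aic_weights(c(0, 2))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(w), 1, tolerance = 1e-10)
})

test_that("fit_mk_models: nesting, weights, ER-1 recovery at reduced scale", {
  tr <- yule_tree(80, seed = 21)
  h <- simulate_mk_history(tr, build_mk_generator("ER", 1, 0.25)$Q, seed = 22)
  fits <- fit_mk_models(tr, h$tip_states, tyings = c("ER", "ARD"),
                        n_classes = 1, n_starts = 3, seed = 1)
  byname <- stats::setNames(fits, vapply(fits, `[[`, "", "name"))
  expect_gte(byname[["ARD-1"]]$lnL, byname[["ER-1"]]$lnL - 1e-4)
  ws <- vapply(fits, `[[`, 0, "AICw")
  expect_equal(sum(ws, na.rm = TRUE), 1, tolerance = 1e-10)

  # ER-1 close to the best model when data are ER-1 (reduced replicate count)
  hits <- 0L
  for (r in 1:6) {
    trr <- yule_tree(70, seed = 400 + r)
    hh <- simulate_mk_history(trr, build_mk_generator("ER", 1, 0.3)$Q,
                              seed = 500 + r)
    ff <- fit_mk_models(trr, hh$tip_states, tyings = c("ER", "ARD"),
                        n_classes = 1, n_starts = 2, seed = r)
    er <- vapply(ff, `[[`, "", "name") == "ER-1"
    if (ff[[which(er)]]$AICc <= min(vapply(ff, `[[`, 0, "AICc")) + 2)
      hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("joint ancestral states: degenerate, enumeration oracle, tie rule", {
  tr <- yule_tree(7, seed = 17)
  st2 <- stats::setNames(rep(2L, 7), tr$tip.label)
  m <- build_mk_generator("ER", 1, 1e-8)
  expect_true(all(joint_ancestral_states(tr, st2, m) == 2L))

  tr4 <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.7,D:0.7):0.3);")
  for (seed in 1:4) {
    st <- rand_states(tr4, 2, seed = seed)
    m2 <- build_mk_generator("ER", 1, 0.6, n_observed = 2)
    expect_identical(as.integer(joint_ancestral_states(tr4, st, m2)),
                     as.integer(joint_enum(tr4, st, m2)))
  }

  cherry <- ape::read.tree(text = "(A:1,B:1);")
  mm <- build_mk_generator("ER", 1, 0.5, n_observed = 2)
  anc <- joint_ancestral_states(cherry, c(A = 1L, B = 2L), mm)
  expect_identical(as.integer(anc), 1L)  # documented tie-break
})

test_that("stochastic maps: zero-rate concordance and bridge change-count oracle", {
  tr <- yule_tree(10, seed = 23)
  st <- stats::setNames(rep(3L, 10), tr$tip.label)
  m0 <- build_mk_generator("ER", 1, 1e-9)
  maps <- sample_stochastic_maps(tr, st, m0, n_maps = 50, seed = 1)
  expect_true(all(vapply(maps, history_change_count, 0) == 0))
  expect_true(all(vapply(maps, function(h) all(h$tip_states == st), TRUE)))

  # endpoint-conditioned expected change count on a single branch
  q <- 0.6; t <- 1.4
  Q <- matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE)
  unif <- latgrad:::uniformization_tables(Q)
  P <- expm_series(Q, t)
  set.seed(7)
  cnt <- vapply(seq_len(10000), function(r) {
    b <- latgrad:::sample_ctmc_bridge(1L, 2L, t, Q, unif, P[1, 2], 1e6, 1L)
    sum(diff(as.integer(names(b))) != 0)
  }, 0)
  target <- expected_changes_oracle(Q, t, 1, 2, ngrid = 600)
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - target), 3 * se)
})

test_that("occupancy profile: constants, hand-built map, sums to one", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  h_const <- structure(list(tree = cherry,
                            maps = list(stats::setNames(1, "2"),
                                        stats::setNames(1, "2")),
                            node_states = c(2L, 2L, 2L),
                            tip_states = c(A = 2L, B = 2L)),
                       class = "latgrad_history", obs = 1:4)
  occ <- occupancy_through_time(list(h_const), bin_width = 1)
  expect_equal(occ$mean[occ$state == 2], 1)

  # one change at the bin midpoint: lineage-time 1.5 in state 1, 0.5 in 2
  h_mid <- structure(list(tree = cherry,
                          maps = list(stats::setNames(c(0.5, 0.5), c("1", "2")),
                                      stats::setNames(1, "1")),
                          node_states = c(2L, 1L, 1L),
                          tip_states = c(A = 2L, B = 1L)),
                     class = "latgrad_history", obs = 1:4)
  occ2 <- occupancy_through_time(list(h_mid), bin_width = 1)
  expect_equal(occ2$mean[occ2$state == 1], 0.75)
  expect_equal(occ2$mean[occ2$state == 2], 0.25)

  tr <- yule_tree(15, seed = 25)
  hh <- simulate_mk_history(tr, build_mk_generator("ER", 1, 0.4)$Q, seed = 26)
  occ3 <- occupancy_through_time(list(hh), bin_width = 0.5)
  sums <- tapply(occ3$mean, occ3$bin_start, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_error(occupancy_through_time(list()), "empty")
})

test_that("a late rate increase into state 4 yields a rising occupancy", {
  tr <- yule_tree(80, seed = 27)
  tr$edge.length <- tr$edge.length * (25 / latgrad:::root_age(tr))
  ra <- latgrad:::root_age(tr)
  d_switch <- ra - 12  # transitions into state 4 possible only after this depth
  Q1 <- build_mk_generator("ER", 1, 0.05)$Q
  Q1[, 4] <- 0; Q1[4, ] <- 0; diag(Q1) <- 0; diag(Q1) <- -rowSums(Q1)
  Q2 <- build_mk_generator("ER", 1, 0.05)$Q
  Q2[1:3, 4] <- 0.25; diag(Q2) <- 0; diag(Q2) <- -rowSums(Q2)
  depths <- latgrad:::node_depths(tr)
  sim_one <- function(seed) {
    set.seed(seed)
    ns <- integer(length(depths))
    ns[length(tr$tip.label) + 1L] <- sample.int(3, 1)
    maps <- vector("list", nrow(tr$edge))
    for (i in latgrad:::preorder_edge_idx(tr)) {
      u <- tr$edge[i, 1]; v <- tr$edge[i, 2]
      d0 <- depths[u]; d1 <- depths[v]
      segs <- NULL
      stt <- ns[u]
      if (d0 < d_switch) {
        len1 <- min(d1, d_switch) - d0
        p1 <- latgrad:::ctmc_forward_path(stt, len1, Q1)
        segs <- p1
        stt <- as.integer(names(p1)[length(p1)])
      }
      if (d1 > d_switch) {
        len2 <- d1 - max(d0, d_switch)
        p2 <- latgrad:::ctmc_forward_path(stt, len2, Q2)
        segs <- c(segs, p2)
        stt <- as.integer(names(p2)[length(p2)])
      }
      maps[[i]] <- segs
      ns[v] <- stt
    }
    structure(list(tree = tr, maps = maps, node_states = ns,
                   tip_states = stats::setNames(ns[seq_along(tr$tip.label)],
                                                tr$tip.label)),
              class = "latgrad_history", obs = 1:4)
  }
  hists <- lapply(1:200, function(r) sim_one(3000 + r))
  occ <- occupancy_through_time(hists, bin_width = 1)
  s4 <- occ[occ$state == 4 & occ$bin_start < 20, ]
  s4 <- s4[order(s4$bin_start), ]
  # monotone rise toward the present (bin_start is time before present)
  expect_true(all(diff(s4$mean) <= 0.01))
  expect_gt(s4$mean[1], s4$mean[nrow(s4)] + 0.1)
})
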