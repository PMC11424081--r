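# Seedable simulators: birth-death trees, discrete CTMC histories,
# state-dependent multivariate Brownian traits, allometric measurements, and
# occurrence tables. These provide the statistical structure the analysis
# assumes, so every stage is testable without external downloads.

#' Simulate an ultrametric birth-death tree with a fixed number of tips
#'
#' Forward simulation from a single lineage, conditioned on survival by
#' rejection: replicates that go extinct before reaching `n_tips` extant
#' lineages are discarded and resimulated. The simulation stops at a uniform
#' time between the moment the `n_tips`-th lineage appears and the next
#' event (simple sampling approach), and extinct subtrees are pruned.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate,death_rate per-Myr rates, `birth_rate > death_rate >= 0`.
#' @param seed integer seed.
#' @return ultrametric `ape::phylo` with tips `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, birth_rate, death_rate = 0, seed = 1) {
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0)
  set.seed(seed)
  repeat {
    res <- bd_forward_once(n_tips, birth_rate, death_rate)
    if (!is.null(res)) return(res)
  }
}

bd_forward_once <- function(n_tips, lambda, mu) {
  # lineage records grown in blocks
  cap <- 4L * n_tips + 8L
  parent <- integer(cap); tb <- numeric(cap); te <- numeric(cap)
  status <- integer(cap)  # 0 alive, 1 dead, 2 split
  parent[1] <- 0L; tb[1] <- 0; status[1] <- 0L
  nrec <- 1L
  alive <- 1L
  t <- 0
  while (TRUE) {
    na <- length(alive)
    if (na == 0L) return(NULL)
    if (na == n_tips) {
      w <- rexp(1, na * (lambda + mu))
      t <- t + runif(1, 0, w)
      break
    }
    t <- t + rexp(1, na * (lambda + mu))
    i <- alive[sample.int(na, 1)]
    if (runif(1) < lambda / (lambda + mu)) {
      status[i] <- 2L; te[i] <- t
      if (nrec + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(tb) <- cap
        length(te) <- cap; length(status) <- cap
      }
      kids <- nrec + 1:2
      parent[kids] <- i; tb[kids] <- t; status[kids] <- 0L
      nrec <- nrec + 2L
      alive <- c(setdiff(alive, i), kids)
    } else {
      status[i] <- 1L; te[i] <- t
      alive <- setdiff(alive, i)
    }
  }
  te[alive] <- t
  kids_of <- split(seq_len(nrec), parent[seq_len(nrec)])
  tipn <- 0L
  build <- function(i) {
    len <- te[i] - tb[i]
    if (status[i] == 0L) {
      tipn <<- tipn + 1L
      return(sprintf("t%d:%.15g", tipn, len))
    }
    if (status[i] == 1L) return(NULL)
    parts <- Filter(Negate(is.null), lapply(kids_of[[as.character(i)]], build))
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) {
      # extinct sister: absorb this branch length into the survivor
      sub <- parts[[1]]
      m <- regmatches(sub, regexpr(":[0-9.eE+-]+$", sub))
      stub <- sub(":[0-9.eE+-]+$", "", sub)
      return(sprintf("%s:%.15g", stub, as.numeric(substring(m, 2)) + len))
    }
    sprintf("(%s):%.15g", paste(unlist(parts), collapse = ","), len)
  }
  s <- build(1L)
  if (is.null(s)) return(NULL)
  tree <- ape::read.tree(text = paste0(s, ";"))
  if (length(tree$tip.label) != n_tips) return(NULL)
  # drop the root stem: ape stores it as root.edge only when written; the
  # string above gives the root a branch length which read.tree keeps as
  # root.edge -- remove it so root age equals the crown age
  tree$root.edge <- NULL
  tree
}

#' Simulate a discrete character history under a CTMC
#'
#' Exact forward realization: exponential waiting times with rate
#' `-Q[s, s]`, jump distribution proportional to the off-diagonal row.
#'
#' @param tree `ape::phylo`.
#' @param q_matrix generator (rows sum to 0, off-diagonals >= 0).
#' @param root_freq probability vector over states for the root draw.
#' @param seed integer seed.
#' @return a `latgrad_history`: list with `tree`, `maps` (per edge, named
#'   vector of segment durations ordered rootward to tipward, names are state
#'   indices), `node_states`, and `tip_states` (named by tip label).
#' @export
simulate_mk_history <- function(tree, q_matrix, root_freq = NULL, seed = 1) {
  check_generator(q_matrix)
  s <- nrow(q_matrix)
  if (is.null(root_freq)) root_freq <- rep(1 / s, s)
  stopifnot(length(root_freq) == s, all(root_freq >= 0),
            abs(sum(root_freq) - 1) < 1e-8)
  set.seed(seed)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  node_states <- integer(nn)
  root <- n + 1L
  node_states[root] <- sample.int(s, 1, prob = root_freq)
  maps <- vector("list", nrow(tree$edge))
  pre <- preorder_edge_idx(tree)
  for (i in pre) {
    st <- node_states[tree$edge[i, 1]]
    len <- tree$edge.length[i]
    maps[[i]] <- ctmc_forward_path(st, len, q_matrix)
    node_states[tree$edge[i, 2]] <- as.integer(names(maps[[i]])[length(maps[[i]])])
  }
  tips <- node_states[seq_len(n)]
  names(tips) <- tree$tip.label
  structure(list(tree = tree, maps = maps, node_states = node_states,
                 tip_states = tips),
            class = "latgrad_history")
}

ctmc_forward_path <- function(state, len, Q) {
  segs <- numeric(0); sts <- integer(0)
  t <- 0
  repeat {
    rate <- -Q[state, state]
    w <- if (rate > 0) rexp(1, rate) else Inf
    if (t + w >= len) {
      segs <- c(segs, len - t); sts <- c(sts, state)
      break
    }
    segs <- c(segs, w); sts <- c(sts, state)
    t <- t + w
    p <- Q[state, ]; p[state] <- 0
    state <- sample.int(length(p), 1, prob = p)
  }
  names(segs) <- as.character(sts)
  segs
}

check_generator <- function(Q) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("generator off-diagonals must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stop("generator rows must sum to 0", call. = FALSE)
  invisible(Q)
}

preorder_edge_idx <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  rev(idx)
}

postorder_edge_idx <- function(tree) rev(preorder_edge_idx(tree))

#' Simulate traits under state-dependent Brownian motion with UCLN branch rates
#'
#' Each branch carries an i.i.d. lognormal background rate (mean log 0, SD
#' `ucln_sd`). Along a branch, each history segment contributes an independent
#' Normal(0, rate x multiplier(state) x base_sigma2_j x duration) increment
#' per trait; increments are independent across traits.
#'
#' @param tree `ape::phylo`.
#' @param history `latgrad_history` on the same tree.
#' @param base_sigma2 per-trait base BM rate (length p).
#' @param multipliers positive per-state rate multiplier.
#' @param ucln_sd SD of the log branch rate (0 for a strict clock).
#' @param seed integer seed.
#' @return list: `tips` (n x p matrix, rownames tip labels), `branch_rates`
#'   (per edge), `edge_weights` (per edge, multiplier-weighted duration).
#' @export
simulate_traits_sdbm <- function(tree, history, base_sigma2, multipliers,
                                 ucln_sd = 0, seed = 1) {
  stopifnot(all(base_sigma2 > 0), all(multipliers > 0), ucln_sd >= 0)
  set.seed(seed)
  p <- length(base_sigma2)
  ne <- nrow(tree$edge)
  rates <- exp(rnorm(ne, 0, ucln_sd))
  w <- vapply(history$maps, function(m)
    sum(multipliers[as.integer(names(m))] * m), 0)
  n <- length(tree$tip.label)
  vals <- matrix(0, n + tree$Nnode, p)
  for (i in preorder_edge_idx(tree)) {
    v <- rates[i] * w[i] * base_sigma2
    vals[tree$edge[i, 2], ] <- vals[tree$edge[i, 1], ] + rnorm(p, 0, sqrt(v))
  }
  tips <- vals[seq_len(n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  colnames(tips) <- paste0("trait", seq_len(p))
  list(tips = tips, branch_rates = rates, edge_weights = w)
}

#' Simulate raw traits with allometric scaling on a latent size axis
#'
#' `log trait_j = slope_j * log size + BM noise`, exponentiated back to
#' positive measurements.
#'
#' @param tree `ape::phylo`; @param sizes positive, named by tip label.
#' @param slopes per-trait allometric slope; @param noise_sigma2 BM rate of
#'   the residual noise (0 for exact allometry); @param seed seed.
#' @return n x p matrix of positive trait values.
#' @export
simulate_allometric_traits <- function(tree, sizes, slopes, noise_sigma2 = 0.01,
                                       seed = 1) {
  stopifnot(all(sizes > 0), noise_sigma2 >= 0)
  set.seed(seed)
  n <- length(tree$tip.label)
  p <- length(slopes)
  sizes <- sizes[tree$tip.label]
  noise <- matrix(0, n + tree$Nnode, p)
  for (i in preorder_edge_idx(tree)) {
    sdv <- sqrt(noise_sigma2 * tree$edge.length[i])
    noise[tree$edge[i, 2], ] <- noise[tree$edge[i, 1], ] + rnorm(p, 0, sdv)
  }
  lt <- outer(log(sizes), slopes) + noise[seq_len(n), , drop = FALSE]
  out <- exp(lt)
  rownames(out) <- tree$tip.label
  colnames(out) <- paste0("trait", seq_len(p))
  out
}

#' Simulate a grid-cell occurrence table
#'
#' Grid cells are opaque identifiers keyed by a latitude band (1.35 degrees,
#' roughly 150 km) and a longitude slot. Each species receives a home
#' longitude and `cells_per_species` cells whose latitudes lie within
#' `latitudinal_spread` degrees of its centroid; with spread 0 every row is
#' the species' centroid cell.
#'
#' @param table trait table with `species` and `lat_centroid`.
#' @param cells_per_species rows per species.
#' @param latitudinal_spread degrees.
#' @param seed seed.
#' @return data.frame with `cell`, `species`, `cell_lat`.
#' @export
simulate_occurrence_table <- function(table, cells_per_species = 5,
                                      latitudinal_spread = 5, seed = 1) {
  set.seed(seed)
  band <- 1.35
  rows <- lapply(seq_len(nrow(table)), function(i) {
    lat0 <- table$lat_centroid[i]
    home_lon <- sample.int(240L, 1)
    lat <- lat0 + if (latitudinal_spread > 0)
      runif(cells_per_species, -latitudinal_spread, latitudinal_spread) else
        rep(0, cells_per_species)
    lat <- pmin(90, pmax(-90, lat))
    lon <- if (latitudinal_spread > 0)
      ((home_lon + sample.int(7L, cells_per_species, replace = TRUE) - 4L) %% 240L) else
        rep(home_lon %% 240L, cells_per_species)
    bi <- floor((lat + 90) / band)
    data.frame(cell = sprintf("c%03d_%03d", bi, lon),
               species = table$species[i],
               cell_lat = (bi + 0.5) * band - 90,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
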