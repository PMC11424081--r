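# Morphospace analyses: PCA of size-corrected traits, group disparity
# (Procrustes-variance convention), convex-hull volume, functional evenness,
# permutation and bootstrap significance, and per-cell assemblage summaries.

#' Principal components of size-corrected traits
#'
#' Covariance-matrix PCA of centered (not rescaled) residuals. Axes are
#' ordered by variance; the sign convention makes the largest-magnitude
#' loading of each axis positive.
#'
#' @param residual_traits n x p matrix (rownames = species).
#' @return list of class `latgrad_pca`: `scores`, `loadings`,
#'   `variance_explained` (sums to 1 over the returned axes).
#' @export
run_pca <- function(residual_traits) {
  X <- as.matrix(residual_traits)
  if (nrow(X) < 2) stop("need at least 2 species", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > max(pc$sdev) * 1e-10
  if (!all(keep)) warning(sum(!keep), " rank-deficient axis/axes dropped")
  sdev <- pc$sdev[keep]
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j]
    }
  }
  structure(list(scores = sco, loadings = rot,
                 variance_explained = sdev^2 / sum(pc$sdev^2)),
            class = "latgrad_pca")
}

#' Group disparity (Procrustes variance)
#'
#' For group g: `(1/n_g) * sum_i ||x_i - center||^2`, with the center the
#' grand mean of all species (default, matching disparity "calculated across
#' all axes using the overall mean") or the group's own mean.
#'
#' @param values n x d matrix; @param groups factor/character of length n.
#' @param center `"overall"` or `"group"`.
#' @return named numeric, one value per group level; empty groups are absent
#'   with a warning.
#' @export
group_disparity <- function(values, groups, center = c("overall", "group")) {
  center <- match.arg(center)
  values <- as.matrix(values)
  groups <- as.factor(groups)
  grand <- colMeans(values)
  out <- vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (!length(idx)) return(NA_real_)
    ctr <- if (center == "overall") grand else colMeans(values[idx, , drop = FALSE])
    mean(rowSums((values[idx, , drop = FALSE] -
                    matrix(ctr, length(idx), ncol(values), byrow = TRUE))^2))
  }, 0)
  if (anyNA(out)) {
    warning("empty group(s): ", paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Convex-hull volume of a group in morphospace
#'
#' @param scores n x d score matrix (the first six PC axes in the standard
#'   analysis); @param groups optional grouping; @param group level to
#'   measure (omit for all rows).
#' @return volume (or named vector over levels when `group` is `NULL` and
#'   `groups` given).
#' @export
hull_volume <- function(scores, groups = NULL, group = NULL) {
  scores <- as.matrix(scores)
  if (!is.null(groups) && is.null(group)) {
    groups <- as.factor(groups)
    return(vapply(levels(groups), function(g)
      hull_volume(scores[groups == g, , drop = FALSE]), 0))
  }
  if (!is.null(group)) scores <- scores[groups == group, , drop = FALSE]
  if (nrow(scores) <= ncol(scores))
    stop("group size must exceed the dimension", call. = FALSE)
  convex_hull_volume(scores)
}

#' Functional evenness (FEve) with equal weights
#'
#' Minimum-spanning-tree based regularity of species spacing in trait space:
#' with S species and MST branch lengths EW_l, partial weights
#' `PEW_l = EW_l / sum(EW)` and
#' `FEve = (sum_l min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#'
#' @param scores n x d matrix (first six PC axes in the standard analysis).
#' @return FEve in `[0, 1]`.
#' @export
functional_evenness <- function(scores) {
  scores <- as.matrix(scores)
  S <- nrow(scores)
  if (S < 3) stop("FEve needs at least 3 species", call. = FALSE)
  ew <- mst_edge_lengths(scores)
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# Prim's algorithm on Euclidean distances; returns the S-1 MST edge lengths.
mst_edge_lengths <- function(x) {
  S <- nrow(x)
  dmin <- rep(Inf, S)
  used <- logical(S)
  used[1] <- TRUE
  d1 <- sqrt(rowSums((x - matrix(x[1, ], S, ncol(x), byrow = TRUE))^2))
  dmin <- pmin(dmin, d1)
  dmin[1] <- Inf
  out <- numeric(S - 1)
  for (k in seq_len(S - 1)) {
    j <- which.min(replace(dmin, used, Inf))
    out[k] <- dmin[j]
    used[j] <- TRUE
    dj <- sqrt(rowSums((x - matrix(x[j, ], S, ncol(x), byrow = TRUE))^2))
    dmin <- pmin(dmin, dj)
  }
  out
}

dispersion_metric_fun <- function(metric) {
  switch(metric,
    disparity = function(values, groups) group_disparity(values, groups, "overall"),
    volume = function(values, groups) hull_volume(values, groups),
    evenness = function(values, groups) {
      groups <- as.factor(groups)
      vapply(levels(groups), function(g)
        functional_evenness(values[groups == g, , drop = FALSE]), 0)
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

#' Pairwise permutation p-values for a dispersion metric
#'
#' Group labels are permuted `n_perm` times with group sizes preserved; for
#' each pair of groups, `p` is the fraction of permutations whose permuted
#' absolute difference strictly exceeds the empirical absolute difference
#' (no +1 correction; a reported 0 means `< 1/n_perm`). Permutations for
#' which the metric is undefined (e.g. a degenerate hull) are redrawn and the
#' count recorded in `attr(, "resampled")`.
#'
#' @param metric `"disparity"`, `"volume"`, or `"evenness"`.
#' @param values species x d matrix appropriate for the metric (8 traits for
#'   disparity; 6 PC axes for volume/evenness).
#' @param groups factor of group labels; @param n_perm permutations;
#' @param seed seed.
#' @return list: `empirical` (per-group metric), `diff` (pairwise absolute
#'   difference matrix), `p` (pairwise p-value matrix).
#' @export
permutation_pvalues <- function(metric, values, groups, n_perm = 1000, seed = 1) {
  set.seed(seed)
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  f <- dispersion_metric_fun(metric)
  emp <- f(values, groups)
  lv <- levels(groups)
  dmat <- abs(outer(emp, emp, "-"))
  exceed <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  resampled <- 0L
  for (r in seq_len(n_perm)) {
    repeat {
      gp <- sample(groups)
      val <- tryCatch(suppressWarnings(f(values, gp)), error = function(e) NULL)
      if (!is.null(val) && !anyNA(val)) break
      resampled <- resampled + 1L
      if (resampled > 100L * n_perm)
        stop("metric undefined for almost all permutations", call. = FALSE)
    }
    pd <- abs(outer(val, val, "-"))
    exceed <- exceed + (pd > dmat)
  }
  if (resampled > 0) message(resampled, " degenerate permutation(s) redrawn")
  p <- exceed / n_perm
  diag(p) <- NA
  structure(list(empirical = emp, diff = dmat, p = p),
            resampled = resampled, class = "latgrad_permtest")
}

#' Bootstrap distributions of a dispersion metric
#'
#' Species are resampled with replacement within each group; the metric is
#' recomputed per replicate. Degenerate replicates are redrawn as in
#' [permutation_pvalues()].
#'
#' @inheritParams permutation_pvalues
#' @param n_boot replicates.
#' @return matrix `n_boot` x groups of metric values.
#' @export
bootstrap_dispersion <- function(metric, values, groups, n_boot = 1000, seed = 1) {
  set.seed(seed)
  values <- as.matrix(values)
  groups <- as.factor(groups)
  f <- dispersion_metric_fun(metric)
  lv <- levels(groups)
  out <- matrix(NA_real_, n_boot, length(lv), dimnames = list(NULL, lv))
  resampled <- 0L
  idx_by <- split(seq_along(groups), groups)
  for (r in seq_len(n_boot)) {
    repeat {
      idx <- unlist(lapply(idx_by, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]))
      val <- tryCatch(suppressWarnings(
        f(values[idx, , drop = FALSE], groups[idx])), error = function(e) NULL)
      if (!is.null(val) && !anyNA(val)) break
      resampled <- resampled + 1L
      if (resampled > 100L * n_boot)
        stop("metric undefined for almost all replicates", call. = FALSE)
    }
    out[r, ] <- val[lv]
  }
  if (resampled > 0) message(resampled, " degenerate replicate(s) redrawn")
  attr(out, "resampled") <- resampled
  out
}

#' Per-cell assemblage summaries
#'
#' For every grid cell: the disparity of member species about their own cell
#' mean (NA for cells with fewer than 2 members) and, when tip rates are
#' supplied, the arithmetic mean member tip rate (defined from 1 member up).
#' Occurrence rows for species absent from `values` are dropped with a
#' message.
#'
#' @param occurrence data.frame with `cell` and `species`.
#' @param values species x d trait/score matrix (rownames = species).
#' @param tip_rates optional named numeric of per-species rates.
#' @param center `"cell"` (default) or `"overall"` disparity centering.
#' @return data.frame: `cell`, `n_species`, `disparity`, `mean_tip_rate`.
#' @export
cell_summaries <- function(occurrence, values, tip_rates = NULL,
                           center = c("cell", "overall")) {
  center <- match.arg(center)
  values <- as.matrix(values)
  known <- occurrence$species %in% rownames(values)
  if (any(!known))
    message(sum(!known), " occurrence row(s) dropped (species not in values)")
  occurrence <- occurrence[known, , drop = FALSE]
  grand <- colMeans(values)
  cells <- split(occurrence$species, occurrence$cell)
  rows <- lapply(names(cells), function(cl) {
    sp <- unique(cells[[cl]])
    X <- values[sp, , drop = FALSE]
    disp <- if (length(sp) < 2) NA_real_ else {
      ctr <- if (center == "cell") colMeans(X) else grand
      mean(rowSums((X - matrix(ctr, nrow(X), ncol(X), byrow = TRUE))^2))
    }
    mr <- if (is.null(tip_rates)) NA_real_ else mean(tip_rates[sp])
    data.frame(cell = cl, n_species = length(sp), disparity = disp,
               mean_tip_rate = mr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
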