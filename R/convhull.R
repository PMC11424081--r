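# d-dimensional convex hull volume by incremental (beneath-beyond)
# construction.  No qhull binding is assumed; dimensions up to 6 and desk-
# scale point counts are the design envelope.

# normal of the hyperplane through the d rows of V (d x d), by cofactor
# expansion of the (d-1) x d difference matrix
facet_normal <- function(V) {
  d <- ncol(V)
  D <- V[-1, , drop = FALSE] - matrix(V[1, ], d - 1, d, byrow = TRUE)
  n <- numeric(d)
  for (k in seq_len(d))
    n[k] <- (-1)^(k + 1) * det(D[, -k, drop = FALSE])
  n
}

#' Convex hull volume in d dimensions
#'
#' Incremental beneath-beyond construction; returns the d-volume of the hull
#' of the rows of `points`. Affinely degenerate inputs give 0 with a warning.
#'
#' @param points n x d numeric matrix, `n >= d + 1`.
#' @return hull volume (area when d = 2).
#' @export
convex_hull_volume <- function(points) {
  points <- unique(as.matrix(points))
  n <- nrow(points); d <- ncol(points)
  if (n < d + 1) stop("need more points than dimensions", call. = FALSE)
  scale <- max(apply(points, 2, function(x) diff(range(x))), 1e-300)
  tol <- 1e-9 * scale^1  # distances scale linearly
  # greedy affinely independent start set
  sel <- 1L
  B <- NULL   # orthonormal basis of the affine span directions
  for (k in seq_len(d)) {
    resid2 <- vapply(seq_len(n), function(i) {
      v <- points[i, ] - points[sel[1], ]
      if (!is.null(B)) v <- v - B %*% crossprod(B, v)
      sum(v^2)
    }, 0)
    j <- which.max(resid2)
    if (sqrt(resid2[j]) < tol) {
      warning("affinely degenerate point set: hull volume 0")
      return(0)
    }
    sel <- c(sel, j)
    v <- points[j, ] - points[sel[1], ]
    if (!is.null(B)) v <- v - B %*% crossprod(B, v)
    B <- cbind(B, v / sqrt(sum(v^2)))
  }
  o <- colMeans(points[sel, , drop = FALSE])   # interior point
  make_facet <- function(idx) {
    V <- points[idx, , drop = FALSE]
    nrm <- facet_normal(V)
    nn <- sqrt(sum(nrm^2))
    if (nn < .Machine$double.eps) return(NULL)
    nrm <- nrm / nn
    off <- sum(nrm * V[1, ])
    if (sum(nrm * o) > off) { nrm <- -nrm; off <- -off }
    list(idx = sort(idx), normal = nrm, offset = off)
  }
  facets <- lapply(seq_len(d + 1), function(k) make_facet(sel[-k]))
  facets <- Filter(Negate(is.null), facets)
  rest <- setdiff(seq_len(n), sel)
  for (p in rest) {
    x <- points[p, ]
    vis <- which(vapply(facets, function(f)
      sum(f$normal * x) > f$offset + tol, TRUE))
    if (!length(vis)) next
    ridges <- list()
    for (fi in vis) {
      idx <- facets[[fi]]$idx
      for (k in seq_along(idx)) {
        key <- paste(idx[-k], collapse = "_")
        ridges[[key]] <- (ridges[[key]] %||% 0L) + 1L
      }
    }
    horizon <- names(ridges)[vapply(ridges, identical, TRUE, 1L)]
    facets <- facets[-vis]
    for (key in horizon) {
      ridge <- as.integer(strsplit(key, "_")[[1]])
      f <- make_facet(c(ridge, p))
      if (!is.null(f)) facets[[length(facets) + 1L]] <- f
    }
  }
  vol <- 0
  for (f in facets) {
    V <- points[f$idx, , drop = FALSE] -
      matrix(o, length(f$idx), d, byrow = TRUE)
    vol <- vol + abs(det(V)) / factorial(d)
  }
  vol
}
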