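# Body size as a geometric mean and size correction via phylogenetic
# regression residuals under a Brownian-motion covariance.

#' Geometric-mean body size
#'
#' Size proxy: the geometric mean of the three major axes of body shape
#' (standard length, maximum body width, maximum body depth).
#'
#' @param std_length,body_width,body_depth positive lengths (same units).
#' @return `(std_length * body_width * body_depth)^(1/3)`.
#' @export
geometric_mean_size <- function(std_length, body_width, body_depth) {
  if (any(c(std_length, body_width, body_depth) <= 0))
    stop("size components must be positive", call. = FALSE)
  exp((log(std_length) + log(body_width) + log(body_depth)) / 3)
}

#' Size-correct log traits by phylogenetic GLS residuals
#'
#' For each trait, fits `log trait ~ log size` by generalized least squares
#' with error covariance proportional to shared branch lengths (Brownian
#' motion; optional Pagel's lambda transform of the off-diagonals). Residuals
#' are observed minus fitted values and have phylogenetically weighted mean
#' zero per trait.
#'
#' @param tree `ape::phylo` whose tips match the rows.
#' @param log_traits n x p matrix of log trait values (rownames = species).
#' @param log_size length-n log size vector (named by species).
#' @param lambda branch-length transform in `[0, 1]`; 1 is plain BM.
#' @return list of class `latgrad_sizecorr`: `residuals` (n x p), `slopes`,
#'   `intercepts`, `size` (exp of `log_size`), `species`.
#' @export
phylo_size_residuals <- function(tree, log_traits, log_size, lambda = 1) {
  log_traits <- as.matrix(log_traits)
  sp <- tree$tip.label
  if (!is.null(rownames(log_traits))) log_traits <- log_traits[sp, , drop = FALSE]
  if (!is.null(names(log_size))) log_size <- log_size[sp]
  stopifnot(nrow(log_traits) == length(sp), length(log_size) == length(sp))
  C <- ape::vcv(tree)[sp, sp]
  if (lambda != 1) {
    D <- diag(C)
    C <- lambda * C
    diag(C) <- D
  }
  Ci <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  X <- cbind(intercept = 1, size = log_size)
  XtCi <- crossprod(X, Ci)
  beta <- solve(XtCi %*% X, XtCi %*% log_traits)
  fitted <- X %*% beta
  res <- log_traits - fitted
  structure(list(residuals = res, slopes = beta["size", ],
                 intercepts = beta["intercept", ],
                 size = exp(log_size), species = sp),
            class = "latgrad_sizecorr")
}

#' Full size-correction step on a matched trait table
#'
#' Computes geometric-mean size, logs the eight measurements, and returns
#' phylogenetic regression residuals plus size per species.
#'
#' @param tree matched `ape::phylo`.
#' @param table matched trait table (see [match_tree_traits()]).
#' @inheritParams phylo_size_residuals
#' @return `latgrad_sizecorr` (residuals are log-scale, dimensionless).
#' @export
size_correct_table <- function(tree, table, lambda = 1) {
  stopifnot(identical(tree$tip.label, table$species))
  size <- geometric_mean_size(table$std_length, table$body_width,
                              table$body_depth)
  lt <- log(as.matrix(table[, trait_columns()]))
  rownames(lt) <- table$species
  phylo_size_residuals(tree, lt, stats::setNames(log(size), table$species),
                       lambda = lambda)
}
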