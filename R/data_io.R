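# Reading trees and trait tables, reconciling species sets, and assigning
# equal-count absolute-latitude quartiles.

#' Trait table column names required by [load_traits()]
#' @export
trait_columns <- function() {
  c("std_length", "jaw_length", "mouth_width", "body_width",
    "body_depth", "ped_width", "ped_depth", "head_depth")
}

required_columns <- function() c("species", trait_columns(), "lat_centroid")

normalize_labels <- function(x) gsub("[ ]+", "_", trimws(x))

#' Read a time-calibrated phylogeny from Newick
#'
#' Tip labels are whitespace-normalized (internal spaces become underscores).
#' The tree must be rooted with unique tip labels and positive branch lengths.
#' Trees that are not ultrametric within `1e-6 * root age` are accepted with a
#' warning, since published time trees are nearly but rarely exactly
#' ultrametric; downstream time-binning normalizes tip depths.
#'
#' @param path path to a plain Newick file.
#' @return an `ape::phylo`.
#' @export
load_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # unify spaces inside labels with underscores before ape drops them
  txt <- gsub("(?<=[A-Za-z0-9_.'-])[ \t]+(?=[A-Za-z0-9_.'-])", "_", txt,
              perl = TRUE)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse failure: no tree in file", call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  tree$tip.label <- normalize_labels(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (any(tree$edge.length == 0)) warning("zero-length branches present")
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  d <- node_depths(tree)
  tipd <- d[seq_along(tree$tip.label)]
  ra <- max(tipd)
  if (diff(range(tipd)) > 1e-6 * ra)
    warning(sprintf("tree not ultrametric: tip depth range %.6g vs root age %.6g",
                    diff(range(tipd)), ra))
  tree
}

#' Read a species-by-trait table
#'
#' Expects a delimited file (comma or tab, sniffed from the header line) with
#' columns `species`, the eight linear measurements (see [trait_columns()]),
#' and `lat_centroid` in degrees. Rows with any missing required value are
#' dropped with a message reporting the count.
#'
#' @param path path to a CSV/TSV file with a header.
#' @return a `data.frame`, one row per species, `quartile` unset.
#' @export
load_traits <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  miss <- setdiff(required_columns(), names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[, c(required_columns(),
               setdiff(names(df), required_columns())), drop = FALSE]
  df$species <- normalize_labels(df$species)
  need <- required_columns()
  keep <- stats::complete.cases(df[, need]) &
    apply(df[, need] != "", 1, all)
  if (any(!keep)) message(sum(!keep), " row(s) dropped (missing values)")
  df <- df[keep, , drop = FALSE]
  for (cl in c(trait_columns(), "lat_centroid"))
    df[[cl]] <- as.numeric(df[[cl]])
  if (any(abs(df$lat_centroid) > 90))
    stop("lat_centroid out of range [-90, 90]", call. = FALSE)
  if (any(df[, trait_columns()] <= 0))
    stop("nonpositive trait measurements", call. = FALSE)
  if (anyDuplicated(df$species))
    stop("duplicate species rows", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Reconcile a tree and a trait table
#'
#' Prunes the tree to the species shared with the table, restricts the table
#' to the same set, and puts table rows in the tree's tip order.
#'
#' @param tree an `ape::phylo`.
#' @param table a trait `data.frame` with a `species` column.
#' @return list with elements `tree` and `table`.
#' @export
match_tree_traits <- function(tree, table) {
  tree$tip.label <- normalize_labels(tree$tip.label)
  table$species <- normalize_labels(table$species)
  common <- intersect(tree$tip.label, table$species)
  if (!length(common)) stop("no species shared between tree and table", call. = FALSE)
  if (length(common) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, common)
  table <- table[match(tree$tip.label, table$species), , drop = FALSE]
  rownames(table) <- NULL
  list(tree = tree, table = table)
}

#' Assign equal-count absolute-latitude quartiles
#'
#' Species are ranked by `|lat_centroid|` and split into four bins with equal
#' counts: the `n %% 4` leftover species go to the lowest-index (most
#' equatorial) bins. Ties in absolute latitude are broken by ascending species
#' label, so assignment is invariant to row order. Reported breakpoints are
#' the maximum absolute latitude within each of the first three bins.
#'
#' @param table trait `data.frame` with `species` and `lat_centroid`.
#' @return the table with a `quartile` factor
#'   (`lower`/`second`/`third`/`upper`); breakpoints in
#'   `attr(, "breakpoints")`.
#' @export
assign_latitude_quartiles <- function(table) {
  n <- nrow(table)
  if (n < 4) stop("need at least 4 species to form quartiles", call. = FALSE)
  alat <- abs(table$lat_centroid)
  ord <- order(alat, table$species)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + c(rep(1L, extra), rep(0L, 4L - extra))
  labels <- c("lower", "second", "third", "upper")
  bin <- rep(labels, times = sizes)
  q <- character(n)
  q[ord] <- bin
  table$quartile <- factor(q, levels = labels)
  br <- vapply(labels[1:3], function(l) max(alat[table$quartile == l]), 0)
  attr(table, "breakpoints") <- br
  table
}

#' Write a trait table (round-trip safe)
#' @param table data.frame; @param path output path; full double precision.
#' @export
write_traits <- function(table, path) {
  tmp <- table
  num <- vapply(tmp, is.numeric, TRUE)
  for (j in which(num)) tmp[[j]] <- sprintf("%.17g", tmp[[j]])
  utils::write.table(tmp, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
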