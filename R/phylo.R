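#' Parse and write Newick trees with validation
#'
#' Thin, validating wrappers around the standard Newick reader/writer.
#' Trees must be rooted with branch lengths on every non-root edge and
#' unique tip labels; violations raise informative errors (unbalanced
#' parentheses are reported with the character offset).
#'
#' @param text a Newick string (terminated by `;`).
#' @return `parse_newick()`: an [ape::phylo] tree. `write_newick()`: a
#'   Newick string; the round trip preserves topology, branch lengths and
#'   labels.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced ')' at character offset ", i)
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick string (", depth, " unclosed)")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  validate_phylogeny(tree)
  tree
}

#' @rdname parse_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree) {
  validate_phylogeny(tree)
  ape::write.tree(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' Requires >= 2 uniquely labelled tips, finite non-negative branch lengths
#' on all edges, and a rooted topology.
#'
#' @param tree an [ape::phylo] tree.
#' @return the tree, invisibly, if valid.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; they are required")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      !all(is.finite(tree$edge.length)))
    stop("every edge must carry a finite branch length")
  if (any(tree$edge.length < 0)) stop("negative branch lengths not allowed")
  invisible(tree)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j (the
#' depth of their most recent common ancestor); the diagonal holds tip
#' depths.  Under Brownian motion, trait covariances are proportional to
#' this matrix, which therefore supplies the error structure for
#' phylogenetic generalized least squares.
#'
#' @param tree a valid [ape::phylo] tree.
#' @return symmetric positive-semidefinite matrix with tip labels as
#'   dimnames, tips ordered as in `tree$tip.label`.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda` in \[0, 1\], leaving tip
#' variances unchanged: `lambda = 1` keeps the full Brownian expectation,
#' `lambda = 0` removes all phylogenetic covariance (a star phylogeny).
#'
#' @param V covariance matrix from [phylo_covariance()].
#' @param lambda signal multiplier in \[0, 1\].
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  d <- diag(V)
  W <- V * lambda
  diag(W) <- d
  W
}

#' Felsenstein's phylogenetic independent contrasts
#'
#' Standardized contrasts by the pruning algorithm: at each internal node
#' joining daughters i and j with (possibly extended) branch lengths b_i,
#' b_j and values x_i, x_j, the contrast is (x_i - x_j) / sqrt(b_i + b_j);
#' the ancestral value is the branch-length-weighted mean, and the node's
#' own parent branch is extended by b_i * b_j / (b_i + b_j).  Under
#' Brownian motion the n - 1 contrasts are independent draws with variance
#' equal to the evolutionary rate.
#'
#' @param tree a rooted, fully bifurcating [ape::phylo] tree.
#' @param trait named numeric vector of tip values (names = tip labels) or
#'   unnamed vector in `tree$tip.label` order.
#' @param resolve_polytomies if `TRUE`, polytomies are randomly resolved
#'   with zero-length branches before pruning (uses the current RNG state);
#'   by default polytomies are an error.
#' @return numeric vector of `n - 1` contrasts, named by the ape internal
#'   node number that produced each.
#' @export
independent_contrasts <- function(tree, trait, resolve_polytomies = FALSE) {
  validate_phylogeny(tree)
  n_children <- tabulate(tree$edge[, 1])
  if (any(n_children[n_children > 0] != 2L)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; resolve them or set ",
           "`resolve_polytomies = TRUE`")
    tree <- ape::multi2di(tree)
  }
  ntip <- ape::Ntip(tree)
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing))
      stop("missing trait values for taxa: ", paste(missing, collapse = ", "))
    x_tip <- trait[tree$tip.label]
  } else {
    if (length(trait) != ntip)
      stop("unnamed trait vector must have one value per tip")
    x_tip <- trait
  }
  if (!all(is.finite(x_tip))) stop("all tip trait values must be finite")

  nnode <- tree$Nnode
  x <- c(as.numeric(x_tip), rep(NA_real_, nnode))
  # working branch lengths indexed by child node of each edge
  bl <- rep(NA_real_, ntip + nnode)
  bl[tree$edge[, 2]] <- tree$edge.length

  tr <- ape::reorder.phylo(tree, "postorder")
  contrasts <- numeric(nnode)
  nodes <- integer(nnode)
  k <- 0L
  # postorder edges come in sibling pairs for a binary tree
  for (e in seq(1L, nrow(tr$edge), by = 2L)) {
    parent <- tr$edge[e, 1]
    ch <- tr$edge[c(e, e + 1L), 2]
    b <- bl[ch]
    if (b[1] + b[2] <= 0)
      stop("zero-length cherry at node ", parent,
           ": contrasts are undefined")
    k <- k + 1L
    contrasts[k] <- (x[ch[1]] - x[ch[2]]) / sqrt(b[1] + b[2])
    nodes[k] <- parent
    x[parent] <- if (b[1] == 0) x[ch[1]] else if (b[2] == 0) x[ch[2]] else
      (x[ch[1]] / b[1] + x[ch[2]] / b[2]) / (1 / b[1] + 1 / b[2])
    if (!is.na(bl[parent]))
      bl[parent] <- bl[parent] + b[1] * b[2] / (b[1] + b[2])
  }
  names(contrasts) <- nodes
  contrasts
}
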