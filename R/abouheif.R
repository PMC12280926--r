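#' Abouheif topological proximity matrix
#'
#' The branch-length-free phylogenetic proximity between tips i and j:
#' one over the product of the numbers of direct descendants of every
#' internal node on the path from i to j (including the MRCA). The
#' diagonal is zero. Sister tips under a bifurcation get proximity 1/2;
#' tips separated by many speciation events get exponentially less.
#'
#' @param tree An \code{ape} \code{phylo} (only the topology is used).
#' @return Symmetric n x n matrix with tip labels as dimnames.
#' @export
abouheif_proximity <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  a <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      path <- ape::nodepath(tree, i, j)
      internal <- path[path > n]
      a[i, j] <- a[j, i] <- 1 / prod(dd[internal])
    }
  }
  a
}

# Moran's I of a trait under a row-normalized weight matrix:
# with W row-normalized, sum(W) = n and I = x' W x / x' x for centered x.
moran_i <- function(x, w_rownorm) {
  x <- x - mean(x)
  sum(x * (w_rownorm %*% x)) / sum(x^2)
}

#' Abouheif's test of phylogenetic signal
#'
#' Tests whether a continuous trait is more similar among closely related
#' tips than expected by chance, using tree topology only (no branch
#' lengths). The statistic C is Moran's I of the standardized trait under
#' the row-normalized Abouheif proximity matrix
#' (\code{\link{abouheif_proximity}}); significance comes from randomly
#' permuting trait values across tips, with the one-sided p-value
#' \code{(1 + #\{C_perm >= C_obs\}) / (n_perm + 1)}. The p-value is
#' invariant to affine transformations of the trait.
#'
#' @param tree An \code{ape} \code{phylo}, a Newick string, or a path to a
#'   Newick file.
#' @param trait Numeric vector named by tip label (order-free); must not
#'   be constant.
#' @param n_perm Number of permutations, at least 99 (default 999).
#' @param seed Seed for the permutations (mandatory for reproducibility).
#' @return Object of class \code{abouheif}: \code{c_stat}, \code{p},
#'   \code{n_perm}, \code{seed}, \code{c_perm} (the null draws).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' abouheif(tr, c(A = 1, B = 1, C = -1, D = -1), n_perm = 999)
#' @export
abouheif <- function(tree, trait, n_perm = 999, seed = 1L) {
  tree <- as_phylo(tree)
  if (n_perm < 99) stop("n_perm must be >= 99")
  tips <- tree$tip.label
  if (is.null(names(trait))) {
    if (length(trait) != length(tips))
      stop("trait length does not match number of tips")
    names(trait) <- tips
  }
  if (!setequal(names(trait), tips))
    stop("trait names do not match tip labels")
  x <- trait[tips]
  if (sd(x) == 0) stop("constant trait: standardization undefined")
  a <- abouheif_proximity(tree)
  w <- a / rowSums(a)
  xs <- (x - mean(x)) / sd(x)
  c_obs <- moran_i(xs, w)
  c_perm <- with_seed(seed, function()
    vapply(seq_len(n_perm),
           function(k) moran_i(xs[sample.int(length(xs))], w),
           numeric(1)))
  p <- (1 + sum(c_perm >= c_obs)) / (n_perm + 1)
  structure(list(c_stat = unname(c_obs), p = p, n_perm = n_perm,
                 seed = seed, c_perm = c_perm),
            class = "abouheif")
}

#' @export
print.abouheif <- function(x, ...) {
  cat(sprintf("Abouheif's test (topology-only): C = %.4f, p = %.4g (%d permutations)\n",
              x$c_stat, x$p, x$n_perm))
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a Newick string or a file path")
}
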