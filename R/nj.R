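## Neighbor-Joining phylogeny from the divergence matrix, with
## site-bootstrap support. The agglomeration itself is the standard
## Saitou-Nei algorithm as implemented in ape; this module supplies the
## distance construction from polarized sites, negative-branch handling
## and the bootstrap over sites.

#' Neighbor-Joining tree from a divergence matrix
#'
#' @param dm a [divergence_matrix()] result or a symmetric numeric matrix
#'   with taxa as dimnames. Off-diagonal entries are used as distances
#'   (diagonal heterozygosities are ignored). Non-symmetric or
#'   negative-distance input is rejected.
#' @return an `ape::phylo` tree. Negative NJ branch lengths are clamped
#'   to zero with the deficit moved to the adjacent branch (standard
#'   practice); the number of clamped branches is attached as attribute
#'   `n_clamped`.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "div_matrix")) dm$normalized else dm
  if (!is.matrix(d) || nrow(d) != ncol(d) ||
      !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("nj_tree needs a symmetric square matrix")
  if (any(d[upper.tri(d)] < 0)) stop("negative distances are not allowed")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  diag(d) <- 0
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  n_clamped <- sum(neg)
  if (n_clamped) {
    ## move each deficit onto the adjacent branch (sister edge at the
    ## same parent node) so path lengths are preserved where possible
    for (e in which(neg)) {
      parent <- tr$edge[e, 1]
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sib))
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
  }
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Does a tree display the expected sister pairs?
#'
#' Checks that `{S, F}` and `{A, M}` are clades of the tree rooted on the
#' mastodon, i.e. the topology `(((S,F),(A,M)),O)`.
#'
#' @param tree an `ape::phylo` with tip labels among the taxon codes.
#' @return logical.
#' @export
topology_matches <- function(tree) {
  if (!("O" %in% tree$tip.label)) return(FALSE)
  rt <- ape::root(tree, outgroup = "O", resolve.root = TRUE)
  ape::is.monophyletic(rt, c("S", "F")) && ape::is.monophyletic(rt, c("A", "M"))
}

#' Site-bootstrap support for the NJ tree
#'
#' Resamples sites with replacement, rebuilds the divergence matrix and
#' the NJ tree for each replicate, and reports for every internal edge of
#' the full-data tree the percentage of replicates displaying the same
#' bipartition.
#'
#' @param table polarized `div_sites` table (complete sites are used).
#' @param replicates number of bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @param taxa taxa to include (default all five).
#' @return the full-data `phylo` with `node.label` holding support
#'   percentages (root label empty); attribute `replicates` records the
#'   replicate count.
#' @export
bootstrap_support <- function(table, replicates = 10000, seed = NULL,
                              taxa = ALL_TAXA) {
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- complete_sites(table)
  k <- length(taxa)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  ## per-site contribution of each unordered taxon pair (sites x pairs)
  contrib <- sapply(seq_len(nrow(pairs)), function(p)
    div_site_contrib(tab, taxa[pairs[p, 1]], taxa[pairs[p, 2]]))
  contrib <- matrix(contrib, nrow = nrow(tab))
  to_matrix <- function(v) {
    d <- matrix(0, k, k, dimnames = list(taxa, taxa))
    d[pairs] <- v; d[pairs[, c(2, 1), drop = FALSE]] <- v
    d
  }
  main <- nj_tree(to_matrix(colSums(contrib)))
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(nrow(tab), replace = TRUE)
    boots[[r]] <- nj_tree(to_matrix(colSums(contrib[idx, , drop = FALSE])))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / replicates, 1))
  main$node.label[1] <- ""  # root of the unrooted representation
  attr(main, "replicates") <- replicates
  main
}
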