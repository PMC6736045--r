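# Distance phylogenetics and clade/subclade assignment.  Tree building is
# delegated to ape (neighbor joining) and phangorn (midpoint rooting); the
# p-distance, bootstrap-support and clade-assignment logic lives here.

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair, computed over mutually ungapped
#' kept columns (for a masked alignment) or over all columns (for a
#' genotype matrix).
#'
#' @param x A [mask_alignment()] result, a character alignment accepted by
#'   `mask_alignment`, or a numeric 0/1 genotype matrix with taxon rownames.
#' @return Symmetric numeric matrix of p-distances with taxon dimnames.
#' @export
p_distance_matrix <- function(x) {
  if (inherits(x, "masked_alignment")) {
    m <- x$matrix[, x$keep, drop = FALSE]
  } else if (is.numeric(x)) {
    m <- x
  } else {
    m <- as_aln_matrix(x)
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      ok <- if (is.character(m)) a != "-" & b != "-" else !is.na(a) & !is.na(b)
      nc <- sum(ok)
      if (nc == 0L) stop("no comparable sites for pair ",
                         rownames(m)[i], "/", rownames(m)[j])
      d[i, j] <- d[j, i] <- sum(a[ok] != b[ok]) / nc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration via [ape::nj()].  Negative branch-length
#' estimates are clamped to zero; the number clamped is attached as the
#' `"n_clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix not symmetric")
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(dm))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Midpoint-root a tree
#'
#' Roots at the midpoint of the longest leaf-to-leaf path
#' (via [phangorn::midpoint()]).
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    stop("tree has no usable branch lengths")
  phangorn::midpoint(tree)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples kept alignment columns (or genotype-matrix columns) with
#' replacement, rebuilds the NJ tree for each replicate and reports, for
#' every internal bipartition of the original tree, the percentage of
#' replicates containing it (stored as `node.label`).
#'
#' @param x Input accepted by [p_distance_matrix()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The original NJ tree with percentage supports in `node.label`.
#' @export
bootstrap_support <- function(x, n_reps = 100L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  cols <- if (inherits(x, "masked_alignment"))
    x$matrix[, x$keep, drop = FALSE] else
      if (is.numeric(x)) x else as_aln_matrix(x)
  if (ncol(cols) < 1L) stop("no kept columns")
  tr <- nj_tree(p_distance_matrix(cols))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    rs <- cols[, sample.int(ncol(cols), replace = TRUE), drop = FALSE]
    reps[[b]] <- nj_tree(p_distance_matrix(rs))
  }
  counts <- ape::prop.clades(tr, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tr$node.label <- round(100 * counts / n_reps, 1)
  tr
}

#' Assign clades and subclades from a rooted tree
#'
#' The two clades are the two children of the deepest split of the rooted
#' tree after excluding taxa flagged as mosaic; within each clade the deepest
#' split defines two subclades.  The clade containing `ref_taxon` is named
#' `REF` (subclades `REF-A`, with `A` holding the reference taxon, and
#' `REF-B`); the other clade `NONREF` (subclades `NONREF-S` for the
#' lower-diversity side and `NONREF-D` for the more diverse side, computed
#' from mean within-subclade distance).  Mosaic taxa are excluded from clade
#' definition but reported with their nearest clade.
#'
#' @param tree Rooted `phylo` covering all taxa.
#' @param dm Distance matrix over the same taxa (used for diversity ranking
#'   and nearest-clade reports).
#' @param ref_taxon Reference taxon (defines the REF side).
#' @param mosaic Character vector of taxa to exclude as mosaics.
#' @return data.frame `type`, `clade`, `subclade`, `mosaic` (logical).
#' @export
assign_clades <- function(tree, dm, ref_taxon, mosaic = character()) {
  stopifnot(ref_taxon %in% tree$tip.label)
  keep <- setdiff(tree$tip.label, mosaic)
  sub <- if (length(mosaic) > 0L) ape::drop.tip(tree, mosaic) else tree
  if (is.null(sub) || ape::Ntip(sub) < 2L) stop("too few non-mosaic taxa")
  split2 <- function(tr) {
    # children of the root bipartition as tip-label sets
    root <- ape::Ntip(tr) + 1L
    kids <- tr$edge[tr$edge[, 1L] == root, 2L]
    lapply(kids, function(k) {
      if (k <= ape::Ntip(tr)) tr$tip.label[k]
      else ape::extract.clade(tr, k)$tip.label
    })
  }
  parts <- split2(sub)
  if (length(parts) < 2L) stop("tree has no internal structure at the root")
  if (length(parts) > 2L)  # unrooted-style basal trifurcation
    parts <- c(parts[1L], list(unlist(parts[-1L])))
  is_ref <- vapply(parts, function(p) ref_taxon %in% p, logical(1L))
  if (!any(is_ref)) stop("ref_taxon lost from tree")
  ref_set <- parts[[which(is_ref)[1L]]]
  nonref_set <- unlist(parts[!is_ref])

  mean_within <- function(set) {
    if (length(set) < 2L) return(0)
    mean(dm[set, set][upper.tri(matrix(0, length(set), length(set)))])
  }
  subclades_of <- function(set, clade) {
    out <- setNames(rep(paste0(clade, "-A"), length(set)), set)
    if (length(set) < 2L) return(out)
    tr <- ape::keep.tip(tree, set)
    p <- split2(tr)
    if (length(p) > 2L) p <- c(p[1L], list(unlist(p[-1L])))
    if (clade == "REF") {
      a_first <- ref_taxon %in% p[[1L]]
      labs <- if (a_first) c("REF-A", "REF-B") else c("REF-B", "REF-A")
    } else {
      div <- vapply(p, mean_within, numeric(1L))
      labs <- if (div[1L] <= div[2L]) c("NONREF-S", "NONREF-D")
        else c("NONREF-D", "NONREF-S")
    }
    out[p[[1L]]] <- labs[1L]
    out[p[[2L]]] <- labs[2L]
    out
  }
  sc <- c(subclades_of(ref_set, "REF"), subclades_of(nonref_set, "NONREF"))
  res <- data.frame(type = keep,
                    clade = ifelse(keep %in% ref_set, "REF", "NONREF"),
                    subclade = unname(sc[keep]), mosaic = FALSE,
                    stringsAsFactors = FALSE)
  if (length(mosaic) > 0L) {
    near <- vapply(mosaic, function(tx) {
      dref <- mean(dm[tx, ref_set]); dnon <- mean(dm[tx, nonref_set])
      if (dref <= dnon) "REF" else "NONREF"
    }, character(1L))
    res <- rbind(res, data.frame(type = mosaic, clade = near,
                                 subclade = "none", mosaic = TRUE,
                                 stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}
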