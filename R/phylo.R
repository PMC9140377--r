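# Distance estimation, neighbor-joining, rooting and path-length queries.
# Trees are ape "phylo" objects throughout; branch lengths are in
# substitutions/site.

#' Pairwise model-corrected distance between two aligned sequences
#'
#' Columns with a gap or ambiguity character in either sequence are excluded
#' pairwise before the distance is computed.
#'
#' @param a,b Aligned nucleotide strings of equal length.
#' @param model `"p"` (raw mismatch fraction), `"jc"` (Jukes-Cantor) or
#'   `"k80"` (Kimura two-parameter, the default).
#' @return Divergence in substitutions/site.
#' @section Errors:
#' Saturated comparisons (p >= 3/4 under JC, or a non-positive log argument
#' under K80) and comparisons with zero comparable columns raise an error.
#' @examples
#' ml_distance("ACGTACGT", "ACGTACGA", model = "p")
#' @export
ml_distance <- function(a, b, model = c("k80", "jc", "p")) {
  model <- match.arg(model)
  va <- .base_to_int(strsplit(toupper(a), "")[[1]])
  vb <- .base_to_int(strsplit(toupper(b), "")[[1]])
  if (length(va) != length(vb)) stop("sequences must have equal length")
  ok <- !is.na(va) & !is.na(vb)
  n <- sum(ok)
  if (n == 0L) stop("no comparable (gap- and ambiguity-free) columns")
  .dist_from_counts(n, sum(va[ok] != vb[ok]),
                    sum(va[ok] == .TS_PARTNER[vb[ok]]), model)
}

# distance from column tallies; nts counts transitions (subset of mismatches)
.dist_from_counts <- function(n, ndiff, nts, model) {
  p <- ndiff / n
  if (model == "p") return(p)
  if (model == "jc") {
    if (p >= 0.75) stop("saturation: p-distance ", signif(p, 4),
                        " >= 0.75, Jukes-Cantor correction undefined")
    return(-0.75 * log(1 - 4 * p / 3))
  }
  P <- nts / n
  Q <- (ndiff - nts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturation: K80 log argument non-positive (P=", signif(P, 4),
         ", Q=", signif(Q, 4), ")")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All pairwise model-corrected distances for an alignment
#'
#' @param aln A [coding_alignment()] (or named character vector of aligned
#'   sequences).
#' @param model Distance model, see [ml_distance()].
#' @param partition When `TRUE` and `aln` carries a coding map, distances are
#'   estimated within each site class (codon positions 1-3, non-coding) and
#'   combined by site-count weighting, which keeps them additive under
#'   class-specific rates; `FALSE` (default) pools all columns.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, model = "k80", partition = FALSE) {
  seqs <- if (inherits(aln, "coding_alignment")) aln$seqs else aln
  n <- length(seqs)
  cls <- if (partition && inherits(aln, "coding_alignment"))
    .site_classes(aln$coding_map, aln$length) else NULL
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- if (is.null(cls)) {
        ml_distance(seqs[[i]], seqs[[j]], model)
      } else {
        .ml_distance_partitioned(seqs[[i]], seqs[[j]], model, cls)
      }
    }
  }
  D
}

.ml_distance_partitioned <- function(a, b, model, cls) {
  va <- .base_to_int(strsplit(toupper(a), "")[[1]])
  vb <- .base_to_int(strsplit(toupper(b), "")[[1]])
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("no comparable (gap- and ambiguity-free) columns")
  dsum <- 0; ntot <- 0
  for (ci in unique(cls)) {
    sel <- ok & cls == ci
    n <- sum(sel)
    if (n == 0L) next
    d <- tryCatch(
      .dist_from_counts(n, sum(va[sel] != vb[sel]),
                        sum(va[sel] == .TS_PARTNER[vb[sel]] &
                              va[sel] != vb[sel]), model),
      error = function(e) NULL)
    if (is.null(d)) {
      # a saturated class: fall back to the pooled-columns estimate
      return(.dist_from_counts(sum(ok), sum(va[ok] != vb[ok]),
                               sum(va[ok] == .TS_PARTNER[vb[ok]] &
                                     va[ok] != vb[ok]), model))
    }
    dsum <- dsum + n * d
    ntot <- ntot + n
  }
  dsum / ntot
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via [ape::nj()]); negative branch lengths are
#' clamped to zero with the deficit shifted onto the sister branch, preserving
#' the sum over each cherry.
#'
#' @param D Symmetric distance matrix (zero diagonal, >= 3 taxa).
#' @param labels Taxon labels (defaults to `rownames(D)`).
#' @return An unrooted ape `phylo`.
#' @export
build_nj_tree <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (anyNA(D) || any(!is.finite(D))) stop("distance matrix contains NA/NaN")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  tr <- ape::nj(D)
  # shift negative-length deficits onto the sister branch, then clamp
  for (pass in 1:3) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent)
      sib <- setdiff(sib, e)
      if (length(sib)) {
        tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
      }
      tr$edge.length[e] <- 0
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree on an outgroup's pendant branch
#'
#' The root is placed at the midpoint of the outgroup's pendant branch, so
#' all pairwise path lengths are preserved.
#'
#' @param t An ape `phylo`.
#' @param outgroup Tip label.
#' @return A rooted ape `phylo`.
#' @export
root_with_outgroup <- function(t, outgroup) {
  tip <- match(outgroup, t$tip.label)
  if (is.na(tip)) stop("outgroup '", outgroup, "' is not a tip of the tree")
  pend <- which(t$edge[, 2] == tip)
  phytools::reroot(t, tip, position = t$edge.length[pend] / 2)
}

.node_id <- function(t, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > ape::Ntip(t) + t$Nnode) {
      stop("node id ", node, " out of range")
    }
    return(node)
  }
  i <- match(node, t$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(t$node.label)) {
    j <- match(node, t$node.label)
    if (!is.na(j)) return(ape::Ntip(t) + j)
  }
  stop("unknown node '", node, "'")
}

#' Path length between two nodes
#'
#' Sum of branch lengths along the unique path connecting two nodes (tips or
#' internal nodes, given as labels or ids).
#'
#' @param t An ape `phylo` with branch lengths.
#' @param a,b Node labels or numeric ids.
#' @return Path length in substitutions/site; 0 when `a == b`.
#' @export
path_length <- function(t, a, b) {
  ai <- .node_id(t, a)
  bi <- .node_id(t, b)
  if (ai == bi) return(0)
  ape::dist.nodes(t)[ai, bi]
}

# tip sets below each edge's child (list indexed by edge row)
.edge_tip_sets <- function(t) {
  ntip <- ape::Ntip(t)
  below <- vector("list", ntip + t$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- t$tip.label[i]
  for (e in ape::postorder(t)) {
    p <- t$edge[e, 1]; ch <- t$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(t$edge)), function(e) below[[t$edge[e, 2]]])
}

#' Find the edge subtending a clade
#'
#' Returns the index (row of `t$edge`) of the branch separating `leaves` from
#' all remaining taxa. Works on rooted and unrooted trees; errors if no branch
#' induces that bipartition (i.e. the set is not monophyletic on the tree).
#'
#' @param t An ape `phylo`.
#' @param leaves Character vector of tip labels.
#' @return Integer edge index.
#' @export
edge_for_clade <- function(t, leaves) {
  if (!all(leaves %in% t$tip.label)) {
    stop("unknown tips: ", paste(setdiff(leaves, t$tip.label), collapse = ", "))
  }
  sets <- .edge_tip_sets(t)
  all_tips <- t$tip.label
  for (e in seq_along(sets)) {
    if (setequal(sets[[e]], leaves) ||
        setequal(sets[[e]], setdiff(all_tips, leaves))) {
      return(e)
    }
  }
  stop("no branch separates {", paste(leaves, collapse = ", "),
       "} from the remaining taxa (clade not monophyletic on this tree)")
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that fail
#' loudly on unparsable input.
#'
#' @param path File path.
#' @return `read_newick`: an ape `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("unparsable Newick in '", path, "'")
  tr
}

#' @param t An ape `phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t, file = path)
  invisible(path)
}
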