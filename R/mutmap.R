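# Ancestral reconstruction (Fitch parsimony with deterministic tie-breaking),
# assignment of substitutions to branches, synonymous/non-synonymous
# classification, and the stem-vs-branches contrast test.

.FITCH_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, gap = 16L)

.char_to_mask <- function(ch) {
  out <- integer(length(ch))
  out[ch == "A"] <- 1L; out[ch == "C"] <- 2L
  out[ch == "G"] <- 4L; out[ch == "T"] <- 8L
  out[ch == "-" | ch == "."] <- 16L
  out[out == 0L] <- 15L  # ambiguity codes treated as missing (any nucleotide)
  out
}

# deterministic state choice from a mask: a gap never overrides a nucleotide,
# nucleotides in alphabetical order
.mask_pick <- function(mask) {
  if (bitwAnd(mask, 1L)) return("A")
  if (bitwAnd(mask, 2L)) return("C")
  if (bitwAnd(mask, 4L)) return("G")
  if (bitwAnd(mask, 8L)) return("T")
  "-"
}

.state_bit <- function(ch) {
  switch(ch, A = 1L, C = 2L, G = 4L, T = 8L, `-` = 16L)
}

# Fitch up/down pass for one site pattern. children: list indexed by node id;
# node_order_up: internal nodes, children before parents; node_order_down:
# parents before children (root first). Returns list(states, score).
.fitch_pattern <- function(leaf_mask, children, node_order_up,
                           node_order_down, root, n_nodes, parent_of) {
  mask <- integer(n_nodes)
  mask[seq_along(leaf_mask)] <- leaf_mask
  score <- 0L
  for (nd in node_order_up) {
    kids <- children[[nd]]
    cur <- mask[kids[1]]
    for (k in kids[-1]) {
      tmp <- bitwAnd(cur, mask[k])
      if (tmp != 0L) cur <- tmp
      else {
        cur <- bitwOr(cur, mask[k])
        score <- score + 1L
      }
    }
    mask[nd] <- cur
  }
  states <- character(n_nodes)
  for (nd in node_order_down) {
    if (nd == root) {
      states[nd] <- .mask_pick(mask[nd])
    } else {
      pb <- .state_bit(states[parent_of[nd]])
      # prefer the parent's state when compatible, but never let a gap
      # override an available nucleotide
      if (bitwAnd(mask[nd], pb) != 0L &&
          !(pb == 16L && bitwAnd(mask[nd], 15L) != 0L)) {
        states[nd] <- states[parent_of[nd]]
      } else {
        states[nd] <- .mask_pick(mask[nd])
      }
    }
  }
  list(states = states, score = score)
}

#' Reconstruct ancestral sequences by Fitch parsimony
#'
#' Column-wise Fitch parsimony on a rooted tree, with gaps carried as a fifth
#' state. Ties on the final (down) pass are broken deterministically: the
#' parent's state is preferred when compatible, otherwise the alphabetically
#' first nucleotide; a gap is assigned only when no nucleotide is compatible.
#' Ambiguity codes in leaves are treated as missing.
#'
#' @param t Rooted ape `phylo`; every tip label must have a sequence in `aln`.
#' @param aln A [coding_alignment()].
#' @return An object of class `ancestral_reconstruction`: list with `tree`
#'   (the input tree, internal nodes labelled), `sequences` (named character
#'   vector over all nodes, tips included), `score` (total parsimony steps)
#'   and `alignment`.
#' @export
reconstruct_ancestors <- function(t, aln) {
  if (!ape::is.rooted(t)) stop("tree must be rooted (see root_with_outgroup)")
  missing <- setdiff(t$tip.label, names(aln$seqs))
  if (length(missing)) {
    stop("no sequence for leaf: ", paste(missing, collapse = ", "))
  }
  ntip <- ape::Ntip(t)
  n_nodes <- ntip + t$Nnode
  if (is.null(t$node.label) || any(t$node.label == "") ||
      anyDuplicated(c(t$tip.label, t$node.label))) {
    t$node.label <- paste0("nd", seq_len(t$Nnode))
  }
  labels <- c(t$tip.label, t$node.label)

  children <- vector("list", n_nodes)
  parent_of <- integer(n_nodes)
  for (e in seq_len(nrow(t$edge))) {
    p <- t$edge[e, 1]; ch <- t$edge[e, 2]
    children[[p]] <- c(children[[p]], ch)
    parent_of[ch] <- p
  }
  root <- ntip + 1L
  po_edges <- ape::postorder(t)
  node_order_up <- unique(t$edge[po_edges, 1])
  node_order_down <- unique(c(root, t$edge[rev(po_edges), 2]))
  internal_down <- node_order_down

  M <- .aln_matrix(aln)[, t$tip.label, drop = FALSE]
  pat <- do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
  uniq <- unique(pat)
  col_of <- match(pat, uniq)

  states_by_pat <- matrix("", nrow = n_nodes, ncol = length(uniq))
  score_by_pat <- integer(length(uniq))
  for (u in seq_along(uniq)) {
    leaf_chars <- strsplit(uniq[u], "")[[1]]
    fm <- .fitch_pattern(.char_to_mask(leaf_chars), children, node_order_up,
                         internal_down, root, n_nodes, parent_of)
    states_by_pat[, u] <- fm$states
    score_by_pat[u] <- fm$score
  }
  seq_mat <- states_by_pat[, col_of, drop = FALSE]  # n_nodes x L
  sequences <- apply(seq_mat, 1L, paste, collapse = "")
  names(sequences) <- labels
  structure(list(tree = t, sequences = sequences,
                 score = sum(score_by_pat[col_of]),
                 alignment = aln),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("ancestral_reconstruction:", ape::Ntip(x$tree), "tips,",
      x$tree$Nnode, "internal nodes\n")
  cat("  parsimony score:", x$score, "steps over",
      x$alignment$length, "columns\n")
  invisible(x)
}

#' Classify a single substitution
#'
#' A coding change is synonymous iff the encoded amino acid (stops included
#' as a state) is unchanged under the genetic code; changes outside coding
#' regions are `non_coding`.
#'
#' @param column Alignment column (metadata, 1-based).
#' @param from_base,to_base Single bases.
#' @param codon_context `NULL` for a non-coding column, else a list with
#'   `codon` (the full 3-base codon containing the column, with `from_base`
#'   at the focal position) and `codon_pos` (1-3).
#' @param code_id Genetic code id.
#' @return `"synonymous"`, `"non_synonymous"` or `"non_coding"`.
#' @examples
#' classify_mutation(3, "T", "C", list(codon = "GCT", codon_pos = 3))  # Ala->Ala
#' @export
classify_mutation <- function(column, from_base, to_base,
                              codon_context = NULL, code_id = "2") {
  if (is.null(codon_context)) return("non_coding")
  codon <- toupper(codon_context$codon)
  pos <- codon_context$codon_pos
  if (is.null(pos) || !pos %in% 1:3 || nchar(codon) != 3L) {
    stop("codon_context needs a 3-base codon and codon_pos in 1..3")
  }
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("column ", column, " is coding but its reading frame is ",
         "unresolvable (codon '", codon, "' contains non-ACGT characters)")
  }
  from_base <- toupper(from_base); to_base <- toupper(to_base)
  if (substr(codon, pos, pos) != from_base) {
    stop("codon_context codon does not carry from_base at codon_pos")
  }
  mutated <- codon
  substr(mutated, pos, pos) <- to_base
  if (!grepl("^[ACGT]$", to_base)) {
    stop("column ", column, " is coding but its reading frame is ",
         "unresolvable (derived base '", to_base, "' is not a nucleotide)")
  }
  code <- get_genetic_code(code_id)
  if (code[[codon]] == code[[mutated]]) "synonymous" else "non_synonymous"
}

#' Assign reconstructed substitutions to branches
#'
#' For every branch, each column at which the parent and child states differ
#' (both being nucleotides; gap-involving differences are not substitutions
#' and are skipped) yields one mutation record, classified against the
#' parent's codon background. Several hits within one codon on one branch are
#' classified in column order against the progressively updated codon; a
#' coding column whose codon context is unresolvable (contains a gap) gets an
#' `NA` class.
#'
#' @param rec An `ancestral_reconstruction` from [reconstruct_ancestors()].
#' @return A data frame of class `branch_mutations` with columns `branch`
#'   (child-node label of the branch), `column`, `from`, `to`, `class`; the
#'   tree is attached as attribute `tree`.
#' @export
assign_branch_mutations <- function(rec) {
  stopifnot(inherits(rec, "ancestral_reconstruction"))
  t <- rec$tree
  aln <- rec$alignment
  ann <- .site_codon_map(aln$coding_map, aln$length)
  labels <- c(t$tip.label, t$node.label)
  out <- vector("list", nrow(t$edge))
  for (e in seq_len(nrow(t$edge))) {
    p <- t$edge[e, 1]; ch <- t$edge[e, 2]
    ps <- strsplit(rec$sequences[[labels[p]]], "")[[1]]
    cs <- strsplit(rec$sequences[[labels[ch]]], "")[[1]]
    diffs <- which(ps != cs & ps %in% .BASES & cs %in% .BASES)
    if (!length(diffs)) next
    work <- ps
    recs <- data.frame(branch = labels[ch], column = diffs,
                       from = ps[diffs], to = cs[diffs],
                       class = NA_character_, stringsAsFactors = FALSE)
    for (k in seq_along(diffs)) {
      col <- diffs[k]
      if (is.na(ann$codon_start[col])) {
        recs$class[k] <- "non_coding"
      } else {
        start <- ann$codon_start[col]
        codon <- paste(work[start:(start + 2L)], collapse = "")
        recs$class[k] <- tryCatch(
          classify_mutation(col, work[col], cs[col],
                            list(codon = codon,
                                 codon_pos = ann$codon_pos[col]),
                            code_id = ann$code[col]),
          error = function(err) NA_character_)
      }
      work[col] <- cs[col]
    }
    out[[e]] <- recs
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(branch = character(0), column = integer(0),
               from = character(0), to = character(0), class = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "tree") <- t
  class(res) <- c("branch_mutations", "data.frame")
  res
}

#' Export a branch mutation set as TSV
#'
#' @param bms A `branch_mutations` data frame.
#' @param path Output path.
#' @export
write_mutations_tsv <- function(bms, path) {
  utils::write.table(as.data.frame(bms)[, c("branch", "column", "from", "to",
                                            "class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stem vs pseudogene-branch synonymous contrast
#'
#' Tests whether the pseudogene stem carries a higher proportion of
#' synonymous changes than the post-insertion branches (the signature that
#' stem mutations accumulated in a functional mitochondrial genome).
#' Non-coding records are excluded; the test is a one-sided Fisher exact test
#' on the 2x2 table (synonymous vs non-synonymous) x (stem vs others) with
#' alternative "stem more synonymous".
#'
#' @param stem,others `branch_mutations` slices (data frames with a `class`
#'   column); both must contain at least one coding-region mutation.
#' @return An object of class `stem_contrast`: list with
#'   `syn_fraction_stem`, `syn_fraction_others`, `p_value`, `table`,
#'   `degenerate` (TRUE when a margin of the table is zero, in which case
#'   `p_value` is 1 by convention).
#' @export
stem_contrast_test <- function(stem, others) {
  count <- function(x, what) {
    sum(x$class == what, na.rm = TRUE)
  }
  tab <- rbind(stem = c(synonymous = count(stem, "synonymous"),
                        non_synonymous = count(stem, "non_synonymous")),
               others = c(synonymous = count(others, "synonymous"),
                          non_synonymous = count(others, "non_synonymous")))
  if (sum(tab["stem", ]) == 0L) {
    stop("stem slice contains no coding-region mutations; the contrast test ",
         "needs protein-coding homology (rRNA-homologous NUMTs are not apt ",
         "for this analysis)")
  }
  if (sum(tab["others", ]) == 0L) {
    stop("comparison slice contains no coding-region mutations; supply the ",
         "post-insertion pseudogene branches")
  }
  degenerate <- any(colSums(tab) == 0L)
  p <- if (degenerate) 1 else
    stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(
    syn_fraction_stem = tab["stem", 1] / sum(tab["stem", ]),
    syn_fraction_others = tab["others", 1] / sum(tab["others", ]),
    p_value = p, table = tab, degenerate = degenerate),
    class = "stem_contrast")
}

#' @export
print.stem_contrast <- function(x, ...) {
  cat("Stem vs branches synonymous-fraction contrast (one-sided Fisher)\n")
  cat(sprintf("  stem:     %d syn / %d non-syn  (%.1f%% synonymous)\n",
              x$table[1, 1], x$table[1, 2], 100 * x$syn_fraction_stem))
  cat(sprintf("  branches: %d syn / %d non-syn  (%.1f%% synonymous)\n",
              x$table[2, 1], x$table[2, 2], 100 * x$syn_fraction_others))
  cat("  p =", format.pval(x$p_value, digits = 3),
      if (x$degenerate) " (degenerate table, p = 1 by convention)" else "",
      "\n")
  invisible(x)
}
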