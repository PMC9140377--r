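# Joint genealogy construction and whole-scenario simulation.
#
# The genealogy is held as a flat node table: for each node an id, a label,
# an age (Myr before present) and the id of its parent (NA at the root),
# plus the phase ("functional" mtDNA / "pseudogene" nuclear) of the edge
# leading to the parent. Ages strictly decrease towards the tips, so
# processing nodes in order of decreasing age evolves parents before
# children deterministically.

.tab_new <- function() {
  list(label = character(0), age = numeric(0), parent = integer(0),
       phase = character(0))
}

.tab_add <- function(tab, label, age, parent = NA_integer_,
                     phase = NA_character_) {
  tab$label <- c(tab$label, label)
  tab$age <- c(tab$age, age)
  tab$parent <- c(tab$parent, parent)
  tab$phase <- c(tab$phase, phase)
  tab
}

.tab_n <- function(tab) length(tab$label)

.tab_root <- function(tab) which(is.na(tab$parent))

.tab_children <- function(tab, id) which(!is.na(tab$parent) & tab$parent == id)

# species phylo -> node table (all edges functional); tips keep their labels,
# internal nodes get "mt_<k>" labels
.tab_from_phylo <- function(phy) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(ntip)]) - depth
  age[abs(age) < 1e-9] <- 0
  labels <- c(phy$tip.label, paste0("mt_", seq_len(phy$Nnode)))
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  list(label = labels, age = age, parent = parent,
       phase = ifelse(is.na(parent), NA_character_, "functional"))
}

# ancestor ids of `id` (excluding id), root last
.tab_ancestors <- function(tab, id) {
  out <- integer(0)
  p <- tab$parent[id]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tab$parent[p]
  }
  out
}

.tab_mrca <- function(tab, labels) {
  ids <- match(labels, tab$label)
  if (anyNA(ids)) stop("unknown taxa: ",
                       paste(labels[is.na(ids)], collapse = ", "))
  if (length(ids) == 1L) return(ids)
  anc <- c(ids[1], .tab_ancestors(tab, ids[1]))
  for (id in ids[-1]) {
    keep <- c(id, .tab_ancestors(tab, id))
    anc <- anc[anc %in% keep]
  }
  anc[1]
}

# Insert a degree-2 node of the given age on the path root -> below_id.
# If age exceeds the current root age a new root is created above the old one.
.tab_insert_on_path <- function(tab, below_id, age, label,
                                phase = "functional") {
  path <- c(below_id, .tab_ancestors(tab, below_id))  # below -> root
  root <- path[length(path)]
  if (age >= tab$age[root]) {
    if (abs(age - tab$age[root]) < 1e-12) {
      stop("event time ", age, " coincides with an existing node age")
    }
    tab <- .tab_add(tab, label, age)
    new_id <- .tab_n(tab)
    tab$parent[root] <- new_id
    tab$phase[root] <- phase
    return(list(tab = tab, id = new_id))
  }
  for (c_id in rev(path)[-1]) {  # walk down from just below the root
    p_id <- tab$parent[c_id]
    if (tab$age[p_id] > age && age > tab$age[c_id]) {
      tab <- .tab_add(tab, label, age, parent = p_id, phase = tab$phase[c_id])
      new_id <- .tab_n(tab)
      tab$parent[c_id] <- new_id
      return(list(tab = tab, id = new_id))
    }
    if (abs(age - tab$age[c_id]) < 1e-12 || abs(age - tab$age[p_id]) < 1e-12) {
      stop("event time ", age, " coincides with an existing node age")
    }
  }
  stop("no edge on the path spans age ", age)
}

# copy the species subtree rooted at `src_id` of `src` into `tab`, attached
# under `attach_id`; tips are renamed via `rename`, edges get `phase`
.tab_copy_subtree <- function(tab, src, src_id, attach_id, phase, rename) {
  recurse <- function(tab, sid, parent_new) {
    is_tip <- length(.tab_children(src, sid)) == 0L
    lab <- if (is_tip) rename(src$label[sid]) else
      paste0("numt_", sub("^mt_", "", src$label[sid]))
    tab <- .tab_add(tab, lab, src$age[sid], parent = parent_new, phase = phase)
    me <- .tab_n(tab)
    for (ch in .tab_children(src, sid)) tab <- recurse(tab, ch, me)
    tab
  }
  recurse(tab, src_id, attach_id)
}

# remove the subtree rooted at id (id included); returns compacted table
.tab_drop_subtree <- function(tab, id) {
  drop <- id
  frontier <- id
  while (length(frontier)) {
    kids <- which(!is.na(tab$parent) & tab$parent %in% frontier)
    drop <- c(drop, kids)
    frontier <- kids
  }
  keep <- setdiff(seq_len(.tab_n(tab)), drop)
  remap <- match(seq_len(.tab_n(tab)), keep)
  list(label = tab$label[keep], age = tab$age[keep],
       parent = remap[tab$parent[keep]], phase = tab$phase[keep])
}

# merge unary nodes (single child, has parent) whose two incident edges share
# a phase; other unary nodes are kept (phase change points)
.tab_suppress_unary <- function(tab, keep_labels = character(0)) {
  repeat {
    done <- TRUE
    for (id in seq_len(.tab_n(tab))) {
      kids <- .tab_children(tab, id)
      if (length(kids) == 1L && !is.na(tab$parent[id]) &&
          !(tab$label[id] %in% keep_labels) &&
          identical(tab$phase[kids], tab$phase[id])) {
        tab$parent[kids] <- tab$parent[id]
        tab <- .tab_drop_node(tab, id)
        done <- FALSE
        break
      }
      # unary root: drop it, child becomes root
      if (length(kids) == 1L && is.na(tab$parent[id]) &&
          !(tab$label[id] %in% keep_labels)) {
        tab$parent[kids] <- NA_integer_
        tab$phase[kids] <- NA_character_
        tab <- .tab_drop_node(tab, id)
        done <- FALSE
        break
      }
    }
    if (done) return(tab)
  }
}

.tab_drop_node <- function(tab, id) {
  keep <- setdiff(seq_len(.tab_n(tab)), id)
  remap <- match(seq_len(.tab_n(tab)), keep)
  list(label = tab$label[keep], age = tab$age[keep],
       parent = remap[tab$parent[keep]], phase = tab$phase[keep])
}

# --- scenario genealogy -----------------------------------------------------

.genealogy <- function(spec) {
  tab <- .tab_from_phylo(spec$phylo)
  events <- data.frame(time = numeric(0), event = character(0))
  log_ev <- function(time, ev) rbind(events, data.frame(time = time, event = ev))

  m_id <- .tab_mrca(tab, spec$recipient_taxa)
  a_m <- tab$age[m_id]
  stem_labels <- character(0)

  if (spec$mode == "numt_transfer") {
    if (spec$transfer_time < a_m) {
      stop("event ordering violated: transfer_time (", spec$transfer_time,
           ") predates the radiation of the recipient clade (", a_m,
           " Myr), so not all recipients could inherit the NUMT")
    }
    ins <- .tab_insert_on_path(tab, m_id, spec$ghost_split_time, "ghost_split")
    tab <- ins$tab; g_id <- ins$id
    tab <- .tab_add(tab, "numt_insertion", spec$insertion_time,
                    parent = g_id, phase = "functional")
    i_id <- .tab_n(tab)
    tab <- .tab_add(tab, "numt_mrca", a_m, parent = i_id, phase = "pseudogene")
    c_id <- .tab_n(tab)
    for (ch in .tab_children(tab, m_id)) {
      tab <- .tab_copy_subtree(tab, tab, ch, c_id, "pseudogene",
                               function(x) paste0("NUMT_", x))
    }
    stem_labels <- c("numt_insertion", "numt_mrca")
    events <- log_ev(spec$ghost_split_time, "ghost mtDNA lineage diverges")
    events <- log_ev(spec$insertion_time, "NUMT insertion on ghost lineage")
    events <- log_ev(spec$transfer_time, "NUMT transferred by hybridization")
  } else if (spec$mode == "mtdna_introgression") {
    if (spec$insertion_time < a_m) {
      stop("event ordering violated: insertion_time (", spec$insertion_time,
           ") predates the radiation of the recipient clade (", a_m, " Myr)")
    }
    mi_id <- .tab_mrca(tab, spec$introgressed_taxa)
    a_mi <- tab$age[mi_id]
    if (spec$transfer_time < a_mi) {
      stop("event ordering violated: transfer_time (", spec$transfer_time,
           ") predates the radiation of the introgressed clade (", a_mi,
           " Myr)")
    }
    ins <- .tab_insert_on_path(tab, m_id, spec$ghost_split_time, "ghost_split")
    tab <- ins$tab; g_id <- ins$id
    ins <- .tab_insert_on_path(tab, m_id, spec$insertion_time,
                               "numt_insertion")
    tab <- ins$tab; i_id <- ins$id
    # NUMT is native to the acceptor lineage from the insertion point on
    tab <- .tab_add(tab, "numt_mrca", a_m, parent = i_id,
                    phase = "pseudogene")
    c_id <- .tab_n(tab)
    for (ch in .tab_children(tab, m_id)) {
      tab <- .tab_copy_subtree(tab, tab, ch, c_id, "pseudogene",
                               function(x) paste0("NUMT_", x))
    }
    # ghost mtDNA replaces the introgressed clade's mtDNA: re-attach the
    # introgressed MRCA under the ghost lineage, drop the old connection
    mi_id <- .tab_mrca(tab, spec$introgressed_taxa)  # ids shifted by inserts
    tab$parent[mi_id] <- g_id
    tab$phase[mi_id] <- "functional"
    stem_labels <- c("numt_insertion", "numt_mrca")
    events <- log_ev(spec$ghost_split_time,
                     "ghost (donor) mtDNA lineage diverges")
    events <- log_ev(spec$insertion_time,
                     "NUMT insertion from the acceptor's old mtDNA")
    events <- log_ev(spec$transfer_time,
                     "ghost mtDNA introgresses, replacing the old mtDNA")
  } else {  # null_no_ghost
    if (spec$insertion_time < a_m) {
      stop("event ordering violated: insertion_time (", spec$insertion_time,
           ") predates the radiation of the recipient clade (", a_m, " Myr)")
    }
    root_age <- max(tab$age)
    if (spec$insertion_time >= root_age && !is.null(spec$outgroup)) {
      stop("insertion_time must fall below the species-tree root (",
           root_age, " Myr)")
    }
    ins <- .tab_insert_on_path(tab, m_id, spec$insertion_time,
                               "numt_insertion")
    tab <- ins$tab; i_id <- ins$id
    tab <- .tab_add(tab, "numt_mrca", a_m, parent = i_id,
                    phase = "pseudogene")
    c_id <- .tab_n(tab)
    for (ch in .tab_children(tab, m_id)) {
      tab <- .tab_copy_subtree(tab, tab, ch, c_id, "pseudogene",
                               function(x) paste0("NUMT_", x))
    }
    stem_labels <- "numt_mrca"
    events <- log_ev(spec$insertion_time,
                     "NUMT insertion from the native mtDNA")
  }
  # prune species-tree nodes that lost all sampled descendants and merge
  # pass-through nodes (keeping event markers)
  tab <- .tab_suppress_unary(
    tab, keep_labels = c("ghost_split", "numt_insertion", "numt_mrca"))
  events <- events[order(-events$time), , drop = FALSE]
  rownames(events) <- NULL
  list(tab = tab, events = events, stem_labels = stem_labels)
}

# newick text from a node table with per-child edge lengths (named by child
# label); unary chains are collapsed by summing lengths
.tab_newick <- function(tab, len_by_child) {
  recurse <- function(id, extra) {
    kids <- .tab_children(tab, id)
    len <- extra + if (is.na(tab$parent[id])) 0 else
      len_by_child[[tab$label[id]]]
    if (length(kids) == 0L) {
      return(paste0(tab$label[id], ":", format(len, digits = 12)))
    }
    if (length(kids) == 1L) return(recurse(kids, len))
    inner <- paste(vapply(kids, recurse, character(1), extra = 0),
                   collapse = ",")
    paste0("(", inner, ")", tab$label[id], ":", format(len, digits = 12))
  }
  root <- .tab_root(tab)
  kids <- .tab_children(tab, root)
  inner <- paste(vapply(kids, recurse, character(1), extra = 0),
                 collapse = ",")
  paste0("(", inner, ")", tab$label[root], ";")
}

#' Simulate a complete NUMT scenario
#'
#' Runs the two-phase simulator along the joint genealogy implied by a
#' [scenario_spec()]: the mtDNA evolves under purifying selection along the
#' species tree, the ghost lineage diverges and gives rise to the pseudogene,
#' and the NUMT reaches the extant recipients by hybrid transfer or remains as
#' the relic of an mtDNA introgression. Identical `(spec, seed)` gives
#' bit-identical output.
#'
#' @param spec A [scenario_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return An object of class `numt_scenario`: a list with `mtdna` and `numt`
#'   ([coding_alignment()]s over the same column space) and `truth`, a
#'   `true_history` with fields `true_stem_divergence` (expected
#'   substitutions/site accumulated by the precursor between the ghost split
#'   and the insertion), `per_branch_counts`, `stem_labels`, `event_log`,
#'   `true_tree` (ape `phylo`, realized substitutions/site) and `mutations`
#'   (per-branch realized substitution records).
#' @export
simulate_scenario <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  L <- spec$sequence_length
  gen <- .genealogy(spec)
  tab <- gen$tab
  ann <- .site_codon_map(spec$coding_map, L)

  root_seq <- sample.int(4L, L, replace = TRUE)
  a <- .proposal_acceptance(root_seq, ann, spec$kappa, spec$omega)
  rate_fun <- spec$mito_rate / a
  rate_pse <- spec$mito_rate * spec$nuclear_rate_ratio

  n <- .tab_n(tab)
  order_ids <- order(-tab$age, seq_len(n))
  seqs <- vector("list", n)
  muts <- vector("list", n)
  root <- .tab_root(tab)
  seqs[[root]] <- root_seq
  for (id in order_ids) {
    p <- tab$parent[id]
    if (is.na(p)) next
    dur <- tab$age[p] - tab$age[id]
    functional <- tab$phase[id] == "functional"
    out <- .evolve_int(seqs[[p]], dur,
                       if (functional) rate_fun else rate_pse,
                       spec$kappa, if (functional) spec$omega else 1,
                       functional, ann)
    seqs[[id]] <- out$seq
    m <- out$mutations
    m$phase <- rep(if (functional) "functional" else "pseudogene", nrow(m))
    m$branch <- rep(tab$label[id], nrow(m))
    muts[[id]] <- m
  }

  all_muts <- do.call(rbind, muts[!vapply(muts, is.null, logical(1))])
  rownames(all_muts) <- NULL

  counts <- data.frame(
    branch = tab$label, parent = tab$label[tab$parent],
    phase = tab$phase,
    duration = tab$age[tab$parent] - tab$age,
    stringsAsFactors = FALSE)[!is.na(tab$parent), ]
  tally <- function(lbl, cls) {
    m <- muts[[match(lbl, tab$label)]]
    if (is.null(m)) return(0L)
    sum(m$class == cls)
  }
  counts$synonymous <- vapply(counts$branch, tally, integer(1), "synonymous")
  counts$non_synonymous <- vapply(counts$branch, tally, integer(1),
                                  "non_synonymous")
  counts$non_coding <- vapply(counts$branch, tally, integer(1), "non_coding")
  counts$n <- counts$synonymous + counts$non_synonymous + counts$non_coding
  counts$realized <- counts$n / L
  rownames(counts) <- NULL

  len_by_child <- stats::setNames(as.list(counts$realized), counts$branch)
  true_tree <- ape::read.tree(text = .tab_newick(tab, len_by_child))

  is_tip <- vapply(seq_len(n), function(i) length(.tab_children(tab, i)) == 0L,
                   logical(1))
  tip_labels <- tab$label[is_tip]
  tip_seqs <- vapply(which(is_tip), function(i) .int_to_seq(seqs[[i]]),
                     character(1))
  names(tip_seqs) <- tip_labels
  numt_ids <- grepl("^NUMT_", tip_labels)
  mtdna <- coding_alignment(tip_seqs[!numt_ids], coding_map = spec$coding_map)
  numt <- coding_alignment(tip_seqs[numt_ids], coding_map = spec$coding_map)

  truth <- structure(list(
    true_stem_divergence = if (spec$mode == "null_no_ghost") 0 else
      spec$mito_rate * (spec$ghost_split_time - spec$insertion_time),
    per_branch_counts = counts,
    stem_labels = gen$stem_labels,
    event_log = gen$events,
    true_tree = true_tree,
    mutations = all_muts,
    mode = spec$mode), class = "true_history")

  structure(list(mtdna = mtdna, numt = numt, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "numt_scenario")
}

#' @export
print.true_history <- function(x, ...) {
  cat("true_history (mode:", x$mode, ")\n")
  cat("  true stem divergence:", x$true_stem_divergence, "subst/site\n")
  cat("  branches:", nrow(x$per_branch_counts),
      " total substitutions:", sum(x$per_branch_counts$n), "\n")
  cat("  events:\n")
  for (i in seq_len(nrow(x$event_log))) {
    cat(sprintf("    %6.2f Myr  %s\n", x$event_log$time[i],
                x$event_log$event[i]))
  }
  invisible(x)
}

#' @export
print.numt_scenario <- function(x, ...) {
  cat("numt_scenario (seed", x$seed, ")\n")
  cat("  mtDNA taxa: ", paste(names(x$mtdna$seqs), collapse = ", "), "\n")
  cat("  NUMT taxa:  ", paste(names(x$numt$seqs), collapse = ", "), "\n")
  print(x$truth)
  invisible(x)
}

#' Joint alignment of mtDNA and NUMT records from a simulated scenario
#'
#' @param scen A `numt_scenario` from [simulate_scenario()].
#' @return A [coding_alignment()] containing both record sets.
#' @export
joint_alignment <- function(scen) {
  stopifnot(inherits(scen, "numt_scenario"))
  coding_alignment(c(scen$mtdna$seqs, scen$numt$seqs),
                   coding_map = scen$mtdna$coding_map)
}
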