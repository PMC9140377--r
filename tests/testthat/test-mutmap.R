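make_aln <- function(seqs, coding = TRUE) {
  L <- nchar(seqs[[1]])
  cm <- if (coding) data.frame(start = 0, end = 3 * (L %/% 3), frame = 0)
  coding_alignment(seqs, coding_map = cm)
}

test_that("invariant columns reconstruct to the shared base everywhere", {
  tr <- root_with_outgroup(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):2);"),
                           "D")
  aln <- make_aln(c(A = "AAAGGG", B = "AAAGGG", C = "AAAGGG", D = "AAAGGG"))
  rec <- reconstruct_ancestors(tr, aln)
  expect_true(all(rec$sequences == "AAAGGG"))
  expect_identical(rec$score, 0L)
})

test_that("the ((A,A),(C,C)) pattern costs one change, resolved by tie-break", {
  tr <- ape::read.tree(text = "((t1:1,t2:1)n1:1,(t3:1,t4:1)n2:1)r;")
  aln <- make_aln(c(t1 = "AAA", t2 = "AAA", t3 = "CAA", t4 = "CAA"),
                  coding = FALSE)
  rec <- reconstruct_ancestors(tr, aln)
  # column 1: leaf pattern A A C C -> one change; root set {A,C} resolved
  # alphabetically to A, then each internal node prefers its parent
  expect_identical(rec$score, 1L)
  expect_identical(substr(rec$sequences[["r"]], 1, 1), "A")
  expect_identical(substr(rec$sequences[["n1"]], 1, 1), "A")
  oracle <- oracle_parsimony_score(tr, c("A", "A", "C", "C"))
  expect_identical(rec$score, as.integer(oracle))
})

test_that("Fitch score equals the exhaustive minimum on random small trees", {
  set.seed(7)
  states <- c("A", "C", "G", "T", "-")
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    leaf <- sample(states, n, replace = TRUE)
    aln <- make_aln(setNames(as.list(strrep(leaf, 1)), tr$tip.label),
                    coding = FALSE)
    aln <- coding_alignment(setNames(leaf, tr$tip.label))
    rec <- reconstruct_ancestors(tr, aln)
    expect_identical(rec$score, as.integer(oracle_parsimony_score(tr, leaf)))
  }
})

test_that("implied changes per column respect the parsimony lower bound", {
  set.seed(31)
  tr <- ape::rtree(6)
  leaf <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
  aln <- coding_alignment(setNames(leaf, tr$tip.label))
  rec <- reconstruct_ancestors(tr, aln)
  expect_gte(rec$score, length(unique(leaf)) - 1L)
})

test_that("gaps never override nucleotides in the final pass", {
  tr <- ape::read.tree(text = "((t1:1,t2:1)n1:1,(t3:1,t4:1)n2:1)r;")
  aln <- coding_alignment(c(t1 = "-", t2 = "-", t3 = "G", t4 = "G"))
  rec <- reconstruct_ancestors(tr, aln)
  expect_identical(rec$sequences[["r"]], "G")
})

test_that("reconstruct_ancestors demands a rooted tree with sequences", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1);")
  aln <- coding_alignment(c(A = "A", B = "A", C = "A"))
  expect_error(reconstruct_ancestors(tr, aln), "rooted")
  tr2 <- root_with_outgroup(tr, "C")
  expect_error(reconstruct_ancestors(
    tr2, coding_alignment(c(A = "A", B = "A"))), "no sequence for leaf")
})

test_that("classify_mutation follows the genetic code", {
  expect_identical(classify_mutation(3, "T", "C",
                                     list(codon = "GCT", codon_pos = 3)),
                   "synonymous")        # GCT -> GCC, Ala -> Ala
  expect_identical(classify_mutation(2, "C", "T",
                                     list(codon = "GCT", codon_pos = 2)),
                   "non_synonymous")    # GCT -> GTT, Ala -> Val
  # TGA -> TGG: Trp -> Trp under the vertebrate mito code...
  expect_identical(classify_mutation(3, "A", "G",
                                     list(codon = "TGA", codon_pos = 3),
                                     code_id = "2"), "synonymous")
  # ...but stop -> Trp under the standard code
  expect_identical(classify_mutation(3, "A", "G",
                                     list(codon = "TGA", codon_pos = 3),
                                     code_id = "1"), "non_synonymous")
  expect_identical(classify_mutation(9, "A", "G", NULL), "non_coding")
  expect_error(classify_mutation(1, "A", "G",
                                 list(codon = "A-G", codon_pos = 1)),
               "unresolvable")
})

test_that("classification is symmetric under from/to exchange", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    codon <- paste(sample(bases, 3, TRUE), collapse = "")
    pos <- sample(3, 1)
    from <- substr(codon, pos, pos)
    to <- sample(setdiff(bases, from), 1)
    rev_codon <- codon
    substr(rev_codon, pos, pos) <- to
    a <- classify_mutation(pos, from, to, list(codon = codon, codon_pos = pos))
    b <- classify_mutation(pos, to, from,
                           list(codon = rev_codon, codon_pos = pos))
    expect_identical(a, b)
  }
})

test_that("assign_branch_mutations records and classifies per-branch changes", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  # identical parent/child -> nothing; one non-coding mismatch -> one record
  aln0 <- coding_alignment(c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT"))
  bms0 <- assign_branch_mutations(reconstruct_ancestors(tr, aln0))
  expect_identical(nrow(bms0), 0L)
  aln1 <- coding_alignment(c(A = "ACGA", B = "ACGT", C = "ACGT", D = "ACGT"))
  bms1 <- assign_branch_mutations(reconstruct_ancestors(tr, aln1))
  expect_identical(nrow(bms1), 1L)
  expect_identical(bms1$branch, "A")
  expect_identical(bms1$class, "non_coding")  # no coding map
  expect_identical(bms1$column, 4L)
})

test_that("multi-hit codons are classified against the updated background", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  # ancestral codon CTT (Leu); child codon ATG: CTT->ATT (Leu->Ile, nonsyn at
  # pos1 against CTT), then TTT->... second change T->G at pos3 against the
  # updated codon ATT -> ATG (Ile->Met under code 2: non-synonymous)
  cm <- data.frame(start = 0, end = 3, frame = 0)
  aln <- coding_alignment(c(A = "ATG", B = "CTT", C = "CTT", D = "CTT"),
                          coding_map = cm)
  bms <- assign_branch_mutations(reconstruct_ancestors(tr, aln))
  a_rows <- bms[bms$branch == "A", ]
  expect_identical(nrow(a_rows), 2L)
  expect_identical(a_rows$class, c("non_synonymous", "non_synonymous"))
})

test_that("branch mutation recovery matches simulation truth at low divergence", {
  # sparse mutations, negligible multiple hits: parsimony should recover the
  # per-branch counts on nearly all branches
  ok <- 0L; total <- 0L
  for (s in 1:20) {
    sp <- ps5_scenario(seed = s, sequence_length = 900L,
                       mito_rate = 0.002)  # sparse regime
    scen <- simulate_scenario(sp)
    aln <- joint_alignment(scen)
    tt <- scen$truth$true_tree   # already rooted at the true origin
    rec <- reconstruct_ancestors(tt, aln)
    bms <- assign_branch_mutations(rec)
    got <- table(bms$branch)
    truth <- scen$truth$per_branch_counts
    labels <- c(tt$tip.label, tt$node.label)
    # pass-through nodes (phase-change markers) are collapsed in the
    # observable tree: fold their counts onto the downstream observable edge
    while (any(!truth$branch %in% labels)) {
      i <- which(!truth$branch %in% labels)[1]
      j <- which(truth$parent == truth$branch[i])
      truth$n[j] <- truth$n[j] + truth$n[i]
      truth$parent[j] <- truth$parent[i]
      truth <- truth[-i, ]
    }
    # the two root-adjacent edges cannot be polarized by parsimony: skip them
    root_kids <- labels[tt$edge[tt$edge[, 1] == ape::Ntip(tt) + 1L, 2]]
    truth <- truth[!truth$branch %in% root_kids, ]
    for (i in seq_len(nrow(truth))) {
      n_hat <- if (truth$branch[i] %in% names(got))
        got[[truth$branch[i]]] else 0L
      total <- total + 1L
      if (abs(n_hat - truth$n[i]) <= max(1, 0.25 * truth$n[i])) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("stem contrast p-value equals the hypergeometric tail oracle", {
  stem <- data.frame(class = rep(c("synonymous", "non_synonymous"),
                                 c(90, 10)))
  others <- data.frame(class = rep(c("synonymous", "non_synonymous"),
                                   c(40, 60)))
  res <- stem_contrast_test(stem, others)
  expect_equal(res$p_value, oracle_fisher_greater(90, 10, 40, 60),
               tolerance = 1e-12)
  expect_equal(res$syn_fraction_stem, 0.9)
  expect_equal(res$syn_fraction_others, 0.4)
})

test_that("stem contrast degenerate and error cases", {
  same <- data.frame(class = rep(c("synonymous", "non_synonymous"), c(5, 5)))
  expect_gte(stem_contrast_test(same, same)$p_value, 0.5)
  all_syn <- data.frame(class = rep("synonymous", 10))
  res <- stem_contrast_test(all_syn, all_syn)
  expect_true(res$degenerate)
  expect_identical(res$p_value, 1)
  rrna <- data.frame(class = rep("non_coding", 10))
  expect_error(stem_contrast_test(rrna, same), "not apt")
  expect_error(stem_contrast_test(same, rrna), "post-insertion")
})

test_that("mutations export as TSV", {
  tr <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)r;")
  aln <- coding_alignment(c(A = "ACGA", B = "ACGT", C = "ACGT", D = "ACGT"))
  bms <- assign_branch_mutations(reconstruct_ancestors(tr, aln))
  f <- tempfile(fileext = ".tsv")
  write_mutations_tsv(bms, f)
  back <- utils::read.delim(f)
  expect_identical(nrow(back), 1L)
  expect_identical(back$branch, "A")
})
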