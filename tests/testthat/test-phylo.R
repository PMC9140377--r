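test_that("ml_distance identities, inversion and errors", {
  s <- "ACGTACGTAC"
  for (m in c("p", "jc", "k80")) expect_identical(ml_distance(s, s, m), 0)
  # numerical inversion of the JC formula: p chosen so that d = 0.045
  d <- 0.045
  p <- 0.75 * (1 - exp(-4 * d / 3))
  L <- 1e6
  a <- strrep("A", L)
  nmut <- round(p * L)
  b <- paste0(strrep("C", nmut), strrep("A", L - nmut))
  expect_equal(ml_distance(a, b, "jc"), -0.75 * log(1 - 4 * (nmut / L) / 3),
               tolerance = 1e-12)
  expect_equal(ml_distance(a, b, "jc"), d, tolerance = 1e-3)
  # saturation at the domain boundary
  a4 <- "AAAACCCCGGGGTTTT"
  b4 <- "CCCCGGGGTTTTAAAA"  # p = 1
  expect_error(ml_distance(a4, b4, "jc"), "saturation")
  expect_error(ml_distance("A-GT", "A-GA", "p"), NA)
  expect_error(ml_distance("----", "ACGT"), "comparable")
  expect_error(ml_distance("ACG", "ACGT"), "equal length")
})

test_that("ml_distance is symmetric, jc >= p, and matches ape::dist.dna", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_seq(400)
    sp <- scenario_spec(sequence_length = 400L, omega = 1, kappa = 4, seed = i)
    b <- evolve_sequence(a, stats::runif(1, 0.5, 12), "functional", sp,
                         seed = i)$seq
    p <- ml_distance(a, b, "p")
    expect_identical(ml_distance(a, b, "jc"), ml_distance(b, a, "jc"))
    expect_gte(ml_distance(a, b, "jc"), p)
    bin <- ape::as.DNAbin(rbind(a = strsplit(a, "")[[1]],
                                b = strsplit(b, "")[[1]]))
    expect_equal(ml_distance(a, b, "jc"),
                 as.numeric(ape::dist.dna(bin, "JC69")), tolerance = 1e-9)
    expect_equal(ml_distance(a, b, "k80"),
                 as.numeric(ape::dist.dna(bin, "K80")), tolerance = 1e-9)
  }
})

test_that("gap and ambiguity columns are excluded pairwise", {
  expect_identical(ml_distance("ACGT-A", "ACGTCA", "p"), 0)
  expect_identical(ml_distance("ACGTNA", "ACGTCC", "p"), 0.2)
})

test_that("neighbor-joining is exact on additive matrices", {
  set.seed(99)
  for (i in 1:25) {
    tr <- random_additive_tree(sample(5:10, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- build_nj_tree(D)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("3-taxon NJ solves the three-point equations exactly", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(D)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl["a", "b"], 0.3, tolerance = 1e-12)
  expect_equal(pl["a", "c"], 0.5, tolerance = 1e-12)
  # pendant lengths from the closed form
  la <- (0.3 + 0.5 - 0.6) / 2
  expect_equal(tr$edge.length[tr$edge[, 2] == match("a", tr$tip.label)], la)
})

test_that("identical rows give a zero-length cherry; bad matrices error", {
  D <- matrix(c(0, 0, 0.4, 0, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- build_nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)["a", "b"], 0, tolerance = 1e-12)
  expect_true(all(tr$edge.length >= 0))
  Dbad <- D; Dbad[1, 2] <- 0.2
  expect_error(build_nj_tree(Dbad), "symmetric")
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(build_nj_tree(Dna), "NA")
  expect_error(build_nj_tree(D[1:2, 1:2]), "3 taxa")
})

test_that("rooting on an outgroup preserves all pairwise path lengths", {
  set.seed(5)
  for (i in 1:5) {
    tr <- ape::unroot(random_additive_tree(8))
    out <- tr$tip.label[1]
    rooted <- root_with_outgroup(tr, out)
    expect_true(ape::is.rooted(rooted))
    d0 <- ape::cophenetic.phylo(tr)
    d1 <- ape::cophenetic.phylo(rooted)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-10)
  }
  expect_error(root_with_outgroup(random_additive_tree(5), "nope"),
               "not a tip")
})

test_that("3-taxon rooting places the root between outgroup and ingroup pair", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:4);")
  rooted <- root_with_outgroup(tr, "C")
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  tipsets <- lapply(kids, function(k) {
    if (k <= 3) rooted$tip.label[k] else ape::extract.clade(rooted, k)$tip.label
  })
  expect_true(any(vapply(tipsets, function(s) setequal(s, "C"), logical(1))))
  expect_true(any(vapply(tipsets, function(s) setequal(s, c("A", "B")),
                         logical(1))))
})

test_that("path_length matches a brute-force walk and handles errors", {
  set.seed(13)
  tr <- random_additive_tree(8)
  expect_identical(path_length(tr, "t1", "t1"), 0)
  # leaf to parent equals the pendant branch
  tip <- match("t1", tr$tip.label)
  pe <- which(tr$edge[, 2] == tip)
  expect_equal(path_length(tr, tip, tr$edge[pe, 1]), tr$edge.length[pe])
  for (i in 1:10) {
    ab <- sample(ape::Ntip(tr) + tr$Nnode, 2)
    expect_equal(path_length(tr, ab[1], ab[2]),
                 oracle_path_length(tr, ab[1], ab[2]), tolerance = 1e-12)
  }
  expect_error(path_length(tr, "t1", "zz"), "unknown node")
})

test_that("edge_for_clade finds bipartitions and rejects non-clades", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  e <- edge_for_clade(tr, c("A", "B"))
  expect_true(setequal(
    ape::extract.clade(tr, tr$edge[e, 2])$tip.label, c("A", "B")))
  expect_error(edge_for_clade(tr, c("A", "C")), "monophyletic")
  expect_error(edge_for_clade(tr, "Z"), "unknown tips")
})

test_that("jc distance to a simulated leaf pair tracks the true path length", {
  # neutral evolution: corrected distance within 3 SE of the realized truth
  sp <- scenario_spec(sequence_length = 4000L, omega = 1, kappa = 1, seed = 17)
  scen <- simulate_scenario(sp)
  aln <- joint_alignment(scen)
  tt <- scen$truth$true_tree
  d_true <- path_length(tt, "Human", "Chimp")
  d_hat <- ml_distance(aln$seqs[["Human"]], aln$seqs[["Chimp"]], "jc")
  L <- sp$sequence_length
  p <- ml_distance(aln$seqs[["Human"]], aln$seqs[["Chimp"]], "p")
  se <- sqrt(p * (1 - p) / L) / (1 - 4 * p / 3)  # delta-method JC variance
  expect_lt(abs(d_hat - d_true), 3 * se + 0.002)
})

test_that("newick i/o round-trips and fails loudly", {
  tr <- random_additive_tree(6)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_identical(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-9)
  bad <- tempfile()
  writeLines("((A,B(;", bad)
  expect_error(read_newick(bad), "unparsable")
})
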