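test_that("scenario_spec validates event ordering and parameters", {
  expect_s3_class(scenario_spec(), "scenario_spec")
  expect_error(scenario_spec(ghost_split_time = 8, insertion_time = 9.5),
               "ghost_split_time")
  expect_error(scenario_spec(insertion_time = 9.5, transfer_time = 9.6),
               "insertion_time")
  expect_error(scenario_spec(omega = 1.2), "omega")
  expect_error(scenario_spec(sequence_length = 0), "sequence_length")
  expect_error(scenario_spec(coding_map = data.frame(start = c(0, 50),
                                                     end = c(100, 80),
                                                     frame = 0)),
               "overlap")
})

test_that("zero-duration evolution is the identity with no mutations", {
  sp <- small_scenario(L = 300)
  s0 <- strrep("ACGT", 75)
  out <- evolve_sequence(s0, 0, "functional", sp, seed = 1)
  expect_identical(out$seq, s0)
  expect_identical(nrow(out$mutations), 0L)
})

test_that("evolve_sequence rejects bad input", {
  sp <- small_scenario(L = 12)
  expect_error(evolve_sequence("ACGTACGTACGN", 1, "functional", sp), "A, C, G, T")
  expect_error(evolve_sequence(strrep("A", 12), -1, "functional", sp),
               "duration")
  expect_error(evolve_sequence(strrep("A", 8), 1, "functional", sp),
               "length")
})

test_that("neutral evolution matches the Jukes-Cantor closed form", {
  # d = rate * duration = 0.045; expected p = 0.75 * (1 - exp(-4 d / 3))
  L <- 10000L
  sp <- scenario_spec(sequence_length = L, coding_map = data.frame(
    start = 0, end = 3, frame = 0), omega = 1, kappa = 1, seed = 99)
  set.seed(7)
  s0 <- random_seq(L)
  out <- evolve_sequence(s0, 4.5, "functional", sp, seed = 11)
  p_obs <- mean(strsplit(s0, "")[[1]] != strsplit(out$seq, "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.045 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("omega = 0 rejects every non-synonymous proposal", {
  L <- 900L
  sp <- scenario_spec(sequence_length = L, omega = 0, seed = 2)
  out <- evolve_sequence(random_seq(L), 3, "functional", sp, seed = 3)
  expect_gt(nrow(out$mutations), 0)
  expect_false(any(out$mutations$class == "non_synonymous"))
})

test_that("realized substitution counts are Poisson-consistent with rate*duration*L", {
  L <- 600L
  duration <- 2
  sp <- scenario_spec(sequence_length = L, omega = 1, kappa = 2, seed = 1)
  lambda <- sp$mito_rate * duration * L
  set.seed(101)
  s0 <- random_seq(L)
  counts <- vapply(1:50, function(s) {
    nrow(evolve_sequence(s0, duration, "functional", sp, seed = s)$mutations)
  }, numeric(1))
  # chi-square dispersion test against Poisson(lambda)
  stat <- sum((counts - lambda)^2 / lambda)
  p <- stats::pchisq(stat, df = 50, lower.tail = FALSE)
  expect_gt(p, 0.01)
  # two-sided location check as well
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 50))
})

test_that("expected_syn_fraction agrees with a nested-loop enumeration oracle", {
  kappa <- 3
  code <- get_genetic_code("2")
  bases <- c("A", "C", "G", "T")
  is_ts <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
  w_syn <- 0; w_tot <- 0
  for (codon in names(code)) {
    for (pos in 1:3) {
      cur <- substr(codon, pos, pos)
      for (to in setdiff(bases, cur)) {
        mut <- codon
        substr(mut, pos, pos) <- to
        w <- if (is_ts(cur, to)) kappa else 1
        w_tot <- w_tot + w
        if (code[[codon]] == code[[mut]]) w_syn <- w_syn + w
      }
    }
  }
  expect_equal(expected_syn_fraction(data.frame(start = 0, end = 90, frame = 0),
                                     "2", kappa),
               w_syn / w_tot, tolerance = 1e-12)
})

test_that("expected_syn_fraction handles degenerate maps and codes", {
  # fully non-coding: the fraction is undefined
  expect_true(is.na(expected_syn_fraction(NULL, "2", 1)))
  expect_true(is.na(expected_syn_fraction(
    data.frame(start = 0, end = 2, frame = 0), "2", 1)))
  # hypothetical code without degeneracy: every change is non-synonymous
  code <- get_genetic_code("1")
  fake <- setNames(sprintf("aa%02d", seq_along(code)), names(code))
  expect_equal(expected_syn_fraction(data.frame(start = 0, end = 90, frame = 0),
                                     kappa = 2, code_table = fake), 0)
})

test_that("neutral realized synonymous fraction matches the analytic value; selection raises it", {
  L <- 1200L
  cm <- data.frame(start = 0, end = L, frame = 0)
  sp_neutral <- scenario_spec(sequence_length = L, coding_map = cm,
                              omega = 1, kappa = 2, seed = 1)
  sp_sel <- scenario_spec(sequence_length = L, coding_map = cm,
                          omega = 0.1, kappa = 2, seed = 1)
  exp_syn <- expected_syn_fraction(cm, "2", 2)
  set.seed(55)
  s0 <- random_seq(L)
  syn_frac <- function(sp, seed) {
    m <- evolve_sequence(s0, 3, "functional", sp, seed = seed)$mutations
    m <- m[m$class != "non_coding", ]
    c(k = sum(m$class == "synonymous"), n = nrow(m))
  }
  neutral <- rowSums(vapply(1:50, function(s) syn_frac(sp_neutral, s),
                            numeric(2)))
  p_hat <- neutral[["k"]] / neutral[["n"]]
  se <- sqrt(exp_syn * (1 - exp_syn) / neutral[["n"]])
  expect_lt(abs(p_hat - exp_syn), 3 * se)
  sel <- rowSums(vapply(1:50, function(s) syn_frac(sp_sel, s), numeric(2)))
  expect_gt(sel[["k"]] / sel[["n"]], p_hat)
})

test_that("simulate_scenario is deterministic and books truth correctly", {
  sp <- small_scenario(L = 600, seed = 42)
  a <- simulate_scenario(sp)
  b <- simulate_scenario(sp)
  expect_identical(a$mtdna$seqs, b$mtdna$seqs)
  expect_identical(a$numt$seqs, b$numt$seqs)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$numt, f1); write_fasta(b$numt, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # expected stem divergence is rate x stem duration, exactly
  expect_identical(a$truth$true_stem_divergence,
                   sp$mito_rate * (sp$ghost_split_time - sp$insertion_time))
  # per-branch counts add up to the total realized substitutions
  expect_identical(sum(a$truth$per_branch_counts$n), nrow(a$truth$mutations))
  # realized tree lengths are counts / L
  pbc <- a$truth$per_branch_counts
  expect_equal(pbc$realized, pbc$n / sp$sequence_length)
})

test_that("null scenario has no ghost stem", {
  sp <- small_scenario(L = 600, seed = 3, mode = "null_no_ghost")
  scen <- simulate_scenario(sp)
  expect_identical(scen$truth$true_stem_divergence, 0)
  expect_false("numt_insertion" %in% scen$truth$stem_labels)
  expect_setequal(names(scen$numt$seqs),
                  paste0("NUMT_", c("Human", "Chimp", "Bonobo", "Gorilla")))
})

test_that("scenario modes place the NUMT clade as intended", {
  # transfer: all recipients carry the NUMT and the ghost stem is functional
  scen <- simulate_scenario(small_scenario(L = 600, seed = 8))
  pbc <- scen$truth$per_branch_counts
  expect_identical(pbc$phase[pbc$branch == "numt_insertion"], "functional")
  expect_identical(pbc$phase[pbc$branch == "numt_mrca"], "pseudogene")
  # introgression: the old-mtDNA keeper (Gorilla) descends via the insertion
  # node, the introgressed clade's mtDNA via the ghost split
  scen2 <- simulate_scenario(small_scenario(L = 600, seed = 8,
                                            mode = "mtdna_introgression"))
  tt <- scen2$truth$true_tree
  expect_true(all(c("ghost_split", "numt_insertion") %in% tt$node.label))
  stem_clade <- ape::extract.clade(
    tt, ape::Ntip(tt) + match("numt_insertion", tt$node.label))
  expect_setequal(stem_clade$tip.label,
                  c("Gorilla", paste0("NUMT_",
                                      c("Human", "Chimp", "Bonobo", "Gorilla"))))
})
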