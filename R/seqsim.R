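# Two-phase sequence-evolution simulator. A protein-coding, mtDNA-like
# sequence evolves along a species tree under purifying selection
# (acceptance-rejection on non-synonymous proposals, K80-style kappa bias);
# a ghost lineage diverges, the sequence becomes a nuclear pseudogene
# (neutral, reduced rate) and is placed into extant lineages either by
# horizontal NUMT transfer or as the relic of an mtDNA introgression.

#' Specify a NUMT evolution scenario
#'
#' Collects every knob of the two-phase simulator: the species tree (branch
#' lengths in Myr, ultrametric), the ghost-lineage event times, rates and the
#' selection parameters, and validates their mutual consistency.
#'
#' The mitochondrial clock `mito_rate` is the *observed* substitution rate
#' (default 0.01 substitutions/site/Myr, i.e. 1% per Myr). In the functional
#' phase the internal proposal rate is scaled by the inverse of the neutral
#' acceptance probability so that the realized, post-selection rate equals
#' `mito_rate`; `omega` therefore controls the synonymous/non-synonymous
#' composition of accepted changes, not the overall clock.
#'
#' @param sequence_length Number of sites (default 9000, a large ~9 kb NUMT).
#' @param coding_map Coding intervals as for [coding_alignment()]; default is
#'   a single interval covering the whole sequence in frame 0 under the
#'   vertebrate mitochondrial code.
#' @param species_tree Newick string, branch lengths in Myr, ultrametric.
#'   Default `((Human:6,Chimp:6):3,Gorilla:9);`.
#' @param outgroup Optional tip label used only to root downstream analyses;
#'   excluded from the default recipient set.
#' @param recipient_taxa Tips whose genomes carry the NUMT (default: all
#'   non-outgroup tips).
#' @param introgressed_taxa For `mode = "mtdna_introgression"`: the clade whose
#'   extant mtDNA descends from the ghost lineage (default Human+Chimp-like:
#'   all recipients except the last one, which keeps the old mtDNA).
#' @param ghost_split_time Myr before present at which the ghost mtDNA lineage
#'   diverges from the lineage ancestral to the recipients.
#' @param insertion_time Myr at which the sequence becomes a nuclear
#'   pseudogene.
#' @param transfer_time Myr at which hybridization places the NUMT into the
#'   recipient lineage (or, under introgression, at which the ghost mtDNA
#'   replaces the recipients' mtDNA).
#' @param mode One of `"numt_transfer"`, `"mtdna_introgression"`,
#'   `"null_no_ghost"`.
#' @param mito_rate Observed mitochondrial substitution rate,
#'   substitutions/site/Myr.
#' @param nuclear_rate_ratio Nuclear/mitochondrial rate ratio (< 1).
#' @param omega Acceptance probability for non-synonymous proposals during the
#'   functional phase (0 = hard purifying selection, 1 = neutral).
#' @param kappa Transition/transversion proposal bias.
#' @param seed Integer RNG seed stored with the spec.
#' @return An object of class `scenario_spec`.
#' @seealso [ps5_scenario()] for the fully configured study conditions,
#'   [simulate_scenario()] to run the simulator.
#' @export
scenario_spec <- function(sequence_length = 9000L,
                          coding_map = NULL,
                          species_tree = "((Human:6,Chimp:6):3,Gorilla:9);",
                          outgroup = NULL,
                          recipient_taxa = NULL,
                          introgressed_taxa = NULL,
                          ghost_split_time = 14,
                          insertion_time = 9.5,
                          transfer_time = 9.2,
                          mode = c("numt_transfer", "mtdna_introgression",
                                   "null_no_ghost"),
                          mito_rate = 0.01,
                          nuclear_rate_ratio = 0.05,
                          omega = 0.1,
                          kappa = 8,
                          seed = 1L) {
  mode <- match.arg(mode)
  sequence_length <- as.integer(sequence_length)
  if (sequence_length <= 0L) stop("sequence_length must be > 0")
  if (is.null(coding_map)) {
    coding_map <- data.frame(start = 0L, end = sequence_length,
                             frame = 0L, code_id = "2")
  }
  coding_map <- .normalize_coding_map(coding_map, sequence_length)
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (kappa <= 0) stop("kappa must be positive")
  if (mito_rate <= 0) stop("mito_rate must be positive")
  if (nuclear_rate_ratio <= 0 || nuclear_rate_ratio >= 1) {
    stop("nuclear_rate_ratio must lie in (0, 1)")
  }
  phy <- tryCatch(ape::read.tree(text = species_tree),
                  error = function(e) NULL)
  if (is.null(phy)) stop("species_tree is not parseable Newick")
  if (is.null(phy$edge.length)) stop("species_tree needs branch lengths (Myr)")
  depth <- ape::node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(ape::Ntip(phy))]
  if (diff(range(tip_depth)) > 1e-6 * max(tip_depth)) {
    stop("species_tree must be ultrametric (equal root-to-tip path lengths)")
  }
  tips <- phy$tip.label
  if (!is.null(outgroup) && !outgroup %in% tips) {
    stop("outgroup '", outgroup, "' is not a tip of species_tree")
  }
  ingroup <- setdiff(tips, outgroup)
  if (is.null(recipient_taxa)) recipient_taxa <- ingroup
  if (!all(recipient_taxa %in% ingroup)) {
    stop("recipient_taxa must be non-outgroup tips of species_tree")
  }
  if (length(recipient_taxa) < 2L) stop("need at least 2 recipient taxa")
  if (mode == "mtdna_introgression") {
    if (is.null(introgressed_taxa)) {
      introgressed_taxa <- recipient_taxa[-length(recipient_taxa)]
    }
    if (!all(introgressed_taxa %in% ingroup)) {
      stop("introgressed_taxa must be non-outgroup tips of species_tree")
    }
    if (setequal(introgressed_taxa, ingroup)) {
      stop("mtDNA introgression must leave at least one ingroup taxon with ",
           "the old mtDNA (otherwise the ghost signal is unobservable)")
    }
  }
  if (mode != "null_no_ghost") {
    if (!(ghost_split_time > insertion_time)) {
      stop("event ordering violated: ghost_split_time (", ghost_split_time,
           ") must exceed insertion_time (", insertion_time, ")")
    }
    if (!(insertion_time > transfer_time)) {
      stop("event ordering violated: insertion_time (", insertion_time,
           ") must exceed transfer_time (", transfer_time, ")")
    }
    if (transfer_time < 0) {
      stop("event ordering violated: transfer_time (", transfer_time,
           ") must be >= 0")
    }
  } else {
    if (insertion_time <= 0) stop("insertion_time must be > 0")
  }
  structure(list(
    sequence_length = sequence_length, coding_map = coding_map,
    species_tree = species_tree, phylo = phy,
    outgroup = outgroup, recipient_taxa = recipient_taxa,
    introgressed_taxa = introgressed_taxa,
    ghost_split_time = ghost_split_time, insertion_time = insertion_time,
    transfer_time = transfer_time, mode = mode,
    mito_rate = mito_rate, nuclear_rate_ratio = nuclear_rate_ratio,
    omega = omega, kappa = kappa, seed = as.integer(seed)),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec (mode:", x$mode, ")\n")
  cat("  sites:", x$sequence_length, " coding intervals:",
      nrow(x$coding_map), "\n")
  cat("  species tree:", x$species_tree, "\n")
  if (x$mode != "null_no_ghost") {
    cat("  ghost split:", x$ghost_split_time, "Myr  insertion:",
        x$insertion_time, "Myr  transfer:", x$transfer_time, "Myr\n")
    cat("  expected precursor stem divergence:",
        x$mito_rate * (x$ghost_split_time - x$insertion_time), "subst/site\n")
  } else {
    cat("  no ghost lineage; insertion:", x$insertion_time, "Myr\n")
  }
  cat("  mito rate:", x$mito_rate, "/site/Myr  nuclear ratio:",
      x$nuclear_rate_ratio, " omega:", x$omega, " kappa:", x$kappa, "\n")
  invisible(x)
}

#' The ps5-like study scenario
#'
#' Convenience constructor for the default study conditions: a ~9 kb
#' protein-coding mtDNA-like locus, hominine-like species tree with a
#' congeneric pair (Chimp/Bonobo, split 2.5 Myr), genus-level splits at 6 and
#' 9 Myr and an Orangutan outgroup at 16 Myr; a ghost lineage diverging 4.5
#' Myr before giving rise to the pseudogene (1%/Myr clock, so an expected
#' precursor stem divergence of 4.5%), purifying selection at `omega = 0.1`
#' and a 20-fold lower nuclear rate.
#'
#' @param mode Scenario mode, as in [scenario_spec()]. Under
#'   `"mtdna_introgression"` the transfer (mtDNA replacement) hits the
#'   Human+Chimp+Bonobo clade at 7 Myr and Gorilla keeps the old mtDNA.
#' @param seed RNG seed.
#' @param ... Overrides passed on to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
ps5_scenario <- function(mode = "numt_transfer", seed = 1L, ...) {
  defaults <- list(
    sequence_length = 9000L,
    species_tree =
      "(((Human:6,(Chimp:2.5,Bonobo:2.5):3.5):3,Gorilla:9):7,Orangutan:16);",
    outgroup = "Orangutan",
    recipient_taxa = c("Human", "Chimp", "Bonobo", "Gorilla"),
    introgressed_taxa = if (mode == "mtdna_introgression")
      c("Human", "Chimp", "Bonobo") else NULL,
    ghost_split_time = 14, insertion_time = 9.5,
    transfer_time = if (mode == "mtdna_introgression") 7 else 9.2,
    mode = mode, mito_rate = 0.01, nuclear_rate_ratio = 0.05,
    omega = 0.1, kappa = 8, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_spec, args)
}

# ---------------------------------------------------------------------------
# proposal acceptance probability under the current sequence background:
# a = sum_w [ syn-or-noncoding + omega * nonsyn ] / sum_w over all (site, alt)
# proposals with kappa transition weighting. Used to calibrate the functional-
# phase proposal rate so the accepted rate equals mito_rate.
.proposal_acceptance <- function(s, ann, kappa, omega) {
  if (omega >= 1) return(1)
  L <- length(s)
  contrib <- c(16L, 4L, 1L)
  coding <- !is.na(ann$codon_start)
  w_nonsyn <- 0
  # per-site proposal weight mass is kappa + 2 regardless of the current base
  w_total <- L * (kappa + 2)
  if (any(coding)) {
    idx <- which(coding)
    cs <- ann$codon_start[idx]; pos <- ann$codon_pos[idx]
    cur <- s[idx]
    codes <- ann$code[idx]
    idx0 <- (s[cs] - 1L) * 16L + (s[cs + 1L] - 1L) * 4L + s[cs + 2L]
    for (k in 1:3) {
      to <- ((cur - 1L + k) %% 4L) + 1L
      w <- ifelse(to == .TS_PARTNER[cur], kappa, 1)
      idx1 <- idx0 + (to - cur) * contrib[pos]
      ns <- logical(length(idx))
      for (cid in unique(codes)) {
        aa <- .aa_by_int(cid)
        sel <- codes == cid
        ns[sel] <- aa[idx0[sel]] != aa[idx1[sel]]
      }
      w_nonsyn <- w_nonsyn + sum(w[ns])
    }
  }
  a <- (w_total - w_nonsyn + omega * w_nonsyn) / w_total
  if (a <= 0) stop("acceptance probability is zero: no change can ever fix")
  a
}

# core integer-coded evolution along one branch; mutates s, records accepted
# substitutions in event order. `rate` is the *proposal* rate per site/Myr.
.evolve_int <- function(s, duration, rate, kappa, omega, functional, ann) {
  L <- length(s)
  n_prop <- stats::rpois(1L, rate * duration * L)
  rec_site <- integer(n_prop); rec_from <- integer(n_prop)
  rec_to <- integer(n_prop); rec_class <- character(n_prop)
  n_acc <- 0L
  if (n_prop > 0L) {
    sites <- sample.int(L, n_prop, replace = TRUE)
    contrib <- c(16L, 4L, 1L)
    aa_cache <- lapply(
      stats::setNames(nm = unique(stats::na.omit(ann$code))), .aa_by_int)
    for (k in seq_len(n_prop)) {
      site <- sites[[k]]
      cur <- s[[site]]
      alts <- (1:4)[-cur]
      w <- c(1, 1, 1)
      w[alts == .TS_PARTNER[cur]] <- kappa
      to <- alts[sample.int(3L, 1L, prob = w)]
      cs <- ann$codon_start[site]
      if (is.na(cs)) {
        cls <- "non_coding"
      } else {
        aa <- aa_cache[[ann$code[site]]]
        idx0 <- (s[cs] - 1L) * 16L + (s[cs + 1L] - 1L) * 4L + s[cs + 2L]
        idx1 <- idx0 + (to - cur) * contrib[ann$codon_pos[site]]
        cls <- if (aa[idx0] == aa[idx1]) "synonymous" else "non_synonymous"
      }
      if (functional && cls == "non_synonymous" && omega < 1 &&
          stats::runif(1) > omega) next
      n_acc <- n_acc + 1L
      rec_site[n_acc] <- site; rec_from[n_acc] <- cur; rec_to[n_acc] <- to
      rec_class[n_acc] <- cls
      s[site] <- to
    }
  }
  keep <- seq_len(n_acc)
  list(seq = s,
       mutations = data.frame(
         site = rec_site[keep],
         from = .BASES[rec_from[keep]],
         to = .BASES[rec_to[keep]],
         class = rec_class[keep],
         stringsAsFactors = FALSE))
}

#' Evolve a sequence for a fixed time in one phase
#'
#' Continuous-time per-site substitution process with a transition/transversion
#' proposal bias. In the functional phase, a proposed change that is
#' non-synonymous under the spec's coding map is accepted with probability
#' `omega`; synonymous and non-coding proposals are always accepted, and the
#' proposal rate is scaled so the realized substitution rate equals
#' `spec$mito_rate`. In the pseudogene phase every proposal is accepted and
#' the rate is `mito_rate * nuclear_rate_ratio`. Multiple hits at a site are
#' allowed; codon effects are judged against the current (already mutated)
#' background.
#'
#' @param seq Nucleotide string (strictly A/C/G/T), length
#'   `spec$sequence_length`.
#' @param duration Time in Myr (>= 0).
#' @param phase `"functional"` or `"pseudogene"`.
#' @param spec A [scenario_spec()].
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A list with `seq` (evolved string) and `mutations` (data frame with
#'   columns `site` (1-based), `from`, `to`, `phase`, `class`).
#' @examples
#' sp <- scenario_spec(sequence_length = 300L, seed = 7)
#' out <- evolve_sequence(strrep("ACGT", 75), 2, "functional", sp, seed = 7)
#' @export
evolve_sequence <- function(seq, duration,
                            phase = c("functional", "pseudogene"),
                            spec, seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  if (duration < 0) stop("duration must be >= 0")
  if (!grepl("^[ACGTacgt]*$", seq)) {
    stop("seq must contain only A, C, G, T")
  }
  s <- .seq_to_int(seq)
  if (length(s) != spec$sequence_length) {
    stop("seq length (", length(s), ") != spec$sequence_length (",
         spec$sequence_length, ")")
  }
  ann <- .site_codon_map(spec$coding_map, spec$sequence_length)
  if (phase == "functional") {
    a <- .proposal_acceptance(s, ann, spec$kappa, spec$omega)
    rate <- spec$mito_rate / a
    out <- .evolve_int(s, duration, rate, spec$kappa, spec$omega, TRUE, ann)
  } else {
    rate <- spec$mito_rate * spec$nuclear_rate_ratio
    out <- .evolve_int(s, duration, rate, spec$kappa, 1, FALSE, ann)
  }
  muts <- out$mutations
  muts$phase <- rep(phase, nrow(muts))
  muts <- muts[, c("site", "from", "to", "phase", "class")]
  list(seq = .int_to_seq(out$seq), mutations = muts)
}

#' Expected synonymous fraction under neutral evolution
#'
#' Analytic oracle for the mutation classifier: the expected fraction of
#' synonymous changes among coding-region substitutions under neutral
#' evolution and uniform codon composition, computed by enumerating all
#' single-site changes over all 64 codons with kappa transition weighting.
#'
#' @param coding_map Coding intervals (see [coding_alignment()]); if no
#'   interval contains a complete codon the fraction is undefined and `NA` is
#'   returned.
#' @param code_id Genetic code id.
#' @param kappa Transition/transversion proposal bias.
#' @param code_table Optional custom code: named character vector of length 64
#'   mapping codons to amino-acid symbols (overrides `code_id`).
#' @return Numeric scalar in \[0, 1\], or `NA` for a fully non-coding map.
#' @export
expected_syn_fraction <- function(coding_map, code_id = "2", kappa = 1,
                                  code_table = NULL) {
  if (is.null(code_table)) {
    aa <- .aa_by_int(code_id)  # errors on unknown code
  } else {
    if (length(code_table) != 64L || is.null(names(code_table))) {
      stop("code_table must be a named character vector of length 64")
    }
    aa <- character(64)
    for (codon in names(code_table)) {
      v <- .base_to_int(strsplit(toupper(codon), "")[[1]])
      aa[(v[1] - 1L) * 16L + (v[2] - 1L) * 4L + v[3]] <- code_table[[codon]]
    }
  }
  cm <- if (is.null(coding_map) || NROW(coding_map) == 0L) NULL else
    as.data.frame(coding_map)
  has_codon <- !is.null(cm) &&
    any((cm$end - cm$start - ifelse(is.null(cm$frame), 0, cm$frame)) >= 3)
  if (!has_codon) return(NA_real_)
  contrib <- c(16L, 4L, 1L)
  w_syn <- 0; w_tot <- 0
  for (c1 in 1:4) for (c2 in 1:4) for (c3 in 1:4) {
    cod <- c(c1, c2, c3)
    idx0 <- (c1 - 1L) * 16L + (c2 - 1L) * 4L + c3
    for (pos in 1:3) {
      cur <- cod[pos]
      for (to in (1:4)[-cur]) {
        w <- if (to == .TS_PARTNER[cur]) kappa else 1
        idx1 <- idx0 + (to - cur) * contrib[pos]
        w_tot <- w_tot + w
        if (aa[idx0] == aa[idx1]) w_syn <- w_syn + w
      }
    }
  }
  w_syn / w_tot
}
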