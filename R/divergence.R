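# Delete-d jackknife divergence estimation on a fixed topology, the
# mitochondrial-fraction correction of the stem estimate, and the taxonomic
# classification of a divergence against reference distributions.

# vectorized distances from column tallies; returns d and a saturation flag
.dist_vec <- function(n, ndiff, nts, model) {
  p <- ndiff / n
  if (model == "p") return(list(d = p, saturated = n == 0))
  if (model == "jc") {
    sat <- n == 0 | p >= 0.75
    d <- ifelse(sat, NA_real_, -0.75 * log(1 - 4 * pmin(p, 0.7499) / 3))
    return(list(d = d, saturated = sat))
  }
  P <- nts / n
  Q <- (ndiff - nts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- n == 0 | w1 <= 0 | w2 <= 0
  d <- ifelse(sat, NA_real_, -0.5 * log(pmax(w1, 1e-12)) -
                0.25 * log(pmax(w2, 1e-12)))
  list(d = d, saturated = sat)
}

# site classes for partitioned distance estimation: codon positions 1..3,
# 0 for non-coding columns
.site_classes <- function(coding_map, L) {
  ann <- .site_codon_map(coding_map, L)
  cls <- ann$codon_pos
  cls[is.na(cls)] <- 0L
  cls
}

# per-pair, per-class distance combination: the per-site divergence is the
# site-count-weighted mean of the class-wise model-corrected distances, which
# keeps the estimate additive when site classes evolve at different rates
# (e.g. third codon positions under purifying selection)
.combine_class_dists <- function(nok, ndiff, nts, model, classes_present) {
  # nok/ndiff/nts: matrices (class x pair). Pairs for which a single class
  # saturates fall back to the pooled-columns estimate; a pair whose pooled
  # estimate saturates too makes the whole fit unusable (NULL).
  total_ok <- colSums(nok)
  if (any(total_ok == 0)) return(NULL)
  np <- ncol(nok)
  dsum <- rep(0, np)
  fallback <- rep(FALSE, np)
  for (ci in seq_len(nrow(nok))) {
    use <- nok[ci, ] > 0
    if (!any(use)) next
    dv <- .dist_vec(nok[ci, use], ndiff[ci, use], nts[ci, use], model)
    fallback[use][dv$saturated] <- TRUE
    d <- dv$d
    d[dv$saturated] <- 0
    dsum[use] <- dsum[use] + nok[ci, use] * d
  }
  d <- dsum / total_ok
  if (any(fallback)) {
    dv <- .dist_vec(total_ok[fallback], colSums(ndiff)[fallback],
                    colSums(nts)[fallback], model)
    if (any(dv$saturated)) return(NULL)
    d[fallback] <- dv$d
  }
  d
}

# Jackknife over alignment columns with OLS branch-length re-fitting on a
# fixed (unrooted) topology. Returns the per-replicate edge-length matrix.
.jackknife_fit <- function(aln, topology, n_replicates = 1000L,
                           delete_fraction = 0.5, model = "k80",
                           seed = NULL, partition = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (delete_fraction < 0 || delete_fraction >= 1) {
    stop("delete_fraction must lie in [0, 1)")
  }
  if (n_replicates < 2L) stop("need at least 2 replicates")
  tr <- ape::unroot(topology)
  if (!all(tr$tip.label %in% names(aln$seqs))) {
    stop("topology tips missing from alignment: ",
         paste(setdiff(tr$tip.label, names(aln$seqs)), collapse = ", "))
  }
  im <- .aln_int_matrix(aln)[, tr$tip.label, drop = FALSE]
  L <- nrow(im)
  ntax <- ncol(im)
  pairs <- utils::combn(ntax, 2L)
  npairs <- ncol(pairs)

  cls <- if (partition) .site_classes(aln$coding_map, L) else
    rep(0L, L)
  class_levels <- sort(unique(cls))
  cls_f <- factor(cls, levels = class_levels)
  ncls <- length(class_levels)

  OK <- matrix(0L, L, npairs); DIFF <- matrix(0L, L, npairs)
  TS <- matrix(0L, L, npairs)
  for (k in seq_len(npairs)) {
    a <- im[, pairs[1, k]]; b <- im[, pairs[2, k]]
    ok <- !is.na(a) & !is.na(b)
    tsv <- ok & (a != b) & (a == .TS_PARTNER[b])
    tsv[is.na(tsv)] <- FALSE
    OK[, k] <- ok
    DIFF[, k] <- ok & (a != b)
    TS[, k] <- tsv
  }

  # design matrix: edge e lies on the i~j path iff the edge's bipartition
  # separates i from j
  sets <- .edge_tip_sets(tr)
  memb <- vapply(sets, function(s) tr$tip.label %in% s, logical(ntax))
  X <- matrix(0, npairs, nrow(tr$edge))
  for (k in seq_len(npairs)) {
    X[k, ] <- memb[pairs[1, k], ] != memb[pairs[2, k], ]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("branch lengths not identifiable from pairwise distances on this ",
         "topology")
  }

  class_sums <- function(M, idx) {
    # (class x pair) tallies over the column subset idx
    m <- rowsum(M[idx, , drop = FALSE], cls_f[idx], reorder = TRUE)
    out <- matrix(0L, ncls, npairs)
    out[match(rownames(m), as.character(class_levels)), ] <- m
    out
  }

  fit_once <- function(idx) {
    d <- .combine_class_dists(class_sums(OK, idx), class_sums(DIFF, idx),
                              class_sums(TS, idx), model, class_levels)
    if (is.null(d)) return(NULL)
    qr.coef(qrX, d)
  }

  full <- fit_once(seq_len(L))
  if (is.null(full)) {
    stop("saturation in the full-data distance matrix; use a closer ",
         "reference set or a different model")
  }

  m <- max(2L, round((1 - delete_fraction) * L))
  est <- matrix(NA_real_, n_replicates, ncol(X))
  excluded <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(L, m)
    b <- fit_once(idx)
    if (is.null(b)) excluded <- excluded + 1L else est[r, ] <- b
  }
  if (excluded > 0.2 * n_replicates) {
    stop("more than 20% of jackknife replicates saturated (",
         excluded, "/", n_replicates, ")")
  }
  est <- est[stats::complete.cases(est), , drop = FALSE]
  list(tree = tr, edge_lengths = est, full = full, excluded = excluded,
       model = model, delete_fraction = delete_fraction)
}

.resolve_target_edge <- function(tr, target) {
  if (is.character(target)) return(edge_for_clade(tr, target))
  e <- as.integer(target)
  if (e < 1L || e > nrow(tr$edge)) stop("target edge index out of range")
  e
}

#' Delete-d jackknife divergence of a branch
#'
#' Repeatedly keeps a random subset of `(1 - delete_fraction) * L` alignment
#' columns (without replacement; the delete-half jackknife by default),
#' recomputes all pairwise model-corrected distances, re-fits branch lengths
#' on the fixed topology by ordinary least squares on the path-length
#' equations, and records the target branch's fitted length. Replicates in
#' which any pairwise distance saturates are excluded (a hard error is raised
#' if more than 20% are).
#'
#' @param aln A [coding_alignment()] containing every topology tip.
#' @param topology An ape `phylo` (rooted or not; branch lengths unused).
#' @param target_branch Either an edge index into the unrooted topology or a
#'   character vector of tip labels whose subtending branch is wanted.
#' @param n_replicates Number of jackknife replicates (default 1000).
#' @param delete_fraction Fraction of columns removed per replicate (default
#'   0.5; 0 keeps every column, making all replicates equal the full-data
#'   estimate).
#' @param model Distance model, see [ml_distance()].
#' @param seed Optional RNG seed; the same seed reproduces the distribution
#'   exactly.
#' @param partition When `TRUE` (default) and the alignment carries a coding
#'   map, distances are estimated separately within each site class
#'   (codon positions 1-3, non-coding) and combined by site-count weighting;
#'   this keeps estimates additive when purifying selection makes the classes
#'   evolve at different rates.
#' @return An object of class `jackknife_divergence` with fields
#'   `replicate_estimates` (substitutions/site, clamped at 0), `n_replicates`,
#'   `n_excluded`, `delete_fraction`, `mean`, `sd`, `full_estimate`,
#'   `correction_factor` (NA until corrected), `model`.
#' @export
jackknife_divergence <- function(aln, topology, target_branch,
                                 n_replicates = 1000L, delete_fraction = 0.5,
                                 model = "k80", seed = NULL,
                                 partition = TRUE) {
  fit <- .jackknife_fit(aln, topology, n_replicates, delete_fraction, model,
                        seed, partition = partition)
  e <- .resolve_target_edge(fit$tree, target_branch)
  est <- pmax(fit$edge_lengths[, e], 0)
  structure(list(
    replicate_estimates = est,
    n_replicates = length(est),
    n_excluded = fit$excluded,
    delete_fraction = delete_fraction,
    mean = mean(est), sd = stats::sd(est),
    full_estimate = max(fit$full[e], 0),
    correction_factor = NA_real_,
    model = model),
    class = "jackknife_divergence")
}

#' @export
print.jackknife_divergence <- function(x, ...) {
  cat(sprintf(
    "jackknife_divergence: %.3f%% +/- %.3f%% (%s, %d replicates, delete-%d%%)\n",
    100 * x$mean, 100 * x$sd, x$model, x$n_replicates,
    round(100 * x$delete_fraction)))
  if (!is.na(x$correction_factor)) {
    cat("  corrected by mitochondrial fraction", x$correction_factor, "\n")
  }
  if (x$n_excluded) cat("  saturated replicates excluded:", x$n_excluded, "\n")
  invisible(x)
}

#' @export
summary.jackknife_divergence <- function(object, ...) {
  c(mean = object$mean, sd = object$sd, full = object$full_estimate,
    q025 = unname(stats::quantile(object$replicate_estimates, 0.025)),
    q975 = unname(stats::quantile(object$replicate_estimates, 0.975)))
}

#' @export
plot.jackknife_divergence <- function(x, main = "Jackknife divergence", ...) {
  graphics::plot(stats::density(100 * x$replicate_estimates),
                 xlab = "% divergence", main = main, ...)
  graphics::abline(v = 100 * x$mean, lty = 2)
  invisible(x)
}

#' Correct a stem divergence by its mitochondrial fraction
#'
#' The raw stem length of a NUMT includes post-insertion (nuclear) changes;
#' multiplying by the fraction of stem mutations attributable to the
#' functional mitochondrial phase isolates the precursor's mtDNA divergence.
#'
#' @param raw Raw divergence: a numeric value or a
#'   [jackknife_divergence()] object (replicates, mean and sd are all scaled).
#' @param mito_fraction Fraction in \[0, 1\]; 0.75 reproduces the reference
#'   hominine analysis, or use [estimate_mito_fraction()].
#' @return Same type as `raw`, scaled; for jackknife objects the
#'   `correction_factor` field records the factor.
#' @export
correct_stem_divergence <- function(raw, mito_fraction = 0.75) {
  if (!is.numeric(mito_fraction) || is.na(mito_fraction) ||
      mito_fraction < 0 || mito_fraction > 1) {
    stop("mito_fraction must lie in [0, 1]")
  }
  if (inherits(raw, "jackknife_divergence")) {
    raw$replicate_estimates <- raw$replicate_estimates * mito_fraction
    raw$mean <- raw$mean * mito_fraction
    raw$sd <- raw$sd * mito_fraction
    raw$full_estimate <- raw$full_estimate * mito_fraction
    raw$correction_factor <- mito_fraction
    return(raw)
  }
  raw * mito_fraction
}

#' Estimate the mitochondrial fraction of stem mutations
#'
#' Linear unmixing of the stem's synonymous fraction: if functional-phase
#' mutations have synonymous fraction `s_f` (estimated from reference mtDNA
#' branches) and neutral nuclear-phase mutations have `s_n` (the analytic
#' neutral expectation), a stem with observed fraction `s_o = f*s_f +
#' (1-f)*s_n` has mitochondrial fraction `f = (s_o - s_n) / (s_f - s_n)`,
#' clamped to \[0, 1\].
#'
#' @param stem `branch_mutations` slice for the stem.
#' @param mito_reference `branch_mutations` slice for functional mtDNA
#'   branches.
#' @param neutral_syn Expected neutral synonymous fraction, e.g. from
#'   [expected_syn_fraction()].
#' @return Estimated fraction, or `NA` when the reference fractions do not
#'   separate (`s_f <= s_n`).
#' @export
estimate_mito_fraction <- function(stem, mito_reference, neutral_syn) {
  frac <- function(x) {
    syn <- sum(x$class == "synonymous", na.rm = TRUE)
    non <- sum(x$class == "non_synonymous", na.rm = TRUE)
    if (syn + non == 0L) return(NA_real_)
    syn / (syn + non)
  }
  s_o <- frac(stem)
  s_f <- frac(mito_reference)
  if (is.na(s_o) || is.na(s_f) || s_f <= neutral_syn) return(NA_real_)
  min(1, max(0, (s_o - neutral_syn) / (s_f - neutral_syn)))
}

#' Classify a stem divergence against reference taxa
#'
#' Places the stem's mean divergence relative to the reference distributions:
#' below every congeneric mean (`within_reference`), within the congeneric
#' range (`congeneric_level`), strictly between the largest congeneric and
#' smallest intergeneric mean (`intermediate`), within the intergeneric range
#' (`intergeneric_level`), or above all (`beyond`). Empirical overlap
#' probabilities of the jackknife distributions are reported alongside.
#'
#' @param stem A [jackknife_divergence()] for the stem.
#' @param congeneric_refs,intergeneric_refs Non-empty lists of
#'   [jackknife_divergence()] objects for within-genus and between-genus
#'   reference branches.
#' @return An object of class `divergence_classification`: list with
#'   `category`, `stem_mean`, `congeneric_means`, `intergeneric_means`,
#'   `p_stem_gt_congeneric`, `p_stem_gt_intergeneric`.
#' @export
classify_divergence <- function(stem, congeneric_refs, intergeneric_refs) {
  if (!length(congeneric_refs) || !length(intergeneric_refs)) {
    stop("need at least one reference divergence of each class")
  }
  cmeans <- vapply(congeneric_refs, function(x) x$mean, numeric(1))
  imeans <- vapply(intergeneric_refs, function(x) x$mean, numeric(1))
  s <- stem$mean
  category <-
    if (s <= min(cmeans)) "within_reference"
    else if (s <= max(cmeans)) "congeneric_level"
    else if (s < min(imeans)) "intermediate"
    else if (s <= max(imeans)) "intergeneric_level"
    else "beyond"
  pool <- function(refs) unlist(lapply(refs, `[[`, "replicate_estimates"))
  p_gt <- function(refs) {
    r <- pool(refs)
    mean(outer(stem$replicate_estimates, r, ">"))
  }
  structure(list(category = category, stem_mean = s,
                 congeneric_means = cmeans, intergeneric_means = imeans,
                 p_stem_gt_congeneric = p_gt(congeneric_refs),
                 p_stem_gt_intergeneric = p_gt(intergeneric_refs)),
            class = "divergence_classification")
}

#' @export
print.divergence_classification <- function(x, ...) {
  cat("divergence classification:", x$category, "\n")
  cat(sprintf("  stem mean: %.3f%%\n", 100 * x$stem_mean))
  cat(sprintf("  congeneric means: %s\n",
              paste(sprintf("%.3f%%", 100 * x$congeneric_means),
                    collapse = ", ")))
  cat(sprintf("  intergeneric means: %s\n",
              paste(sprintf("%.3f%%", 100 * x$intergeneric_means),
                    collapse = ", ")))
  cat(sprintf("  P(stem > congeneric) = %.3f; P(stem > intergeneric) = %.3f\n",
              x$p_stem_gt_congeneric, x$p_stem_gt_intergeneric))
  invisible(x)
}
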