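# End-to-end orchestration: simulate (or ingest) -> joint tree -> mutation
# map -> jackknife -> calibration -> Ne test -> introgression-vs-transfer
# verdict, with a JSON report and per-stage logging.

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Comma-separated values
#' become vectors; numeric and true/false values are converted.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[[i]], fixed = TRUE)) {
      stop("config: line ", i, " is not of the form key = value")
    }
    key <- trimws(sub("=.*$", "", lines[[i]]))
    val <- trimws(sub("^[^=]*=", "", lines[[i]]))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    suppressWarnings(num <- as.numeric(parts))
    if (!anyNA(num)) {
      out[[key]] <- num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      out[[key]] <- tolower(parts) == "true"
    } else {
      out[[key]] <- parts
    }
  }
  out
}

.pipeline_defaults <- function() {
  list(
    mode = "numt_transfer",
    seed = 1L,
    sequence_length = 9000,
    n_replicates = 1000,
    delete_fraction = 0.5,
    model = "k80",
    congeneric_taxa = c("Chimp", "Bonobo"),
    intergeneric_taxa = c("Human", "Gorilla"),
    candidate_taxa = "Gorilla",
    ancestral_ne = 120000,
    kappa = 8,
    calibration = "clock",  # "clock" (fixed slope) or "self" (fit to refs)
    clock_myr = 1, clock_pct = 1,
    verbose = FALSE)
}

.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }
  res
}

# Shared path between (root -> MRCA(numt)) and (root -> MRCA(candidate)).
# The two paths diverge at MRCA(numt_clade U candidate), so the shared
# segment is the path root -> that node, which is well defined even when the
# candidate intrudes into the NUMT clade (extreme introgression affinity);
# `strict` additionally enforces NUMT monophyly (the exported contract).
.shared_path <- function(t, numt_clade, candidate, strict = TRUE) {
  ntip <- ape::Ntip(t)
  stopifnot(ape::is.rooted(t))
  if (!all(numt_clade %in% t$tip.label)) {
    stop("unknown NUMT tips: ",
         paste(setdiff(numt_clade, t$tip.label), collapse = ", "))
  }
  if (!all(candidate %in% t$tip.label)) {
    stop("unknown candidate tips: ",
         paste(setdiff(candidate, t$tip.label), collapse = ", "))
  }
  if (length(intersect(numt_clade, candidate))) {
    stop("candidate set must be disjoint from the NUMT clade")
  }
  mrca_of <- function(tips) {
    ids <- match(tips, t$tip.label)
    if (length(ids) == 1L) ids else ape::getMRCA(t, ids)
  }
  monophyletic <- TRUE
  if (length(numt_clade) > 1L) {
    below <- ape::extract.clade(t, mrca_of(numt_clade))$tip.label
    monophyletic <- setequal(below, numt_clade)
    if (strict && !monophyletic) {
      stop("NUMT clade is not monophyletic on this tree (subtree holds: ",
           paste(below, collapse = ", "), ")")
    }
  }
  m12 <- mrca_of(c(numt_clade, candidate))
  root <- ntip + 1L
  p <- ape::nodepath(t, root, m12)
  if (length(p) < 2L) {
    return(list(length = 0, children = integer(0),
                monophyletic = monophyletic))
  }
  children <- p[-1L]
  idx <- match(children, t$edge[, 2])
  list(length = sum(t$edge.length[idx]), children = children,
       monophyletic = monophyletic)
}

#' Shared stem between a NUMT clade and a candidate mtDNA branch
#'
#' Length of the path shared between (root -> MRCA of the NUMT clade) and
#' (root -> MRCA of the candidate leaves). A long shared stem with one
#' reference mtDNA branch is the signature of the mtDNA-introgression
#' scenario: the NUMT then descends from the recipient's old mtDNA, which
#' last shared ancestry with that branch, while under plain NUMT transfer the
#' pseudogene clade attaches independently (shared stem 0).
#'
#' @param t Rooted ape `phylo` with branch lengths.
#' @param numt_clade Tip labels of the NUMT orthologs (must be monophyletic).
#' @param candidate_branch_leaves Non-empty tip set disjoint from
#'   `numt_clade`.
#' @return Shared stem length in substitutions/site (0 when the two attach
#'   independently at the root).
#' @export
detect_shared_stem <- function(t, numt_clade, candidate_branch_leaves) {
  .shared_path(t, numt_clade, candidate_branch_leaves)$length
}

.md5_of_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full NUMT dating pipeline
#'
#' Orchestrates every stage on either a simulated scenario or user-supplied
#' files: joint NUMT/mtDNA tree (NJ on model-corrected distances, rooted on
#' the outgroup), Fitch mutation map and stem contrast, delete-half jackknife
#' of the stem with mitochondrial-fraction correction, divergence
#' classification against congeneric/intergeneric references, linear
#' divergence-to-time calibration, the ancestral-Ne counterargument, and the
#' shared-stem scenario call.
#'
#' @param config Named list or path to a key=value file (see
#'   [read_config()]). With no input files the scenario parameters (any
#'   argument of [scenario_spec()], plus `seed`) drive a simulation; with
#'   `aln_fasta` (joint alignment) and `outgroup`/`numt_taxa` set, real data
#'   are ingested. `ne_table` points to a TSV of (taxon, Ne_nuc,
#'   max_mtdna_divergence); `calibration_tsv` to (taxon, time, divergence)
#'   split-time points (by default the calibration is fitted to the reference
#'   taxa's own split times and measured divergences).
#' @param out_dir Optional output directory for `report.json`, the alignment,
#'   trees and the divergence figure; partial outputs are removed on error.
#' @return An object of class `numt_report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  verbose <- isTRUE(cfg$verbose)
  written <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit({
      if (!is.null(attr(written, "failed"))) unlink(written)
    }, add = TRUE)
  }
  ok <- FALSE
  on.exit({
    if (!ok && length(written)) unlink(written)
  }, add = TRUE)

  # ---- stage: input ------------------------------------------------------
  simulated <- is.null(cfg$aln_fasta)
  scen <- NULL
  truth <- NULL
  if (simulated) {
    scen <- .stage("simulate", verbose, {
      spec_args <- cfg[intersect(names(cfg), names(formals(scenario_spec)))]
      if (is.null(spec_args$species_tree)) {
        base <- ps5_scenario(mode = cfg$mode, seed = cfg$seed)
        spec_args <- utils::modifyList(
          base[intersect(names(base), names(formals(scenario_spec)))],
          spec_args)
        spec_args$phylo <- NULL
        # let scenario_spec rebuild the default full-length coding map when
        # the user resizes the locus without supplying one
        if (!"coding_map" %in% names(config)) spec_args$coding_map <- NULL
      }
      spec_args$mode <- cfg$mode
      spec_args$seed <- cfg$seed
      spec <- do.call(scenario_spec, spec_args)
      simulate_scenario(spec)
    })
    truth <- scen$truth
    aln <- joint_alignment(scen)
    outgroup <- scen$spec$outgroup
    numt_taxa <- names(scen$numt$seqs)
  } else {
    aln <- .stage("ingest", verbose, {
      cm <- NULL
      if (!is.null(cfg$coding)) {
        parts <- strsplit(cfg$coding, ":", fixed = TRUE)
        cm <- do.call(rbind, lapply(parts, function(p) {
          data.frame(start = as.integer(p[1]), end = as.integer(p[2]),
                     frame = as.integer(p[3]),
                     code_id = if (length(p) >= 4) p[4] else "2")
        }))
      }
      read_fasta(cfg$aln_fasta, coding_map = cm)
    })
    outgroup <- cfg$outgroup
    numt_taxa <- if (!is.null(cfg$numt_taxa)) cfg$numt_taxa else
      grep("^NUMT_", names(aln$seqs), value = TRUE)
    if (is.null(outgroup)) stop("config must name an outgroup for rooting")
    if (!length(numt_taxa)) stop("config must list numt_taxa")
  }
  mtdna_taxa <- setdiff(names(aln$seqs), c(numt_taxa, outgroup))

  # ---- stage: tree -------------------------------------------------------
  partition <- nrow(aln$coding_map) > 0L
  trees <- .stage("tree", verbose, {
    D <- distance_matrix(aln, model = cfg$model, partition = partition)
    tr <- build_nj_tree(D)
    rooted <- root_with_outgroup(tr, outgroup)
    ingroup_rooted <- ape::drop.tip(rooted, outgroup)
    list(unrooted = tr, rooted = rooted, ingroup = ingroup_rooted)
  })

  # ---- stage: mutation map ----------------------------------------------
  coding_available <- nrow(aln$coding_map) > 0L
  mutmap <- .stage("mutmap", verbose, {
    rec <- reconstruct_ancestors(trees$rooted, aln)
    bms <- assign_branch_mutations(rec)
    t <- rec$tree
    labels <- c(t$tip.label, t$node.label)
    numt_mrca <- if (length(numt_taxa) > 1L)
      ape::getMRCA(t, match(numt_taxa, t$tip.label)) else
      match(numt_taxa, t$tip.label)
    stem_label <- labels[numt_mrca]
    clade_nodes <- if (length(numt_taxa) > 1L) {
      sub <- ape::extract.clade(t, numt_mrca)
      setdiff(c(sub$tip.label, sub$node.label), stem_label)
    } else character(0)
    stem_slice <- bms[bms$branch == stem_label, , drop = FALSE]
    inner_slice <- bms[bms$branch %in% clade_nodes, , drop = FALSE]
    mito_slice <- bms[bms$branch %in% mtdna_taxa, , drop = FALSE]
    contrast <- NULL
    if (coding_available) {
      contrast <- tryCatch(stem_contrast_test(stem_slice, inner_slice),
                           error = function(e) {
                             if (verbose) message("[mutmap] contrast skipped: ",
                                                  conditionMessage(e))
                             NULL
                           })
    } else if (verbose) {
      message("[mutmap] no coding annotation (rRNA-like locus): ",
              "stem contrast skipped, not apt for this analysis")
    }
    list(reconstruction = rec, mutations = bms, contrast = contrast,
         stem_label = stem_label, stem_slice = stem_slice,
         inner_slice = inner_slice, mito_slice = mito_slice)
  })

  # ---- stage: jackknife --------------------------------------------------
  jk <- .stage("jackknife", verbose, {
    fit <- .jackknife_fit(aln, trees$unrooted,
                          n_replicates = cfg$n_replicates,
                          delete_fraction = cfg$delete_fraction,
                          model = cfg$model, seed = cfg$seed + 1L,
                          partition = partition)
    pick <- function(target) {
      e <- .resolve_target_edge(fit$tree, target)
      est <- pmax(fit$edge_lengths[, e], 0)
      structure(list(replicate_estimates = est, n_replicates = length(est),
                     n_excluded = fit$excluded,
                     delete_fraction = cfg$delete_fraction,
                     mean = mean(est), sd = stats::sd(est),
                     full_estimate = max(fit$full[e], 0),
                     correction_factor = NA_real_, model = cfg$model),
                class = "jackknife_divergence")
    }
    # target: the branch subtending the smallest clade holding every NUMT --
    # identical to the NUMT bipartition when the orthologs are monophyletic,
    # and still defined when a reference mtDNA lineage nests inside the
    # pseudogene clade (the extreme introgression-affinity case)
    stem_taxa <- numt_taxa
    if (length(numt_taxa) > 1L) {
      mn <- ape::getMRCA(trees$rooted, match(numt_taxa,
                                             trees$rooted$tip.label))
      below <- ape::extract.clade(trees$rooted, mn)$tip.label
      if (length(below) < length(trees$rooted$tip.label)) stem_taxa <- below
    }
    stem <- pick(stem_taxa)
    refs_c <- lapply(intersect(cfg$congeneric_taxa, mtdna_taxa),
                     function(x) pick(x))
    refs_i <- lapply(intersect(cfg$intergeneric_taxa, mtdna_taxa),
                     function(x) pick(x))
    names(refs_c) <- intersect(cfg$congeneric_taxa, mtdna_taxa)
    names(refs_i) <- intersect(cfg$intergeneric_taxa, mtdna_taxa)
    list(fit = fit, stem = stem, congeneric = refs_c, intergeneric = refs_i)
  })

  # ---- stage: correction + classification --------------------------------
  corrected <- .stage("correct", verbose, {
    mito_fraction <- if (!is.null(cfg$mito_fraction)) cfg$mito_fraction else {
      f <- if (coding_available)
        estimate_mito_fraction(mutmap$stem_slice, mutmap$mito_slice,
                               expected_syn_fraction(aln$coding_map,
                                                     kappa = cfg$kappa))
      else NA_real_
      if (is.na(f)) 1 else f
    }
    list(stem = correct_stem_divergence(jk$stem, mito_fraction),
         mito_fraction = mito_fraction)
  })
  classification <- NULL
  if (length(jk$congeneric) && length(jk$intergeneric)) {
    classification <- .stage("classify", verbose,
      classify_divergence(corrected$stem, jk$congeneric, jk$intergeneric))
  }

  # ---- stage: calibration ------------------------------------------------
  timing <- .stage("calibrate", verbose, {
    cal <- if (!is.null(cfg$calibration_tsv)) {
      pts <- read_tsv_points(cfg$calibration_tsv)
      fit_calibration(pts[, setdiff(names(pts), "taxon"), drop = FALSE])
    } else if (identical(cfg$calibration, "self") && simulated) {
      # self-calibration: reference taxa's known split times vs their
      # measured pendant divergences
      phy <- scen$spec$phylo
      depth <- ape::node.depth.edgelength(phy)
      age <- max(depth[seq_len(ape::Ntip(phy))]) - depth
      ref <- c(names(jk$congeneric), names(jk$intergeneric))
      pts <- data.frame(
        time = vapply(ref, function(x) {
          tip <- match(x, phy$tip.label)
          age[phy$edge[phy$edge[, 2] == tip, 1]]
        }, numeric(1)),
        divergence = vapply(ref, function(x)
          100 * jk[[if (x %in% names(jk$congeneric)) "congeneric"
                    else "intergeneric"]][[x]]$mean, numeric(1)))
      fit_calibration(pts)
    } else {
      # default: the accepted hominine mtDNA clock, 1% divergence per Myr
      fit_calibration(data.frame(time = cfg$clock_myr,
                                 divergence = cfg$clock_pct))
    }
    est <- divergence_to_time(100 * corrected$stem$mean, cal,
                              sd = 100 * corrected$stem$sd)
    list(calibration = cal, time = est)
  })

  # ---- stage: Ne test ----------------------------------------------------
  ne <- NULL
  ne_path <- if (!is.null(cfg$ne_table)) cfg$ne_table else
    system.file("extdata", "ne_points_synthetic.tsv", package = "numtfossil")
  if (nzchar(ne_path) && file.exists(ne_path)) {
    ne <- .stage("ne_test", verbose,
      ne_extrapolation(read_tsv_points(ne_path), cfg$ancestral_ne,
                       100 * corrected$stem$mean))
  }

  # ---- stage: scenario call ----------------------------------------------
  scenario <- .stage("scenario", verbose, {
    cand <- intersect(cfg$candidate_taxa, mtdna_taxa)
    if (!length(cand)) cand <- mtdna_taxa[length(mtdna_taxa)]
    # the shared stem is the internal branch subtending (NUMT clade + the
    # candidate) -- absent when the two attach independently, long when the
    # NUMT descends from the candidate's old mtDNA (introgression signature)
    e <- tryCatch(edge_for_clade(jk$fit$tree, c(numt_taxa, cand)),
                  error = function(err) NA_integer_)
    if (!is.na(e)) {
      shared_reps <- pmax(jk$fit$edge_lengths[, e], 0)
      shared_full <- max(jk$fit$full[e], 0)
    } else {
      shared_reps <- rep(0, nrow(jk$fit$edge_lengths))
      shared_full <- 0
    }
    sd_shared <- stats::sd(shared_reps)
    call <- if (is.na(e) || shared_full <= sd_shared) {
      "numt_transfer_consistent"
    } else if (shared_full > 3 * sd_shared) {
      "introgression_consistent"
    } else "ambiguous"
    list(candidate = cand, shared_stem = shared_full,
         shared_stem_ols = shared_full, shared_sd = sd_shared,
         call = call)
  })

  # ---- report ------------------------------------------------------------
  aln_txt <- paste(names(aln$seqs), aln$seqs, sep = ":", collapse = "\n")
  report <- structure(list(
    stem_divergence = list(
      raw = jk$stem$mean, raw_sd = jk$stem$sd,
      mito_fraction = corrected$mito_fraction,
      corrected = corrected$stem$mean, corrected_sd = corrected$stem$sd,
      corrected_pct = 100 * corrected$stem$mean,
      model = cfg$model, n_replicates = jk$stem$n_replicates,
      n_excluded = jk$stem$n_excluded),
    time_estimate = list(myr = timing$time$time, sd = timing$time$sd,
                         slope_pct_per_myr = timing$calibration$slope),
    stem_contrast = if (!is.null(mutmap$contrast)) list(
      syn_fraction_stem = mutmap$contrast$syn_fraction_stem,
      syn_fraction_branches = mutmap$contrast$syn_fraction_others,
      p_value = mutmap$contrast$p_value) else NULL,
    divergence_category = if (!is.null(classification))
      classification$category else NULL,
    ne_verdict = if (!is.null(ne)) list(
      verdict = ne$verdict, predicted = ne$predicted,
      pi_upper = ne$pi_upper, correlation = ne$correlation,
      p_value = ne$p_value) else NULL,
    scenario = list(call = scenario$call,
                    shared_stem = scenario$shared_stem_ols,
                    shared_stem_sd = scenario$shared_sd,
                    candidate = scenario$candidate),
    truth = if (!is.null(truth)) list(
      mode = truth$mode,
      true_stem_divergence = truth$true_stem_divergence) else NULL,
    provenance = list(
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("numtfossil")),
      n_taxa = length(aln$seqs), n_columns = aln$length,
      input_md5 = .md5_of_text(aln_txt),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "numt_report")
  report$objects <- list(trees = trees, jackknife = jk,
                         mutmap = mutmap, corrected = corrected,
                         classification = classification,
                         calibration = timing$calibration, ne = ne,
                         alignment = aln)

  if (!is.null(out_dir)) {
    .stage("write", verbose, {
      f1 <- file.path(out_dir, "report.json")
      out <- report[setdiff(names(report), "objects")]
      jsonlite::write_json(out, f1, auto_unbox = TRUE, digits = NA,
                           null = "null")
      f2 <- file.path(out_dir, "joint_alignment.fasta")
      write_fasta(aln, f2)
      f3 <- file.path(out_dir, "joint_tree.nwk")
      write_newick(trees$rooted, f3)
      f4 <- file.path(out_dir, "divergence_distributions.png")
      grDevices::png(f4, width = 800, height = 500)
      plot(report)
      grDevices::dev.off()
      written <<- c(f1, f2, f3, f4)
    })
  }
  ok <- TRUE
  report
}

#' @export
print.numt_report <- function(x, ...) {
  cat("NUMT dating report\n")
  cat(sprintf("  stem divergence: raw %.2f%% +/- %.2f%%, corrected (x%.3f) %.2f%% +/- %.2f%%\n",
              100 * x$stem_divergence$raw, 100 * x$stem_divergence$raw_sd,
              x$stem_divergence$mito_fraction,
              100 * x$stem_divergence$corrected,
              100 * x$stem_divergence$corrected_sd))
  cat(sprintf("  time since precursor divergence: %.2f +/- %.2f Myr (clock %.3f%%/Myr)\n",
              x$time_estimate$myr, x$time_estimate$sd,
              x$time_estimate$slope_pct_per_myr))
  if (!is.null(x$stem_contrast)) {
    cat(sprintf("  stem contrast: %.0f%% vs %.0f%% synonymous, p = %s\n",
                100 * x$stem_contrast$syn_fraction_stem,
                100 * x$stem_contrast$syn_fraction_branches,
                format.pval(x$stem_contrast$p_value, digits = 3)))
  }
  if (!is.null(x$divergence_category)) {
    cat("  divergence category:", x$divergence_category, "\n")
  }
  if (!is.null(x$ne_verdict)) {
    cat(sprintf("  ancestral-Ne alternative: %s (predicted %.2f%%, PI upper %.2f%%)\n",
                x$ne_verdict$verdict, x$ne_verdict$predicted,
                x$ne_verdict$pi_upper))
  }
  cat(sprintf("  scenario: %s (shared stem %.4f +/- %.4f with %s)\n",
              x$scenario$call, x$scenario$shared_stem,
              x$scenario$shared_stem_sd,
              paste(x$scenario$candidate, collapse = "+")))
  if (!is.null(x$truth)) {
    cat(sprintf("  [simulation truth: mode %s, stem %.4f subst/site]\n",
                x$truth$mode, x$truth$true_stem_divergence))
  }
  invisible(x)
}

#' @export
summary.numt_report <- function(object, ...) {
  c(stem_pct = 100 * object$stem_divergence$corrected,
    stem_sd_pct = 100 * object$stem_divergence$corrected_sd,
    time_myr = object$time_estimate$myr,
    time_sd = object$time_estimate$sd,
    contrast_p = if (!is.null(object$stem_contrast))
      object$stem_contrast$p_value else NA_real_,
    shared_stem = object$scenario$shared_stem)
}

#' @export
plot.numt_report <- function(x, ...) {
  jk <- x$objects$jackknife
  corrected <- x$objects$corrected
  dens <- list(stem = stats::density(100 * corrected$stem$replicate_estimates))
  for (nm in names(jk$congeneric)) {
    dens[[nm]] <- stats::density(100 * jk$congeneric[[nm]]$replicate_estimates)
  }
  for (nm in names(jk$intergeneric)) {
    dens[[nm]] <- stats::density(100 * jk$intergeneric[[nm]]$replicate_estimates)
  }
  xr <- range(unlist(lapply(dens, `[[`, "x")))
  yr <- range(unlist(lapply(dens, `[[`, "y")))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "% divergence",
                 ylab = "density",
                 main = "Jackknife divergence distributions")
  cols <- c("turquoise3", rep(c("grey40", "purple", "darkgreen", "orange",
                                "steelblue"), length.out = length(dens) - 1))
  for (i in seq_along(dens)) {
    graphics::lines(dens[[i]], col = cols[i], lwd = if (i == 1) 3 else 1.5)
  }
  graphics::legend("topright", legend = names(dens), col = cols,
                   lwd = c(3, rep(1.5, length(dens) - 1)), bty = "n")
  invisible(x)
}
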