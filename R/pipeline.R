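#' @include io.R network.R metrics.R comparison.R mrcc.R module-stats.R
NULL

#' Run the full covariance-network pipeline
#'
#' Orchestrates the complete analysis over a set of group uptake tables:
#' per group, the covariance network, random-shift edge p-values,
#' thresholded networks at each configured level, nodal metrics, degree-
#' and strength-based hubs, and the MRCC consensus; per unordered group
#' pair, the KS and edgewise permutation comparison; finally, module-mean
#' SUVR ANOVA (with Tukey-Kramer post hocs for significant factors) against
#' the reference partition - by convention the consensus partition of the
#' reference group (default: the first 4-month WT male group present, the
#' study's choice). All results are written under \code{out_dir} as
#' labelled CSV (matrices), two-column CSV (partitions), JSON (hierarchy)
#' and a plain-text log recording the seed and configuration of every
#' stochastic stage. A rerun with the same seed is bit-identical.
#'
#' @param tables named list of \linkS4class{UptakeTable}s sharing one
#'   region set.
#' @param config a \linkS4class{PipelineConfig}.
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list with per-group results, comparisons, and
#'   ANOVA results per module of the reference partition.
#' @export
runPipeline <- function(tables, config = pipelineConfig(), out_dir) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, groupId, character(1))
  ref_regions <- regionLabels(tables[[1L]])
  for (tab in tables[-1L])
    .check_same_regions(ref_regions, regionLabels(tab), "tables")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.txt")
  log_lines <- c("covnet pipeline log",
                 sprintf("rng_seed: %d", config@rngSeed),
                 sprintf("n_null_permutations: %d", config@nNullPermutations),
                 sprintf("n_mrcc_partitions: %d", config@nMrccPartitions),
                 sprintf("mrcc_alpha: %g | mrcc_sampling: %s",
                         config@mrccAlpha, config@mrccSampling),
                 sprintf("threshold_p_levels: %s",
                         paste(config@thresholdPLevels, collapse = ", ")),
                 sprintf("hub_quantile: %g | fdr_q: %g | ss_type: %s",
                         config@hubQuantile, config@fdrQ, config@ssType),
                 sprintf("groups (%d): %s", length(tables),
                         paste(names(tables), collapse = ", ")))

  n_groups <- length(tables)
  seeds <- .derive_seeds(config@rngSeed,
                         2L * n_groups + n_groups * (n_groups - 1L) / 2L)
  si <- 0L
  take_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  ## ---- per-group stage -------------------------------------------------
  groups <- list()
  for (g in names(tables)) {
    tab <- tables[[g]]
    gdir <- file.path(out_dir, "groups", g)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    net <- covarianceNetwork(tab)
    s_edge <- take_seed()
    net@edgeP <- edgeSignificance(tab, config@nNullPermutations, s_edge)
    writeMatrix(edgeWeights(net), file.path(gdir, "covariance.csv"))
    writeMatrix(edgePValues(net), file.path(gdir, "edge_pvalues.csv"))
    thr <- list()
    for (lev in config@thresholdPLevels) {
      tn <- thresholdNetwork(net, lev)
      thr[[as.character(lev)]] <- tn
      writeMatrix(edgeWeights(tn),
                  file.path(gdir, sprintf("thresholded_p%s.csv", lev)))
      met <- nodalMetrics(tn)
      write.csv(met, file.path(gdir, sprintf("metrics_p%s.csv", lev)),
                row.names = FALSE, quote = FALSE)
      writeLines(identifyHubs(tn, config@hubQuantile, mode = "degree"),
                 file.path(gdir, sprintf("hubs_degree_p%s.txt", lev)))
      writeLines(identifyHubs(tn, config@hubQuantile, mode = "strength"),
                 file.path(gdir, sprintf("hubs_strength_p%s.txt", lev)))
    }
    writeLines(identifyHubs(net, config@hubQuantile, mode = "strength"),
               file.path(gdir, "hubs_strength_unthresholded.txt"))
    s_mrcc <- take_seed()
    cons <- mrcc(net, n_partitions = config@nMrccPartitions,
                 alpha = config@mrccAlpha, seed = s_mrcc,
                 sampling = config@mrccSampling)
    writePartition(consensusPartition(cons),
                   file.path(gdir, "consensus_partition.csv"))
    writeMatrix(coassignment(cons), file.path(gdir, "coassignment.csv"))
    hier <- lapply(hierarchyPartitions(cons), function(p)
      as.integer(p@labels))
    write_json(list(region_labels = regionLabels(cons),
                    gamma_range = cons@gammaRange,
                    alpha = cons@alpha,
                    levels = hier),
               file.path(gdir, "hierarchy.json"), digits = NA,
               auto_unbox = FALSE)
    log_lines <- c(log_lines,
                   sprintf("group %s: edge_seed=%d mrcc_seed=%d n=%d consensus_k=%d",
                           g, s_edge, s_mrcc, nAnimals(tab),
                           nCommunities(cons)))
    groups[[g]] <- list(network = net, thresholded = thr, consensus = cons)
  }

  ## ---- pairwise stage ---------------------------------------------------
  comparisons <- list()
  if (n_groups >= 2L) {
    pdir <- file.path(out_dir, "pairs")
    dir.create(pdir, showWarnings = FALSE)
    pairs <- combn(names(tables), 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      cmp <- compareGroups(tables[[a]], tables[[b]], config,
                           seed = take_seed())
      key <- paste(a, b, sep = "__vs__")
      writeMatrix(cmp@edgeP, file.path(pdir, paste0(key, "_edge_p.csv")))
      writeMatrix(cmp@edgeQ, file.path(pdir, paste0(key, "_edge_q.csv")))
      summ <- data.frame(
        group_a = a, group_b = b,
        ks_D = cmp@ksStat, ks_p = cmp@ksP,
        n_perm = cmp@nPerm,
        edges_p05 = sum(.lower_tri(cmp@sigUncorrected)),
        edges_fdr = sum(.lower_tri(cmp@sigFdr)),
        stringsAsFactors = FALSE)
      write.csv(summ, file.path(pdir, paste0(key, "_summary.csv")),
                row.names = FALSE, quote = FALSE)
      write.csv(cmp@ksNodal, file.path(pdir, paste0(key, "_ks_nodal.csv")),
                row.names = FALSE, quote = FALSE)
      comparisons[[key]] <- cmp
    }
  } else {
    warning("single group supplied; comparison stage skipped")
    log_lines <- c(log_lines, "comparison stage skipped (single group)")
  }

  ## ---- module-mean ANOVA against the reference partition -----------------
  anovas <- list()
  if (n_groups >= 2L) {
    ref_name <- .pick_reference_group(tables)
    reference <- consensusPartition(groups[[ref_name]]$consensus)
    adir <- file.path(out_dir, "module_anova")
    dir.create(adir, showWarnings = FALSE)
    writePartition(reference, file.path(adir, "reference_partition.csv"))
    can_fit <- length(unique(vapply(tables, function(t)
      metadata(t)$genotype, character(1)))) >= 2L &&
      length(unique(vapply(tables, function(t)
        metadata(t)$sex, character(1)))) >= 2L &&
      length(unique(vapply(tables, function(t)
        metadata(t)$age_months, numeric(1)))) >= 2L
    if (can_fit) {
      for (m in seq_len(nCommunities(reference))) {
        vals <- moduleMeanSUVR(tables, reference, m)
        av <- nwayAnova(vals, ss_type = config@ssType)
        write.csv(av@table,
                  file.path(adir, sprintf("module%d_anova.csv", m)),
                  row.names = FALSE, quote = FALSE)
        ph <- list()
        for (f in c("age", "sex", "genotype")) {
          prow <- av@table[av@table$term == f, ]
          if (nrow(prow) && !is.na(prow$p.value) && prow$p.value < 0.05) {
            ph[[f]] <- tukeyKramer(av, f)
            write.csv(ph[[f]],
                      file.path(adir, sprintf("module%d_posthoc_%s.csv", m, f)),
                      row.names = FALSE, quote = FALSE)
          }
        }
        anovas[[paste0("module", m)]] <- list(anova = av, posthoc = ph)
      }
      log_lines <- c(log_lines,
                     sprintf("module ANOVA: reference group %s (%d modules)",
                             ref_name, nCommunities(reference)))
    } else {
      log_lines <- c(log_lines,
                     "module ANOVA skipped (factors need >= 2 levels each)")
    }
  }

  writeLines(log_lines, log_path)
  invisible(list(groups = groups, comparisons = comparisons,
                 anovas = anovas))
}

## The study's reference for module extraction is the 4-month male WT
## partition; fall back to the first table when no such group exists.
.pick_reference_group <- function(tables) {
  for (g in names(tables)) {
    md <- metadata(tables[[g]])
    if (identical(md$genotype, "WT") && identical(md$sex, "M") &&
        identical(md$age_months, 4)) return(g)
  }
  names(tables)[1L]
}
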