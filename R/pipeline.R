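## End-to-end orchestration: segment -> consensus -> NMI test -> shape ->
## metrics -> group statistics -> correlations -> classification, with a
## single master seed fanned out to per-stage seeds (seed + stage index).

#' Pipeline configuration
#'
#' @param k,alpha,beta,max_iter,tol Segmentation settings (see
#'   \code{\link{clustering_config}}).
#' @param n_perm_metrics Permutations for the two-group metric tests
#'   (default 2000).
#' @param n_perm_nmi Permutations for the NMI group test (default 1000; 0
#'   skips the test).
#' @param q FDR level (default 0.05).
#' @param n_folds,n_repeats Cross-validation layout (defaults 3 and 20).
#' @param max_fixels Fixels retained per voxel (default 3).
#' @param seed Master seed; stage s uses \code{seed + s}.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(k = 7, alpha = 0.5, beta = 85, max_iter = 300,
                            tol = 1e-6, n_perm_metrics = 2000,
                            n_perm_nmi = 1000, q = 0.05, n_folds = 3,
                            n_repeats = 20, max_fixels = 3, seed = 1L) {
  structure(list(k = k, alpha = alpha, beta = beta, max_iter = max_iter,
                 tol = tol, n_perm_metrics = n_perm_metrics,
                 n_perm_nmi = n_perm_nmi, q = q, n_folds = n_folds,
                 n_repeats = n_repeats, max_fixels = max_fixels,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Subjects x (region x metric) table of aggregated metrics
#'
#' For every subject, fixels (FD, with FC/FDC from the subject's deformation
#' field) and tensor metrics (FA, MD, AD, RD) are aggregated as means over
#' each region: the nuclei of the supplied labeling, optionally each pathway
#' tube, and the whole thalamus. Volume (voxel count) is included per
#' nucleus region.
#'
#' @param cohort A \code{synthetic_cohort} (or compatible list).
#' @param labelings List (one per subject) of 3D label arrays defining the
#'   nucleus regions; pass the same array repeatedly for a population-level
#'   parcellation.
#' @param include_pathways Aggregate along pathway tubes too (default TRUE
#'   when the cohort has pathways).
#' @param config A \code{\link{pipeline_config}} (fixel settings).
#' @param fixel_tables Optional precomputed per-subject fixel tables from
#'   \code{\link{cohort_fixel_tables}} (they do not depend on the labeling,
#'   so they can be shared across parcellation modes).
#' @return Numeric matrix (subjects x columns) with attribute
#'   \code{"colinfo"} (region, metric, region_type).
#' @export
compute_metric_table <- function(cohort, labelings,
                                 include_pathways = !is.null(
                                   cohort$template$pathways),
                                 config = pipeline_config(),
                                 fixel_tables = NULL) {
  if (is.null(fixel_tables))
    fixel_tables <- cohort_fixel_tables(cohort, include_pathways, config)
  n <- length(cohort$subjects)
  k <- max(cohort$template$parcellation)
  pw <- cohort$template$pathways
  regions <- data.frame(
    region = paste0("nucleus", seq_len(k)),
    region_type = "nucleus")
  if (include_pathways && !is.null(pw))
    regions <- rbind(regions, data.frame(
      region = paste0("pathway", pw$table$pathway),
      region_type = "pathway"))
  regions <- rbind(regions, data.frame(region = "whole",
                                       region_type = "whole"))
  metrics <- c("fd", "fc", "fdc", "fa", "md", "ad", "rd", "volume")
  colinfo <- do.call(rbind, lapply(seq_len(nrow(regions)), function(r)
    data.frame(region = regions$region[r], metric = metrics,
               region_type = regions$region_type[r])))
  out <- matrix(NA_real_, n, nrow(colinfo))
  colnames(out) <- paste(colinfo$region, colinfo$metric, sep = "_")
  rownames(out) <- vapply(cohort$subjects, `[[`, character(1), "id")
  dims <- dim(cohort$template$parcellation)
  for (s in seq_len(n)) {
    sub <- cohort$subjects[[s]]
    lab <- parcellation_labels(labelings[[s]])
    full_mask <- sub$mask
    if (include_pathways && !is.null(pw)) full_mask <- full_mask |
      (pw$labels > 0)
    fx <- fixel_tables[[s]]
    flin <- fx$i + dims[1] * (fx$j - 1L + dims[2] * (fx$k - 1L))
    tm <- tensor_metrics(matrix(sub$tensor, ncol = 3)[which(full_mask), ,
                                                      drop = FALSE])
    tlin <- which(full_mask)
    region_sel <- function(r) {
      if (regions$region_type[r] == "nucleus")
        which(lab == as.integer(sub("nucleus", "", regions$region[r])))
      else if (regions$region_type[r] == "pathway")
        which(pw$labels == as.integer(sub("pathway", "", regions$region[r])))
      else which(lab > 0)
    }
    for (r in seq_len(nrow(regions))) {
      sel <- region_sel(r)
      infx <- flin %in% sel
      intm <- tlin %in% sel
      base <- (r - 1) * length(metrics)
      out[s, base + 1] <- if (any(infx)) mean(fx$fd[infx]) else NA
      out[s, base + 2] <- if (any(infx)) mean(fx$fc[infx]) else NA
      out[s, base + 3] <- if (any(infx)) mean(fx$fdc[infx]) else NA
      out[s, base + 4] <- mean(tm$fa[intm])
      out[s, base + 5] <- mean(tm$md[intm])
      out[s, base + 6] <- mean(tm$ad[intm])
      out[s, base + 7] <- mean(tm$rd[intm])
      out[s, base + 8] <- length(sel)
    }
  }
  attr(out, "colinfo") <- colinfo
  out
}

#' Per-subject fixel tables for a cohort
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param include_pathways Include pathway-tube voxels (default TRUE when
#'   present).
#' @param config A \code{\link{pipeline_config}}.
#' @return List of fixel tables (one per subject), FC/FDC attached from each
#'   subject's deformation field.
#' @export
cohort_fixel_tables <- function(cohort,
                                include_pathways = !is.null(
                                  cohort$template$pathways),
                                config = pipeline_config()) {
  pw <- cohort$template$pathways
  lapply(cohort$subjects, function(sub) {
    full_mask <- sub$mask
    if (include_pathways && !is.null(pw)) full_mask <- full_mask |
      (pw$labels > 0)
    fixel_table(sub$fod, full_mask, cohort$basis, field = sub$field,
                max_fixels = config$max_fixels)
  })
}

#' Run the full individualized-parcellation analysis on a cohort
#'
#' Stages: (1) hybrid FOD/spatial k-means segmentation of every subject on
#' the template mask, labels matched across subjects; (2) consensus
#' partitions per group (HC vs patients) and over all subjects (the
#' population-level parcellation); (3) NMI group-reallocation permutation
#' test; (4) log-Jacobian shape statistics per nucleus with
#' covariate-adjusted one-sample tests (FDR over nuclei) and volumetric
#' ratios; (5) metric tables under the individual and population
#' parcellations; (6) covariate-adjusted two-group permutation tests with
#' BH-FDR per metric family; (7) partial correlations of CRS-R with nucleus
#' volume change and FD among patients; (8) sparse logistic classification
#' (DOC vs HC, MCS vs VS) under individual / population / whole-thalamus
#' features. Fully deterministic given \code{config$seed}.
#'
#' @param cohort A \code{synthetic_cohort} or a cohort directory path.
#' @param config A \code{\link{pipeline_config}}.
#' @param reference Optional 3D label volume (e.g. an external atlas on the
#'   template grid) used only to put all subject parcellations into a common
#'   label order; by default the first subject's parcellation anchors the
#'   ordering.
#' @param verbose Log stage progress to stderr (default FALSE).
#' @return List of class \code{thalparc_report}; see \code{$summary} for the
#'   JSON-ready digest.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         reference = NULL, verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  say <- function(...) if (verbose) message("[thalparc] ", ...)
  meta <- cohort$meta
  doc <- meta$group %in% c("MCS", "VS")
  covs <- meta[, c("age", "icv", "doc_duration")]
  ## for the two-group tests the DOC-duration covariate is undefined for
  ## controls; it is imputed at the patient mean so it adjusts within-patient
  ## variance without acting as a group indicator
  covs_grp <- covs
  covs_grp$doc_duration[!doc] <- mean(covs$doc_duration[doc])
  cc <- clustering_config(k = config$k, alpha = config$alpha,
                          beta = config$beta, max_iter = config$max_iter,
                          tol = config$tol, seed = config$seed)

  say("stage 1: segmentation (", length(cohort$subjects), " subjects)")
  ## all subjects share the template mask, so the spatial-only hierarchical
  ## initialization is computed once
  mask1 <- cohort$subjects[[1]]$mask
  pos1 <- which(mask1, arr.ind = TRUE) - 1
  init_memb <- stats::cutree(stats::hclust(stats::dist(pos1),
                                           method = "ward.D2"), k = config$k)
  parcs <- lapply(cohort$subjects, function(s)
    kmeans_segment(s$fod, s$mask, cc, init = init_memb))
  anchor <- if (is.null(reference)) parcs[[1]] else reference
  parcs <- lapply(parcs, match_labels, reference = anchor)

  say("stage 2: consensus partitions")
  cons_hc <- consensus_partition(parcs[!doc], k = config$k)
  cons_doc <- consensus_partition(parcs[doc], k = config$k)
  cons_all <- consensus_partition(parcs, k = config$k)
  cons_all <- match_labels(cons_all, anchor)
  cons_hc <- match_labels(cons_hc, anchor)

  nmi_res <- NULL
  if (config$n_perm_nmi > 0) {
    say("stage 3: NMI permutation test")
    nmi_res <- nmi_permutation_test(parcs[!doc], parcs[doc],
                                    n_perm = config$n_perm_nmi,
                                    seed = config$seed + 1L, k = config$k)
  }

  say("stage 4: shape statistics")
  k <- config$k
  logjs <- lapply(cohort$subjects, function(s)
    log_jacobian(s$field, mask = s$mask))
  logj_means <- t(vapply(logjs, nucleus_shape_stats, numeric(k),
                         parcellation = cons_hc))
  ## warp-integrated nucleus volume ratio (continuous, sub-voxel aware):
  ## mean local volume-change factor over the nucleus
  vol_jac <- t(vapply(logjs, function(lj)
    nucleus_shape_stats(exp(lj), cons_hc), numeric(k)))
  vol_ratio <- t(vapply(seq_along(parcs), function(i)
    volume_ratio_change(parcs[[i]], cons_hc), numeric(k)))
  shape_tests <- lapply(seq_len(k), function(j)
    tryCatch(covariate_adjusted_one_sample_test(logj_means[doc, j],
                                                covs[doc, , drop = FALSE]),
             error = function(e) list(estimate = NA_real_, t = NA_real_,
                                      df = NA_integer_, p.value = NA_real_)))
  shape_p <- vapply(shape_tests, `[[`, numeric(1), "p.value")
  shape_fdr <- list(q.values = rep(NA_real_, k),
                    significant = rep(FALSE, k))
  if (any(is.finite(shape_p))) {
    ok <- is.finite(shape_p)
    f <- fdr_bh(shape_p[ok], config$q)
    shape_fdr$q.values[ok] <- f$q.values
    shape_fdr$significant[ok] <- f$significant
  }
  shape <- data.frame(
    nucleus = seq_len(k),
    mean_logj_doc = colMeans(logj_means[doc, , drop = FALSE]),
    mean_logj_hc = colMeans(logj_means[!doc, , drop = FALSE]),
    t = vapply(shape_tests, `[[`, numeric(1), "t"),
    p = shape_p, q.value = shape_fdr$q.values,
    significant = shape_fdr$significant)

  say("stage 5: metric tables")
  lab_ind <- lapply(parcs, parcellation_labels)
  lab_pop <- rep(list(parcellation_labels(cons_all)),
                 length(cohort$subjects))
  fxt <- cohort_fixel_tables(cohort, config = config)
  mt_ind <- compute_metric_table(cohort, lab_ind, config = config,
                                 fixel_tables = fxt)
  mt_pop <- compute_metric_table(cohort, lab_pop, config = config,
                                 fixel_tables = fxt)

  say("stage 6: group permutation tests")
  ci <- attr(mt_ind, "colinfo")
  testable <- ci$metric != "volume" | ci$region_type == "nucleus"
  grp2 <- factor(ifelse(doc, "DOC", "HC"), levels = c("DOC", "HC"))
  stats_ind <- group_permutation_test(
    mt_ind[, testable, drop = FALSE], grp2, covs_grp,
    n_perm = config$n_perm_metrics, seed = config$seed + 2L, q = config$q,
    families = paste(ci$metric[testable], ci$region_type[testable]))

  say("stage 7: CRS-R partial correlations (patients)")
  pc_cov <- covs[doc, , drop = FALSE]
  crs <- meta$crs_r_total[doc]
  safe_pc <- function(x, y, cv) tryCatch(partial_correlation(x, y, cv),
                                         error = function(e)
                                           list(r = NA_real_,
                                                p.value = NA_real_))
  correlations <- do.call(rbind, lapply(seq_len(k), function(j) {
    fd_col <- paste0("nucleus", j, "_fd")
    r_vol <- safe_pc(crs, vol_jac[doc, j] - 1, pc_cov)
    r_fd <- safe_pc(crs, mt_ind[doc, fd_col], pc_cov)
    data.frame(nucleus = j,
               r_volume = r_vol$r, p_volume = r_vol$p.value,
               r_fd = r_fd$r, p_fd = r_fd$p.value)
  }))

  say("stage 8: classification")
  tasks <- list(doc_vs_hc = grp2,
                mcs_vs_vs = factor(as.character(meta$group[doc]),
                                   levels = c("MCS", "VS")))
  feats <- list(individual = build_features(mt_ind, "regions"),
                population = build_features(mt_pop, "regions"),
                whole = build_features(mt_pop, "whole"))
  classification <- lapply(names(tasks), function(tn) {
    y <- tasks[[tn]]
    keep <- if (tn == "doc_vs_hc") rep(TRUE, nrow(meta)) else doc
    lapply(feats, function(X)
      tryCatch(crossval_classify(X[keep, , drop = FALSE], y,
                                 n_folds = config$n_folds,
                                 n_repeats = config$n_repeats,
                                 seed = config$seed + 3L),
               error = function(e)
                 structure(list(accuracies = numeric(0), mean = NA_real_,
                                sd = NA_real_, predictions = NULL,
                                n_folds = config$n_folds,
                                n_repeats = config$n_repeats,
                                levels = levels(y), seed = config$seed + 3L,
                                failed = conditionMessage(e)),
                           class = "thalparc_cv")))
  })
  names(classification) <- names(tasks)
  embedding <- pca_embed(feats$individual, 3)

  summary <- list(
    provenance = list(tool = "thalparc",
                      version = as.character(utils::packageVersion("thalparc")),
                      seed = config$seed,
                      config = unclass(config)),
    n_subjects = nrow(meta),
    groups = as.list(table(meta$group)),
    nmi = if (is.null(nmi_res)) NULL else list(
      observed = nmi_res$observed, p = nmi_res$p.value,
      ci = nmi_res$ci, significant = nmi_res$significant),
    shape = shape,
    metric_tests = as.data.frame(stats_ind),
    correlations = correlations,
    classification = lapply(classification, function(task)
      lapply(task, function(cv) list(mean = cv$mean, sd = cv$sd))),
    pca_explained = embedding$explained)

  structure(list(parcellations = parcs, consensus = list(
    hc = cons_hc, doc = cons_doc, all = cons_all),
    nmi_test = nmi_res, logj_means = logj_means, vol_jac = vol_jac,
    vol_ratio = vol_ratio,
    shape = shape, metric_tables = list(individual = mt_ind,
                                        population = mt_pop),
    stats = stats_ind, correlations = correlations,
    classification = classification, embedding = embedding,
    summary = summary, config = config),
    class = "thalparc_report")
}

#' @export
print.thalparc_report <- function(x, ...) {
  cat("Individualized thalamic parcellation report\n")
  if (!is.null(x$nmi_test))
    cat(sprintf("  consensus NMI (HC vs DOC): %.3f (p = %.3g)\n",
                x$nmi_test$observed, x$nmi_test$p.value))
  sig <- x$shape$nucleus[x$shape$significant]
  cat("  nuclei with significant shape change:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  cat(sprintf("  FD columns significant after FDR: %d\n",
              sum(x$stats$significant[grepl("_fd$", x$stats$column)])))
  for (tn in names(x$classification))
    cat(sprintf("  %s accuracy: %s\n", tn,
                paste(sprintf("%s %.0f%%", names(x$classification[[tn]]),
                              100 * vapply(x$classification[[tn]],
                                           `[[`, numeric(1), "mean")),
                      collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes \code{summary.json} plus TSV tables (shape, metric tests,
#' correlations) into a directory.
#'
#' @param report A \code{thalparc_report}.
#' @param dir Output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$shape, file.path(dir, "shape.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$stats),
                     file.path(dir, "metric_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$correlations, file.path(dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
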