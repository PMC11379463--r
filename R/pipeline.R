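#' Run the full clone-inference workflow
#'
#' Orchestrates the three stages of the method: (i) fixed filtering and the
#' six-subset filtering grid, (ii) bootstrapped weighted NMF on every
#' (subset, K) candidate, (iii) orthogonality-score selection, per-cell
#' clone assignment, healthy/cancer factor labelling from cell-type priors
#' and clone-associated variant extraction. Every random draw is seeded
#' deterministically from \code{seed} and the (subset, K, replicate) key,
#' so reruns with an identical configuration are bit-identical and adding
#' K values does not perturb existing candidates.
#'
#' A model failure (every factor containing known-healthy cells, or
#' known-cancer cells in fallback mode) is reported through
#' \code{assignment@success == FALSE}, not an error. When no cell types are
#' available the pipeline completes with factors left \code{"unlabelled"}
#' and success undefined. Samples whose known-healthy cells are below 3\%
#' of all cells trigger a warning: such samples fall below the inclusion
#' threshold the method assumes for a recoverable healthy population.
#'
#' @param counts an \linkS4class{AlleleCounts} with annotation flags set
#'   (>= 2 cells; >= 10 variants must survive the fixed filters).
#' @param k_grid factor numbers to try (default \code{2:4}).
#' @param n_iter,n_bootstrap,subsample_fraction fitting and bootstrap
#'   controls (defaults 100, 50, 0.9).
#' @param maf_thresholds filtering grid MAF thresholds
#'   (default \code{c(0.02, 0.05, 0.10)}).
#' @param healthy_types,cancer_types known cell-type name lists used to
#'   label factors.
#' @param undetermined_threshold,variant_diff_threshold,coverage_threshold
#'   assignment and variant-selection thresholds (defaults 0.3, 0.3, 0.2).
#' @param contamination_tolerance,min_prior_cells factor-labelling controls
#'   (defaults 0.01, 20).
#' @param seed master seed.
#' @param out_dir optional directory for TSV exports and a run log.
#' @param verbose emit one log line per stage (default TRUE).
#' @return List with elements \code{selection}
#'   (\linkS4class{SelectionResult}), \code{assignment}
#'   (\linkS4class{CloneAssignment}), \code{variants} (the
#'   clone-associated variant table, NULL if fewer than two clones),
#'   \code{subsets}, and \code{config}.
#' @export
runCloneNMF <- function(counts,
                        k_grid = 2:4,
                        n_iter = 100,
                        n_bootstrap = 50,
                        subsample_fraction = 0.9,
                        maf_thresholds = c(0.02, 0.05, 0.10),
                        healthy_types = character(),
                        cancer_types = character(),
                        undetermined_threshold = 0.3,
                        variant_diff_threshold = 0.3,
                        coverage_threshold = 0.2,
                        contamination_tolerance = 0.01,
                        min_prior_cells = 20,
                        seed = 1,
                        out_dir = NULL,
                        verbose = TRUE) {
    stopifnot(all(k_grid >= 2),
              undetermined_threshold >= 0, undetermined_threshold <= 1,
              variant_diff_threshold >= 0, variant_diff_threshold <= 1,
              coverage_threshold >= 0, coverage_threshold <= 1)
    if (ncol(counts) < 2) stop("need at least 2 cells")

    fixed <- applyFixedFilters(counts)
    if (sum(fixed) < 10)
        stop("fewer than 10 variants survive the fixed filters (",
             sum(fixed), "); the dataset cannot support clone inference")
    .log_stage(verbose, "fixed filters: %d/%d variants retained",
               sum(fixed), nrow(counts))

    subsets <- makeVariantSubsets(counts, maf_thresholds,
                                  fixed_mask = fixed)
    skipped <- character()
    results <- list()
    for (sub in subsets) {
        n_sub <- sum(sub@mask)
        if (n_sub < 10 || n_sub < max(k_grid)) {
            skipped <- c(skipped, sub@name)
            .log_stage(verbose, "subset %s skipped (%d variants)",
                       sub@name, n_sub)
            next
        }
        obs <- buildObservationMatrices(counts, sub)
        for (K in k_grid) {
            .log_stage(verbose,
                       "bootstrapping subset %s (%d variants), K = %d",
                       sub@name, n_sub, K)
            boot <- bootstrapWNMF(
                obs, K = K, n_bootstrap = n_bootstrap,
                fraction = subsample_fraction, n_iter = n_iter,
                seed = deriveSeed(seed, sub@name, K))
            results[[sprintf("%s_K%d", sub@name, K)]] <-
                list(subset = sub, K = K, boot = boot)
        }
    }
    if (length(results) == 0)
        stop("every variant subset was too small to fit")

    selection <- selectBestModel(results)
    .log_stage(verbose, "selected %s (s = %.4f)", selection@best,
               max(selection@scores$score))

    assignment <- assignCells(selection@chosen,
                              threshold = undetermined_threshold)

    types <- cellTypes(counts)
    have_types <- !all(is.na(types))
    if (have_types && length(healthy_types)) {
        frac_healthy <- mean(types %in% healthy_types)
        if (frac_healthy < 0.03)
            warning(sprintf(
                "known healthy cells are %.1f%% of the sample, below the ",
                100 * frac_healthy),
                "3% inclusion threshold; labelling may be unreliable")
    }
    if (have_types && (length(healthy_types) || length(cancer_types)) &&
        any(types %in% c(healthy_types, cancer_types))) {
        assignment <- labelFactors(
            assignment, types, healthy_types, cancer_types,
            contamination_tolerance = contamination_tolerance,
            min_prior_cells = min_prior_cells)
        .log_stage(verbose, "factor labels: %s (success: %s)",
                   paste(assignment@factorLabel, collapse = ", "),
                   assignment@success)
    } else {
        .log_stage(verbose, "no usable cell types; factors left unlabelled")
    }

    obs_best <- buildObservationMatrices(counts, selection@bestSubset)
    n_clones <- length(setdiff(unique(assignment@cellClone),
                               "undetermined"))
    variants <- NULL
    if (n_clones >= 2) {
        variants <- selectCloneVariants(
            selection@chosen, vafMatrix(obs_best), weightMatrix(obs_best),
            assignment, diff_threshold = variant_diff_threshold,
            coverage_threshold = coverage_threshold)
        .log_stage(verbose, "%d clone-associated variants selected",
                   sum(variants$selected))
    }

    config <- list(k_grid = k_grid, n_iter = n_iter,
                   n_bootstrap = n_bootstrap,
                   subsample_fraction = subsample_fraction,
                   maf_thresholds = maf_thresholds,
                   healthy_types = healthy_types,
                   cancer_types = cancer_types,
                   undetermined_threshold = undetermined_threshold,
                   variant_diff_threshold = variant_diff_threshold,
                   coverage_threshold = coverage_threshold,
                   contamination_tolerance = contamination_tolerance,
                   min_prior_cells = min_prior_cells, seed = seed,
                   skipped_subsets = skipped)
    out <- list(selection = selection, assignment = assignment,
                variants = variants, subsets = subsets, config = config)
    if (!is.null(out_dir)) .write_run_outputs(out, counts, out_dir)
    out
}

.write_run_outputs <- function(out, counts, out_dir) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
        out$selection@scores, file.path(out_dir, "scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

    memb <- data.frame(variant = variantKeys(counts))
    for (sub in out$subsets) memb[[sub@name]] <- sub@mask
    utils::write.table(memb, file.path(out_dir, "subsets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    asg <- out$assignment
    lab <- asg@factorLabel
    clone <- asg@cellClone
    status <- ifelse(clone == "undetermined", "undetermined",
                     lab[suppressWarnings(as.integer(clone))])
    cells <- data.frame(barcode = names(clone), clone = unname(clone),
                        status = unname(status),
                        round(asg@normalizedC, 6), check.names = FALSE)
    colnames(cells)[3 + seq_len(ncol(asg@normalizedC))] <-
        paste0("weight_factor", seq_len(ncol(asg@normalizedC)))
    utils::write.table(cells, file.path(out_dir, "cell_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(out$variants))
        utils::write.table(
            out$variants, file.path(out_dir, "clone_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

    cfg <- out$config
    log_lines <- c(
        sprintf("n_cells\t%d", ncol(counts)),
        sprintf("n_variants\t%d", nrow(counts)),
        sprintf("best\t%s", out$selection@best),
        sprintf("success\t%s", asg@success),
        vapply(names(cfg), function(k)
            sprintf("%s\t%s", k, paste(cfg[[k]], collapse = ",")),
            character(1)))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    invisible(NULL)
}
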