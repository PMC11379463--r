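#' Fixed variant filters: repeats, RNA edits, low coverage
#'
#' Variants in repeat regions or annotated as RNA edits are artefact-prone
#' and always removed, as are low-coverage variants seen with depth >= 2 in
#' fewer than 10\% of the cells. The boundary is strict: a variant covered in
#' exactly 10\% of cells is retained.
#'
#' @param counts an \linkS4class{AlleleCounts} with annotation flags set.
#' @param min_cov minimum depth for a cell to count as covered (default 2).
#' @param min_cell_fraction minimum fraction of covered cells (default 0.1).
#' @return Logical mask over variants (TRUE = retained). Idempotent by
#'   construction; warns when fewer than 10 variants survive.
#' @export
applyFixedFilters <- function(counts, min_cov = 2, min_cell_fraction = 0.1) {
    rd <- rowData(counts)
    n_cells <- ncol(counts)
    covered <- Matrix::rowSums(dpCounts(counts) >= min_cov)
    mask <- !rd$in_repeat_region & !rd$is_rna_edit &
        (covered >= min_cell_fraction * n_cells)
    if (sum(mask) < 10)
        warning("only ", sum(mask), " variants survive the fixed filters")
    unname(mask)
}

#' Minor-allele frequency of each variant over covered cells
#'
#' For each variant, cells with depth >= 2 are the covered cells; among
#' them the rule of \code{\link{observedAlleles}} decides whether each
#' allele is observed. The minor allele is the one observed in fewer covered
#' cells and the MAF is the fraction of covered cells in which it is
#' observed (0 for variants with no covered cell).
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param min_cov coverage threshold defining a covered cell (default 2).
#' @return Numeric vector of per-variant MAF values in [0, 1] (a variant
#'   heterozygous in every covered cell has both alleles observed everywhere
#'   and MAF 1).
#' @export
variantMAF <- function(counts, min_cov = 2) {
    ad <- as.matrix(adCounts(counts))
    dp <- as.matrix(dpCounts(counts))
    obs <- observedAlleles(ad, dp)
    cov <- dp >= min_cov
    n_cov <- rowSums(cov)
    n_alt <- rowSums(obs$alt_observed & cov)
    n_ref <- rowSums(obs$ref_observed & cov)
    ifelse(n_cov == 0, 0, pmin(n_alt, n_ref) / pmax(n_cov, 1L))
}

#' Build the six-subset variant filtering grid
#'
#' Crosses germline inclusion/exclusion with strict minor-allele-frequency
#' thresholds (default 2\%, 5\%, 10\%), on top of the fixed filters. The
#' germline-included subsets deliberately keep dbSNP-common variants so that
#' loss-of-heterozygosity and deletion signals carried by germline sites
#' remain discoverable; model selection later picks the most informative
#' subset. Empty subsets are retained (they will lose selection).
#'
#' @param counts an \linkS4class{AlleleCounts} with flags set.
#' @param maf_thresholds strict lower bounds on the MAF (default
#'   \code{c(0.02, 0.05, 0.10)}).
#' @param fixed_mask optionally, a precomputed \code{\link{applyFixedFilters}}
#'   mask.
#' @return List of \code{2 * length(maf_thresholds)}
#'   \linkS4class{VariantSubset} objects, named like
#'   \code{"germline_incl_maf2"}.
#' @export
makeVariantSubsets <- function(counts,
                               maf_thresholds = c(0.02, 0.05, 0.10),
                               fixed_mask = NULL) {
    if (is.null(fixed_mask))
        fixed_mask <- suppressWarnings(applyFixedFilters(counts))
    maf <- variantMAF(counts)
    germ <- rowData(counts)$is_germline_common
    out <- list()
    for (incl in c(TRUE, FALSE)) {
        for (thr in maf_thresholds) {
            mask <- fixed_mask & (maf > thr) & (incl | !germ)
            name <- sprintf("germline_%s_maf%g",
                            if (incl) "incl" else "excl", 100 * thr)
            out[[name]] <- methods::new(
                "VariantSubset", mask = unname(mask),
                includeGermline = incl, mafThreshold = thr, name = name)
        }
    }
    out
}
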