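#' Which alleles count as observed at one cell-variant pair
#'
#' An allele is observed when at least one UMI (or read, for non-UMI
#' technology) matches it and its within-cell allelic frequency is >= 0.05.
#' The rule is applied symmetrically to the alternative allele (count
#' \code{ad}) and the reference allele (count \code{dp - ad}); with
#' \code{dp = 0} neither allele is observed. Note that with \code{dp >= 1}
#' at least one allele always passes, since the two frequencies sum to 1.
#'
#' @param ad,dp integer scalars, vectors or matrices with
#'   \code{0 <= ad <= dp}.
#' @return List with logical components \code{ref_observed} and
#'   \code{alt_observed}, shaped like the inputs.
#' @examples
#' observedAlleles(1, 31)  # ALT frequency 1/31 < 0.05: only REF observed
#' observedAlleles(2, 7)   # both alleles observed
#' @export
observedAlleles <- function(ad, dp) {
    if (any(ad > dp)) stop("AD exceeds DP")
    if (any(ad < 0) || any(dp < 0)) stop("negative counts")
    rf <- dp - ad
    denom <- pmax(dp, 1L)
    list(ref_observed = rf >= 1 & rf / denom >= 0.05,
         alt_observed = ad >= 1 & ad / denom >= 0.05)
}

.observation_pair <- function(ad, dp) {
    obs <- observedAlleles(ad, dp)
    alt <- obs$alt_observed
    ref <- obs$ref_observed
    M <- 1 * (alt & !ref) + 0.5 * (alt & ref)
    W <- 0.5 * xor(alt, ref) + 1 * (alt & ref)
    list(M = M, W = W)
}

#' Discretized VAF matrix M for one variant subset
#'
#' Entries are 1 where only alternative reads are observed (homozygous
#' variant observation), 0.5 where both alleles are observed (heterozygous),
#' and 0 where only reference reads, or nothing, is observed.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param subset a \linkS4class{VariantSubset} (or logical mask); default
#'   keeps every variant.
#' @return Dense cells x variants matrix with entries in \{0, 0.5, 1\}.
#' @export
buildM <- function(counts, subset = NULL) {
    .build_obs_component(counts, subset, "M")
}

#' Confidence weight matrix W for one variant subset
#'
#' Entries are 1 where both alleles are observed, 0.5 where exactly one is,
#' and 0 where the position is uncovered; zero-weight entries contribute
#' nothing to the factorization cost.
#'
#' @inheritParams buildM
#' @return Dense cells x variants matrix with entries in \{0, 0.5, 1\}.
#' @export
buildW <- function(counts, subset = NULL) {
    .build_obs_component(counts, subset, "W")
}

.subset_mask <- function(counts, subset) {
    if (is.null(subset)) return(rep(TRUE, nrow(counts)))
    if (methods::is(subset, "VariantSubset")) subset <- subset@mask
    stopifnot(length(subset) == nrow(counts))
    subset
}

.build_obs_component <- function(counts, subset, which) {
    mask <- .subset_mask(counts, subset)
    ad <- Matrix::t(adCounts(counts)[mask, , drop = FALSE])
    dp <- Matrix::t(dpCounts(counts)[mask, , drop = FALSE])
    pair <- .observation_pair(as.matrix(ad), as.matrix(dp))
    out <- pair[[which]]
    dimnames(out) <- list(cellBarcodes(counts), variantKeys(counts)[mask])
    out
}

#' Build both observation matrices for one variant subset
#'
#' @inheritParams buildM
#' @return An \linkS4class{ObservationMatrices} object holding M and W.
#' @export
buildObservationMatrices <- function(counts, subset = NULL) {
    if (!methods::is(subset, "VariantSubset")) {
        mask <- .subset_mask(counts, subset)
        subset <- methods::new("VariantSubset", mask = mask,
                               includeGermline = TRUE, mafThreshold = 0.5,
                               name = "all")
    }
    methods::new("ObservationMatrices",
                 M = buildM(counts, subset),
                 W = buildW(counts, subset),
                 cells = cellBarcodes(counts),
                 variants = variantKeys(counts)[subset@mask],
                 subset = subset)
}
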