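#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

#' AlleleCounts: per-cell allele counts at candidate variant sites
#'
#' Container for cellsnp-lite-style single-cell variant call data. It extends
#' \linkS4class{SummarizedExperiment} with two sparse integer assays:
#' \code{AD} (alternative-allele UMI/read counts) and \code{DP} (total depth),
#' both variants x cells. Variant metadata (chromosome, position, ref/alt
#' alleles and the annotation flags used by the filtering step) live in
#' \code{rowData}; cell barcodes and optional cell-type labels live in
#' \code{colData}.
#'
#' @section Invariants:
#' \itemize{
#'   \item \code{0 <= AD_ij <= DP_ij} for every entry (the reference count is
#'     \code{DP - AD});
#'   \item variant keys \code{(chrom, pos, ref, alt)} are unique;
#'   \item alleles are non-empty strings over A/C/G/T and \code{pos >= 1}.
#' }
#'
#' @aliases AlleleCounts-class
#' @exportClass AlleleCounts
setClass("AlleleCounts", contains = "SummarizedExperiment")

.validity_allele_counts <- function(object) {
    msg <- character()
    if (!all(c("AD", "DP") %in% names(assays(object))))
        return("assays 'AD' and 'DP' are required")
    ad <- assay(object, "AD")
    dp <- assay(object, "DP")
    if (!identical(dim(ad), dim(dp)))
        msg <- c(msg, "AD and DP dimensions differ")
    if (length(ad) > 0) {
        if (min(ad) < 0 || min(dp) < 0)
            msg <- c(msg, "counts must be non-negative")
        bad <- ad - dp
        if (max(bad) > 0) {
            idx <- which(as.matrix(bad) > 0, arr.ind = TRUE)[1, ]
            msg <- c(msg, sprintf(
                "AD exceeds DP at variant %d, cell %d", idx[1], idx[2]))
        }
    }
    rd <- rowData(object)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain chrom, pos, ref, alt")
    } else if (nrow(rd) > 0) {
        if (any(rd$pos < 1)) msg <- c(msg, "positions must be >= 1")
        if (any(rd$ref == rd$alt)) msg <- c(msg, "ref and alt must differ")
        if (!all(grepl("^[ACGT]+$", rd$ref)) ||
            !all(grepl("^[ACGT]+$", rd$alt)))
            msg <- c(msg, "alleles must be non-empty strings over A,C,G,T")
        key <- paste(rd$chrom, rd$pos, rd$ref, rd$alt)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated variant keys (chrom,pos,ref,alt)")
    }
    if (length(msg)) msg else TRUE
}

setValidity("AlleleCounts", .validity_allele_counts)

#' Construct an AlleleCounts object
#'
#' @param AD,DP sparse or dense integer matrices, variants x cells, with
#'   \code{AD <= DP} elementwise.
#' @param variants a \code{data.frame}/\code{DataFrame} with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, and optionally the
#'   annotation flags \code{is_germline_common}, \code{is_rna_edit},
#'   \code{in_repeat_region} (defaulted to \code{FALSE}) and
#'   \code{consequence}.
#' @param cells character vector of cell barcodes (one per column).
#' @param cell_types optional named character vector or two-column
#'   \code{data.frame} mapping barcodes to cell-type names; cells without an
#'   entry get \code{"unknown"}.
#'
#' @return An \linkS4class{AlleleCounts} object.
#' @examples
#' ad <- Matrix::Matrix(c(1, 0, 0, 0, 2, 0), 3, 2, sparse = TRUE)
#' dp <- Matrix::Matrix(c(2, 0, 0, 0, 3, 0), 3, 2, sparse = TRUE)
#' v <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G")
#' AlleleCounts(ad, dp, v, cells = c("bc1", "bc2"))
#' @export
AlleleCounts <- function(AD, DP, variants, cells,
                         cell_types = NULL) {
    AD <- methods::as(methods::as(AD, "CsparseMatrix"), "dMatrix")
    DP <- methods::as(methods::as(DP, "CsparseMatrix"), "dMatrix")
    variants <- as(variants, "DataFrame")
    for (fl in c("is_germline_common", "is_rna_edit", "in_repeat_region")) {
        if (is.null(variants[[fl]]))
            variants[[fl]] <- logical(nrow(variants))
    }
    if (ncol(AD) != length(cells))
        stop("number of cells does not match matrix columns")
    if (nrow(AD) != nrow(variants))
        stop("number of variants does not match matrix rows")
    cd <- DataFrame(barcode = as.character(cells),
                    row.names = as.character(cells))
    cd$cell_type <- .match_cell_types(cell_types, cells)
    rownames(variants) <- paste(variants$chrom, variants$pos,
                                variants$ref, variants$alt, sep = "_")
    se <- SummarizedExperiment(
        assays = list(AD = AD, DP = DP),
        rowData = variants, colData = cd)
    methods::new("AlleleCounts", se)
}

.match_cell_types <- function(cell_types, cells) {
    if (is.null(cell_types)) return(rep(NA_character_, length(cells)))
    if (is.data.frame(cell_types) || methods::is(cell_types, "DataFrame")) {
        cell_types <- stats::setNames(as.character(cell_types[[2]]),
                                      as.character(cell_types[[1]]))
    }
    out <- unname(cell_types[as.character(cells)])
    out[is.na(out)] <- "unknown"
    out
}

#' VariantSubset: one cell of the filtering grid
#'
#' A boolean mask over the variants of a parent \linkS4class{AlleleCounts},
#' together with the germline rule and minor-allele-frequency threshold that
#' produced it. The filtering grid crosses germline inclusion/exclusion with
#' MAF thresholds of 2, 5 and 10 percent, giving six subsets per dataset.
#'
#' @aliases VariantSubset-class
#' @exportClass VariantSubset
setClass("VariantSubset", representation(
    mask = "logical",
    includeGermline = "logical",
    mafThreshold = "numeric",
    name = "character"))

setValidity("VariantSubset", function(object) {
    msg <- character()
    if (length(object@mafThreshold) != 1 ||
        object@mafThreshold <= 0 || object@mafThreshold >= 1)
        msg <- c(msg, "mafThreshold must be a single value in (0, 1)")
    if (length(object@includeGermline) != 1)
        msg <- c(msg, "includeGermline must be a single logical")
    if (length(msg)) msg else TRUE
})

#' ObservationMatrices: discretized VAF matrix M and confidence weights W
#'
#' Holds the two inputs of the weighted NMF for one variant subset. Both
#' matrices are cells x variants with entries in \{0, 0.5, 1\}:
#' \code{M} is the discretized variant allele frequency (0 = only reference
#' observed or nothing observed, 0.5 = both alleles, 1 = only alternative)
#' and \code{W} the confidence in each entry (0 = no allele observed,
#' 0.5 = one allele, 1 = both). Zero-weight entries never contribute to the
#' factorization cost.
#'
#' @aliases ObservationMatrices-class
#' @exportClass ObservationMatrices
setClass("ObservationMatrices", representation(
    M = "matrix",
    W = "matrix",
    cells = "character",
    variants = "character",
    subset = "VariantSubset"))

setValidity("ObservationMatrices", function(object) {
    msg <- character()
    if (!identical(dim(object@M), dim(object@W)))
        msg <- c(msg, "M and W dimensions differ")
    ok_pairs <- cbind(M = c(0, 0, 0.5, 1), W = c(0, 0.5, 1, 0.5))
    pair <- paste(object@M, object@W)
    if (!all(pair %in% paste(ok_pairs[, 1], ok_pairs[, 2])))
        msg <- c(msg, "(M, W) entries outside {(0,0),(0,0.5),(0.5,1),(1,0.5)}")
    if (length(msg)) msg else TRUE
})

#' FactorModel: one weighted NMF fit
#'
#' Result of factorizing M ~ C V at a fixed number of factors K: the
#' non-negative cell factors \code{C} (cells x K), variant factors \code{V}
#' (K x variants), the final weighted sum of squared errors \code{E}, the
#' per-iteration cost trace, the iteration count and the initialization seed.
#' \code{flagged} marks fits where a factor collapsed to zero and stayed
#' there after one re-randomization.
#'
#' @aliases FactorModel-class
#' @exportClass FactorModel
setClass("FactorModel", representation(
    C = "matrix",
    V = "matrix",
    K = "integer",
    E = "numeric",
    costTrace = "numeric",
    nIter = "integer",
    seed = "integer",
    flagged = "logical"))

setValidity("FactorModel", function(object) {
    msg <- character()
    if (ncol(object@C) != object@K || nrow(object@V) != object@K)
        msg <- c(msg, "factor dimensions do not match K")
    if (length(object@C) && min(object@C) < 0)
        msg <- c(msg, "C has negative entries")
    if (length(object@V) && min(object@V) < 0)
        msg <- c(msg, "V has negative entries")
    if (object@E < 0) msg <- c(msg, "E must be non-negative")
    if (length(msg)) msg else TRUE
})

#' BootstrapResult: aligned mean/variance of factors over bootstrap replicates
#'
#' The weighted NMF is refit on random 90\% variant subsamples; replicate
#' factors are aligned to the first replicate by maximum-weight bipartite
#' matching on column cosine similarities, then averaged entrywise.
#' \code{meanV}/\code{varV} aggregate, for each variant, only the replicates
#' in which it was drawn; \code{timesSampled} records that count and
#' \code{lowConfidence} flags variants drawn in fewer than 5 replicates.
#'
#' @aliases BootstrapResult-class
#' @exportClass BootstrapResult
setClass("BootstrapResult", representation(
    meanC = "matrix",
    varC = "matrix",
    meanV = "matrix",
    varV = "matrix",
    nBootstrap = "integer",
    subsampleFraction = "numeric",
    seeds = "integer",
    timesSampled = "integer",
    lowConfidence = "logical",
    permutations = "list",
    flagged = "logical"))

setValidity("BootstrapResult", function(object) {
    msg <- character()
    if (length(object@meanC) && min(object@meanC) < 0)
        msg <- c(msg, "meanC has negative entries")
    if (length(object@meanV) && min(object@meanV) < 0)
        msg <- c(msg, "meanV has negative entries")
    if ((length(object@varC) && min(object@varC) < -1e-12) ||
        (length(object@varV) && min(object@varV) < -1e-12))
        msg <- c(msg, "variances must be non-negative")
    if (length(msg)) msg else TRUE
})

#' SelectionResult: orthogonality-score model selection over the grid
#'
#' Scores every (variant subset, K) candidate by the orthogonality score of
#' its mean cell factors and keeps the argmax. \code{scores} is the full
#' table (subset, K, score, n_variants) retained for reporting; \code{best}
#' names the winning key and \code{chosen} is its
#' \linkS4class{BootstrapResult}.
#'
#' @aliases SelectionResult-class
#' @exportClass SelectionResult
setClass("SelectionResult", representation(
    scores = "data.frame",
    best = "character",
    bestSubset = "VariantSubset",
    bestK = "integer",
    chosen = "BootstrapResult"))

#' CloneAssignment: per-cell clone labels and factor annotation
#'
#' Cells are assigned to the factor with the largest row-normalized weight
#' unless the top two weights differ by less than the undetermined threshold
#' (default 0.3). Factors are labelled healthy/cancer from known cell types:
#' a factor containing no known-healthy cells is cancer, the rest healthy
#' (with a symmetric known-cancer fallback). \code{success} is FALSE when
#' the labelling leaves no healthy or no cancer factor.
#'
#' @aliases CloneAssignment-class
#' @exportClass CloneAssignment
setClass("CloneAssignment", representation(
    cellClone = "character",
    factorLabel = "character",
    success = "logical",
    normalizedC = "matrix",
    threshold = "numeric"))

setValidity("CloneAssignment", function(object) {
    msg <- character()
    K <- ncol(object@normalizedC)
    ok <- c(as.character(seq_len(K)), "undetermined")
    if (!all(object@cellClone %in% ok))
        msg <- c(msg, "cellClone labels must be factor indices or 'undetermined'")
    if (length(object@factorLabel) &&
        !all(object@factorLabel %in% c("healthy", "cancer", "unlabelled")))
        msg <- c(msg, "factorLabel must be healthy/cancer/unlabelled")
    if (length(msg)) msg else TRUE
})
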