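#' @describeIn AlleleCounts alternative-allele count matrix (variants x cells).
#' @param object an object of the documented class.
#' @export
setGeneric("adCounts", function(object) standardGeneric("adCounts"))

#' @describeIn AlleleCounts total-depth matrix (variants x cells).
#' @export
setGeneric("dpCounts", function(object) standardGeneric("dpCounts"))

#' @describeIn AlleleCounts cell barcodes.
#' @export
setGeneric("cellBarcodes", function(object) standardGeneric("cellBarcodes"))

#' @describeIn AlleleCounts cell-type labels (NA when never supplied).
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @describeIn AlleleCounts variant metadata as a DataFrame.
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @describeIn AlleleCounts unique variant keys "chrom_pos_ref_alt".
#' @export
setGeneric("variantKeys", function(object) standardGeneric("variantKeys"))

setMethod("adCounts", "AlleleCounts", function(object) assay(object, "AD"))
setMethod("dpCounts", "AlleleCounts", function(object) assay(object, "DP"))
setMethod("cellBarcodes", "AlleleCounts",
          function(object) colData(object)$barcode)
setMethod("cellTypes", "AlleleCounts",
          function(object) {
              ct <- colData(object)$cell_type
              stats::setNames(ct, colData(object)$barcode)
          })
setMethod("variantInfo", "AlleleCounts", function(object) rowData(object))
setMethod("variantKeys", "AlleleCounts", function(object) {
    rd <- rowData(object)
    paste(rd$chrom, rd$pos, rd$ref, rd$alt, sep = "_")
})

setMethod("show", "AlleleCounts", function(object) {
    cat("AlleleCounts:", nrow(object), "variants x", ncol(object), "cells\n")
    dp <- dpCounts(object)
    cov <- if (length(dp)) Matrix::nnzero(dp) / length(dp) else NA_real_
    cat(sprintf("  covered entries (DP > 0): %.1f%%\n", 100 * cov))
    rd <- rowData(object)
    cat(sprintf(
        "  flags: %d germline-common, %d RNA-edit, %d repeat-region\n",
        sum(rd$is_germline_common), sum(rd$is_rna_edit),
        sum(rd$in_repeat_region)))
    ct <- colData(object)$cell_type
    if (!all(is.na(ct)))
        cat("  cell types:", paste(utils::head(sort(unique(ct)), 6),
                                   collapse = ", "), "\n")
})

#' @describeIn VariantSubset number of variants retained by the mask.
#' @param x a VariantSubset.
#' @export
subsetSize <- function(x) sum(x@mask)

#' @describeIn VariantSubset the logical mask over the parent variants.
#' @export
subsetMask <- function(x) x@mask

#' @describeIn VariantSubset the subset identifier.
#' @export
subsetName <- function(x) x@name

setMethod("show", "VariantSubset", function(object) {
    cat(sprintf("VariantSubset '%s': %d/%d variants (germline %s, MAF > %g)\n",
                object@name, sum(object@mask), length(object@mask),
                if (object@includeGermline) "included" else "excluded",
                object@mafThreshold))
})

#' @describeIn ObservationMatrices the discretized VAF matrix (cells x variants).
#' @param object an object of the documented class.
#' @export
setGeneric("vafMatrix", function(object) standardGeneric("vafMatrix"))

#' @describeIn ObservationMatrices the confidence weight matrix.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

setMethod("vafMatrix", "ObservationMatrices", function(object) object@M)
setMethod("weightMatrix", "ObservationMatrices", function(object) object@W)

setMethod("show", "ObservationMatrices", function(object) {
    cat("ObservationMatrices:", nrow(object@M), "cells x",
        ncol(object@M), "variants (subset", object@subset@name, ")\n")
    cat(sprintf("  weights: %.1f%% zero, %.1f%% half, %.1f%% full\n",
                100 * mean(object@W == 0), 100 * mean(object@W == 0.5),
                100 * mean(object@W == 1)))
})

#' @describeIn FactorModel cell factor matrix (cells x K).
#' @param object an object of the documented class.
#' @export
setGeneric("cellFactors", function(object) standardGeneric("cellFactors"))

#' @describeIn FactorModel variant factor matrix (K x variants).
#' @export
setGeneric("variantFactors",
           function(object) standardGeneric("variantFactors"))

#' @describeIn FactorModel final weighted sum of squared errors.
#' @export
setGeneric("modelCost", function(object) standardGeneric("modelCost"))

setMethod("cellFactors", "FactorModel", function(object) object@C)
setMethod("variantFactors", "FactorModel", function(object) object@V)
setMethod("modelCost", "FactorModel", function(object) object@E)

setMethod("show", "FactorModel", function(object) {
    cat(sprintf(
        "FactorModel: K = %d, %d cells x %d variants, E = %.4g (%d iter%s)\n",
        object@K, nrow(object@C), ncol(object@V), object@E, object@nIter,
        if (object@flagged) ", flagged degenerate" else ""))
})

setMethod("cellFactors", "BootstrapResult", function(object) object@meanC)
setMethod("variantFactors", "BootstrapResult", function(object) object@meanV)

setMethod("show", "BootstrapResult", function(object) {
    cat(sprintf(
        "BootstrapResult: %d replicates (%.0f%% variant subsample), K = %d\n",
        object@nBootstrap, 100 * object@subsampleFraction,
        ncol(object@meanC)))
    cat(sprintf("  mean var(C) = %.3g; %d low-confidence variants\n",
                mean(object@varC), sum(object@lowConfidence)))
})

#' @describeIn SelectionResult the full (subset, K) score table.
#' @param object an object of the documented class.
#' @export
setGeneric("scoreTable", function(object) standardGeneric("scoreTable"))

#' @describeIn SelectionResult the winning BootstrapResult.
#' @export
setGeneric("chosenModel", function(object) standardGeneric("chosenModel"))

setMethod("scoreTable", "SelectionResult", function(object) object@scores)
setMethod("chosenModel", "SelectionResult", function(object) object@chosen)

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: best = %s (K = %d, s = %.4f) of %d candidates\n",
                object@best, object@bestK,
                max(object@scores$score), nrow(object@scores)))
})

#' @describeIn CloneAssignment per-cell clone labels.
#' @param object an object of the documented class.
#' @export
setGeneric("cloneLabels", function(object) standardGeneric("cloneLabels"))

#' @describeIn CloneAssignment per-factor healthy/cancer labels.
#' @export
setGeneric("factorLabels", function(object) standardGeneric("factorLabels"))

#' @describeIn CloneAssignment TRUE when both healthy and cancer factors exist.
#' @export
setGeneric("assignmentSuccess",
           function(object) standardGeneric("assignmentSuccess"))

setMethod("cloneLabels", "CloneAssignment", function(object) object@cellClone)
setMethod("factorLabels", "CloneAssignment",
          function(object) object@factorLabel)
setMethod("assignmentSuccess", "CloneAssignment",
          function(object) object@success)

setMethod("show", "CloneAssignment", function(object) {
    tab <- table(object@cellClone)
    cat("CloneAssignment:", ncol(object@normalizedC), "factors,",
        length(object@cellClone), "cells\n")
    cat("  clone sizes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    if (length(object@factorLabel))
        cat("  factor labels:",
            paste(object@factorLabel, collapse = ", "),
            sprintf("(success: %s)\n", object@success))
})
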