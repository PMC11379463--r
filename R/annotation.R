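#' Assign cells to clones from the mean cell factors
#'
#' Each row of the cell factor matrix is normalized to sum 1 (factor scale
#' is arbitrary in an NMF, so only the normalized weights are meaningful)
#' and the cell is assigned to its argmax factor. Cells whose top two
#' normalized weights differ by less than \code{threshold} carry too little
#' evidence either way and are labelled \code{"undetermined"}, as are cells
#' with all-zero factor rows.
#'
#' @param mean_C non-negative cells x K matrix (typically
#'   \code{meanC} of a \linkS4class{BootstrapResult}).
#' @param threshold undetermined threshold on the weight difference
#'   (default 0.3).
#' @return A \linkS4class{CloneAssignment} with factor labels unset
#'   (\code{"unlabelled"}).
#' @export
assignCells <- function(mean_C, threshold = 0.3) {
    if (methods::is(mean_C, "BootstrapResult")) mean_C <- mean_C@meanC
    mean_C <- as.matrix(mean_C)
    if (length(mean_C) && min(mean_C) < 0) stop("mean_C must be non-negative")
    K <- ncol(mean_C)
    rs <- rowSums(mean_C)
    normC <- mean_C / ifelse(rs > 0, rs, 1)
    top <- apply(normC, 1, function(x) {
        o <- order(x, decreasing = TRUE)
        c(o[1], x[o[1]] - x[o[2]])
    })
    clone <- as.character(top[1, ])
    clone[rs == 0 | top[2, ] < threshold] <- "undetermined"
    methods::new("CloneAssignment",
                 cellClone = stats::setNames(clone, rownames(mean_C)),
                 factorLabel = rep("unlabelled", K),
                 success = NA, normalizedC = normC, threshold = threshold)
}

#' Label factors as healthy or cancer from known cell types
#'
#' A factor "contains" a cell type when more than
#' \code{contamination_tolerance} of the cells assigned to it carry that
#' type (the tolerance absorbs single mislabelled cells; 0 reproduces the
#' literal containment rule). Factors containing no known-healthy cells are
#' labelled cancer and the others healthy. When the dataset holds fewer
#' than \code{min_prior_cells} known-healthy cells, the rule is applied
#' analogously with known-cancer types and inverted logic. The labelling is
#' successful only if it yields at least one healthy and one cancer factor:
#' a model whose every factor mixes known lineages has failed to separate
#' the clones.
#'
#' @param assignment a \linkS4class{CloneAssignment} from
#'   \code{\link{assignCells}}.
#' @param cell_types named character vector (or vector ordered like the
#'   cells) of cell-type labels.
#' @param healthy_types,cancer_types character vectors naming the known
#'   healthy / known cancer cell types (e.g. T cells / blasts in AML).
#' @param contamination_tolerance containment tolerance (default 0.01).
#' @param min_prior_cells minimum dataset-wide known-healthy cells before
#'   falling back to cancer-type labelling (default 20).
#' @return The assignment with \code{factorLabel} and \code{success} set.
#' @export
labelFactors <- function(assignment, cell_types, healthy_types,
                         cancer_types = character(),
                         contamination_tolerance = 0.01,
                         min_prior_cells = 20) {
    K <- ncol(assignment@normalizedC)
    cells <- names(assignment@cellClone)
    if (!is.null(names(cell_types)) && !is.null(cells))
        cell_types <- cell_types[cells]
    if (length(cell_types) != length(assignment@cellClone))
        stop("cell_types length does not match the number of cells")

    n_healthy <- sum(cell_types %in% healthy_types, na.rm = TRUE)
    n_cancer <- sum(cell_types %in% cancer_types, na.rm = TRUE)
    if (n_healthy == 0 && n_cancer == 0)
        stop("no known healthy or cancer cell types present; ",
             "label the factors manually")

    use_healthy <- n_healthy >= min_prior_cells ||
        (n_healthy > 0 && n_cancer < min_prior_cells)
    prior_types <- if (use_healthy) healthy_types else cancer_types

    contains <- vapply(seq_len(K), function(k) {
        in_k <- assignment@cellClone == as.character(k)
        if (!any(in_k)) return(FALSE)
        mean(cell_types[in_k] %in% prior_types) > contamination_tolerance
    }, logical(1))

    label <- if (use_healthy) {
        ifelse(contains, "healthy", "cancer")
    } else {
        ifelse(contains, "cancer", "healthy")
    }
    assignment@factorLabel <- label
    assignment@success <- any(label == "healthy") && any(label == "cancer")
    assignment
}

#' Extract clone-associated variants
#'
#' Variant factor columns are normalized to sum 1 (mirroring the cell-side
#' convention) and a variant is selected when the spread between its largest
#' and smallest normalized factor weight exceeds \code{diff_threshold} and
#' it is covered (at least one allele observed, W > 0) in at least
#' \code{coverage_threshold} of the cells assigned to every clone. The table
#' also reports the per-clone mean discretized VAF over covered cells,
#' which supports clone-by-variant heatmaps.
#'
#' @param mean_V K x variants non-negative matrix (typically \code{meanV}
#'   of a \linkS4class{BootstrapResult}).
#' @param M,W the observation matrices of the same subset (cells x
#'   variants).
#' @param assignment a \linkS4class{CloneAssignment}; at least two clones
#'   must be non-empty.
#' @param diff_threshold weight-difference threshold (default 0.3).
#' @param coverage_threshold per-clone coverage fraction (default 0.2).
#' @return \code{data.frame}, sorted by weight difference (descending), with
#'   the normalized factor weights, weight difference, enriched-factor
#'   index, per-clone coverage and mean VAF, and the \code{selected} flag.
#' @export
selectCloneVariants <- function(mean_V, M, W, assignment,
                                diff_threshold = 0.3,
                                coverage_threshold = 0.2) {
    if (methods::is(mean_V, "BootstrapResult")) mean_V <- mean_V@meanV
    mean_V <- as.matrix(mean_V)
    M <- as.matrix(M); W <- as.matrix(W)
    K <- nrow(mean_V)
    clones <- as.character(seq_len(K))
    clone_cells <- lapply(clones, function(k) assignment@cellClone == k)
    nonempty <- vapply(clone_cells, any, logical(1))
    if (sum(nonempty) < 2)
        stop("need at least two non-empty clones to contrast variants")

    cs <- colSums(mean_V)
    normV <- t(t(mean_V) / ifelse(cs > 0, cs, 1))
    normV[, cs == 0] <- 0
    diff <- apply(normV, 2, max) - apply(normV, 2, min)
    direction <- apply(normV, 2, which.max)

    cov <- vapply(clone_cells[nonempty], function(idx) {
        colMeans(W[idx, , drop = FALSE] > 0)
    }, numeric(ncol(W)))
    cov <- matrix(cov, ncol = sum(nonempty))
    mean_vaf <- vapply(clone_cells[nonempty], function(idx) {
        Wk <- W[idx, , drop = FALSE] > 0
        n <- colSums(Wk)
        ifelse(n > 0, colSums(M[idx, , drop = FALSE] * Wk) / pmax(n, 1), NA)
    }, numeric(ncol(W)))
    mean_vaf <- matrix(mean_vaf, ncol = sum(nonempty))

    selected <- diff > diff_threshold & apply(
        cov >= coverage_threshold, 1, all)

    out <- data.frame(variant = colnames(M) %||% seq_len(ncol(M)),
                      t(normV), weight_diff = diff,
                      enriched_factor = direction,
                      check.names = FALSE)
    colnames(out)[1 + seq_len(K)] <- paste0("weight_factor", seq_len(K))
    for (i in seq_len(sum(nonempty))) {
        out[[paste0("coverage_clone", clones[nonempty][i])]] <- cov[, i]
        out[[paste0("mean_vaf_clone", clones[nonempty][i])]] <- mean_vaf[, i]
    }
    out$selected <- selected
    out[order(-out$weight_diff), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
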