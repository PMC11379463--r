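#' @importFrom igraph make_graph max_bipartite_match V
NULL

#' Align candidate factor columns to a reference by bipartite matching
#'
#' Finds the permutation of candidate columns maximizing the total cosine
#' similarity to the matching reference columns, via maximum-weight
#' bipartite matching (similarities are shifted by +1 so all edge weights
#' are positive and the optimal matching is perfect). Zero-norm columns have
#' similarity 0 to everything.
#'
#' @param reference_C,candidate_C matrices of equal shape (cells x K).
#' @return Integer permutation \code{p} such that
#'   \code{candidate_C[, p]} is column-aligned to \code{reference_C}.
#' @export
alignFactors <- function(reference_C, candidate_C) {
    if (!identical(dim(reference_C), dim(candidate_C)))
        stop("reference and candidate shapes differ")
    K <- ncol(reference_C)
    if (K == 1) return(1L)
    S <- .cosine_matrix(reference_C, candidate_C)
    edges <- as.vector(t(cbind(rep(seq_len(K), each = K),
                               K + rep(seq_len(K), times = K))))
    g <- make_graph(edges, directed = FALSE)
    types <- rep(c(FALSE, TRUE), each = K)
    w <- as.vector(t(S)) + 1  # edge order follows the edge list above
    mm <- max_bipartite_match(g, types = types, weights = w)
    as.integer(mm$matching[seq_len(K)] - K)
}

#' Orthogonality score of the cell factors
#'
#' \deqn{s = -\frac{1}{\binom{K}{2}} \sum_{i < j}
#'   \frac{C_{\cdot i} \cdot C_{\cdot j}}{\|C_{\cdot i}\|\,\|C_{\cdot j}\|}}
#' the negative mean pairwise cosine similarity between factor columns. For
#' non-negative C this lies in [-1, 0]; 0 means perfectly disjoint clones
#' and -1 identical ones. Zero-norm columns contribute 0 to their pairs.
#'
#' @param C non-negative matrix with K >= 2 columns.
#' @return Scalar score in [-1, 0].
#' @export
orthogonalityScore <- function(C) {
    C <- as.matrix(C)
    K <- ncol(C)
    if (K < 2) stop("orthogonality score needs at least 2 factors")
    S <- .cosine_matrix(C, C)
    -mean(S[upper.tri(S)])
}

#' Bootstrap the weighted NMF over variant subsamples
#'
#' Refits the factorization \code{n_bootstrap} times on uniform
#' without-replacement subsamples of 90\% of the variants, aligns every
#' replicate's factors to the first replicate, and returns the entrywise
#' mean and variance of the aligned factors. Because the factorization is
#' scale-indeterminate (C column k and V row k can be rescaled
#' reciprocally at no cost), each aligned replicate is first put on a
#' common scale: C columns are normalized to unit Euclidean norm and V
#' rows carry the reciprocal factor, leaving every replicate's product
#' C V unchanged. Without this, a single replicate with a blown-up factor
#' scale would dominate the mean. Variant factors are aggregated
#' only over replicates in which the variant was drawn; variants drawn in
#' fewer than 5 replicates are flagged low-confidence. Fully deterministic
#' given \code{seed}.
#'
#' @param M,W cells x variants matrices (an
#'   \linkS4class{ObservationMatrices} may be passed as \code{M}).
#' @param K number of factors.
#' @param n_bootstrap number of replicates (default 50).
#' @param fraction variant subsample fraction (default 0.9).
#' @param n_iter,tol passed to \code{\link{fitWNMF}}.
#' @param seed master seed; per-replicate subsampling and initialization
#'   seeds are derived from it.
#' @return A \linkS4class{BootstrapResult}.
#' @export
bootstrapWNMF <- function(M, W = NULL, K, n_bootstrap = 50, fraction = 0.9,
                          n_iter = 100, tol = 1e-6, seed = 1) {
    if (methods::is(M, "ObservationMatrices")) {
        W <- weightMatrix(M)
        M <- vafMatrix(M)
    }
    M <- as.matrix(M); W <- as.matrix(W)
    n_vars <- ncol(M)
    if (n_vars < 10)
        stop("fewer than 10 variants; bootstrap subsampling is meaningless")
    n_draw <- max(2L, round(fraction * n_vars))

    sumC <- sumC2 <- matrix(0, nrow(M), K)
    sumV <- sumV2 <- matrix(0, K, n_vars)
    times <- integer(n_vars)
    seeds <- integer(n_bootstrap)
    perms <- vector("list", n_bootstrap)
    refC <- NULL
    flagged <- FALSE

    for (r in seq_len(n_bootstrap)) {
        s_draw <- deriveSeed(seed, "draw", r)
        seeds[r] <- s_fit <- deriveSeed(seed, "fit", r)
        set.seed(s_draw)
        cols <- sort(sample.int(n_vars, n_draw))
        fit <- fitWNMF(M[, cols, drop = FALSE], W[, cols, drop = FALSE],
                       K = K, n_iter = n_iter, tol = tol, seed = s_fit)
        flagged <- flagged || fit@flagged
        if (is.null(refC)) {
            refC <- fit@C
            p <- seq_len(K)
        } else {
            p <- alignFactors(refC, fit@C)
        }
        perms[[r]] <- p
        Ca <- fit@C[, p, drop = FALSE]
        Va <- fit@V[p, , drop = FALSE]
        scale <- sqrt(colSums(Ca^2))
        scale[scale == 0] <- 1
        Ca <- sweep(Ca, 2, scale, "/")
        Va <- sweep(Va, 1, scale, "*")
        sumC <- sumC + Ca
        sumC2 <- sumC2 + Ca^2
        sumV[, cols] <- sumV[, cols] + Va
        sumV2[, cols] <- sumV2[, cols] + Va^2
        times[cols] <- times[cols] + 1L
    }

    meanC <- sumC / n_bootstrap
    varC <- pmax(sumC2 / n_bootstrap - meanC^2, 0)
    denomV <- matrix(pmax(times, 1L), K, n_vars, byrow = TRUE)
    meanV <- sumV / denomV
    varV <- pmax(sumV2 / denomV - meanV^2, 0)
    meanV[, times == 0] <- 0
    varV[, times == 0] <- 0
    dimnames(meanC) <- dimnames(varC) <- list(rownames(M), NULL)
    dimnames(meanV) <- dimnames(varV) <- list(NULL, colnames(M))

    methods::new("BootstrapResult",
                 meanC = meanC, varC = varC, meanV = meanV, varV = varV,
                 nBootstrap = as.integer(n_bootstrap),
                 subsampleFraction = fraction, seeds = seeds,
                 timesSampled = times, lowConfidence = times < 5L,
                 permutations = perms, flagged = flagged)
}

#' Select the best (variant subset, K) candidate by orthogonality score
#'
#' The weighted errors of fits on different variant subsets are not
#' comparable (different variant counts and properties), so candidates are
#' ranked on the cell factors alone: the winner has the orthogonality score
#' closest to 0. Candidates with a degenerate (all-zero) mean factor column
#' are scored but cannot win; ties break towards smaller K, then the
#' stricter (smaller) subset.
#'
#' @param results list of candidates, each a list with elements
#'   \code{subset} (\linkS4class{VariantSubset}), \code{K} and \code{boot}
#'   (\linkS4class{BootstrapResult}).
#' @return A \linkS4class{SelectionResult} with the full score table.
#' @export
selectBestModel <- function(results) {
    if (length(results) == 0) stop("no candidate results to select from")
    rows <- lapply(results, function(res) {
        mc <- res$boot@meanC
        data.frame(subset = res$subset@name, K = res$K,
                   score = orthogonalityScore(mc),
                   n_variants = sum(res$subset@mask),
                   degenerate = any(colSums(mc) == 0) || res$boot@flagged)
    })
    scores <- do.call(rbind, rows)
    rownames(scores) <- NULL
    eligible <- which(!scores$degenerate)
    if (length(eligible) == 0)
        stop("every candidate has a degenerate factor; inspect the fits")
    ord <- eligible[order(-scores$score[eligible], scores$K[eligible],
                          scores$n_variants[eligible])]
    best <- ord[1]
    methods::new("SelectionResult",
                 scores = scores[, c("subset", "K", "score", "n_variants")],
                 best = sprintf("%s_K%d", scores$subset[best],
                                scores$K[best]),
                 bestSubset = results[[best]]$subset,
                 bestK = as.integer(scores$K[best]),
                 chosen = results[[best]]$boot)
}
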