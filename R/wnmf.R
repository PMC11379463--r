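#' Weighted sum of squared reconstruction errors
#'
#' \deqn{E = \sum_i \sum_j W_{ij} (M_{ij} - \sum_k C_{ik} V_{kj})^2}
#' Entries with zero weight (uncovered positions) contribute nothing.
#'
#' @param M,W cells x variants matrices.
#' @param C cells x K non-negative cell factors.
#' @param V K x variants non-negative variant factors.
#' @return Non-negative scalar.
#' @export
weightedCost <- function(M, W, C, V) {
    M <- as.matrix(M); W <- as.matrix(W)
    C <- as.matrix(C); V <- as.matrix(V)
    if (!identical(dim(M), dim(W)))
        stop("M and W dimensions differ")
    if (nrow(C) != nrow(M) || ncol(V) != ncol(M) || ncol(C) != nrow(V))
        stop("factor dimensions not conformable with M")
    .wnmf_cost_cpp(M, W, C, V)
}

#' Exact weighted non-negative least squares
#'
#' Solves \eqn{\min_{x \ge 0} \sum_t w_t (b_t - (Ax)_t)^2} by scaling the
#' rows of A and b by \eqn{\sqrt{w_t}} and running an exact active-set
#' (Lawson-Hanson) non-negative least-squares solver. This is the inner
#' solve of both half-steps of the alternating factorization.
#'
#' @param A design matrix (t x k).
#' @param b response vector (length t).
#' @param w non-negative weight vector (length t); all-zero weights return
#'   the zero vector.
#' @return Non-negative solution vector of length \code{ncol(A)}.
#' @examples
#' solveWeightedNNLS(cbind(c(1, 1)), c(2, 4), c(1, 1))  # 3
#' solveWeightedNNLS(cbind(1), -1, 1)                   # 0, bound active
#' @export
solveWeightedNNLS <- function(A, b, w) {
    A <- as.matrix(A)
    if (length(w) != length(b) || length(b) != nrow(A))
        stop("lengths of b and w must equal nrow(A)")
    if (any(w < 0)) stop("weights must be non-negative")
    keep <- w > 0
    if (!any(keep)) return(numeric(ncol(A)))
    sw <- sqrt(w[keep])
    as.numeric(.nnls_cpp(A[keep, , drop = FALSE] * sw, b[keep] * sw))
}

#' Fit the weighted NMF by alternating exact non-negative least squares
#'
#' Factorizes the discretized VAF matrix as \eqn{M \approx C V} under
#' elementwise weights W. Starting from a random uniform initialization of
#' C (deterministic given \code{seed}), each iteration solves every column
#' of V as an independent weighted NNLS with design C, then every row of C
#' with design \eqn{V^\top}; both half-steps are exact minimizers, so the
#' recorded per-iteration cost sequence is non-increasing. Cells or variants
#' whose weights are entirely zero are dropped before fitting and their
#' factor rows/columns reinserted as zeros afterwards.
#'
#' If a factor column of C collapses to all-zero, it is re-randomized once
#' and fitting continues; a second collapse leaves it at zero and flags the
#' model (the returned cost trace is that of the final fitting segment).
#'
#' @param M,W cells x variants matrices (an
#'   \linkS4class{ObservationMatrices} may be passed as \code{M}).
#' @param K number of latent factors, >= 2 and <= min(dim(M)).
#' @param n_iter maximum alternating iterations (default 100).
#' @param seed integer seed for the initialization.
#' @param tol,tol_window early stop when the relative cost change over
#'   \code{tol_window} iterations falls below \code{tol}; early stopping
#'   cannot raise the cost. Set \code{tol = 0} to always run \code{n_iter}
#'   iterations.
#' @return A \linkS4class{FactorModel}.
#' @export
fitWNMF <- function(M, W = NULL, K, n_iter = 100, seed = 1,
                    tol = 1e-6, tol_window = 5) {
    if (methods::is(M, "ObservationMatrices")) {
        W <- weightMatrix(M)
        M <- vafMatrix(M)
    }
    M <- as.matrix(M); W <- as.matrix(W)
    if (length(M) == 0) stop("empty observation matrix")
    if (!identical(dim(M), dim(W))) stop("M and W dimensions differ")
    if (K < 2) stop("K must be >= 2")
    if (K > min(dim(M)))
        stop("K = ", K, " exceeds min(n_cells, n_vars) = ", min(dim(M)))

    keep_rows <- rowSums(W > 0) > 0
    keep_cols <- colSums(W > 0) > 0
    Mk <- M[keep_rows, keep_cols, drop = FALSE]
    Wk <- W[keep_rows, keep_cols, drop = FALSE]
    if (length(Mk) == 0) stop("all weights are zero")

    set.seed(seed)
    C0 <- matrix(stats::runif(nrow(Mk) * K), nrow(Mk), K)
    fit <- .wnmf_fit_cpp(Mk, Wk, C0, n_iter, tol, tol_window)
    flagged <- FALSE
    dead <- colSums(fit$C) == 0
    if (any(dead)) {
        C1 <- fit$C
        C1[, dead] <- matrix(stats::runif(nrow(Mk) * sum(dead)),
                             nrow(Mk), sum(dead))
        refit <- .wnmf_fit_cpp(Mk, Wk, C1, n_iter, tol, tol_window)
        if (utils::tail(refit$cost_trace, 1) <=
            utils::tail(fit$cost_trace, 1)) fit <- refit
        flagged <- any(colSums(fit$C) == 0)
    }

    C <- matrix(0, nrow(M), K, dimnames = list(rownames(M), NULL))
    V <- matrix(0, K, ncol(M), dimnames = list(NULL, colnames(M)))
    C[keep_rows, ] <- fit$C
    V[, keep_cols] <- fit$V
    methods::new(Class = "FactorModel", C = C, V = V, K = as.integer(K),
                 E = utils::tail(fit$cost_trace, 1),
                 costTrace = as.numeric(fit$cost_trace),
                 nIter = as.integer(fit$n_iter), seed = as.integer(seed),
                 flagged = flagged)
}
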