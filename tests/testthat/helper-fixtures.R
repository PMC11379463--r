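# Small in-code fixtures shared across the suite.

# AlleleCounts from dense AD/DP matrices (variants x cells).
make_counts <- function(ad, dp, chrom = NULL, germline = NULL,
                        rna_edit = NULL, repeat_region = NULL,
                        cell_types = NULL) {
    n <- nrow(ad)
    variants <- S4Vectors::DataFrame(
        chrom = chrom %||% rep("chr1", n),
        pos = 100L + seq_len(n),
        ref = rep("A", n), alt = rep("G", n),
        is_germline_common = germline %||% logical(n),
        is_rna_edit = rna_edit %||% logical(n),
        in_repeat_region = repeat_region %||% logical(n))
    AlleleCounts(Matrix::Matrix(ad, sparse = TRUE),
                 Matrix::Matrix(dp, sparse = TRUE),
                 variants,
                 cells = sprintf("bc%03d", seq_len(ncol(ad))),
                 cell_types = cell_types)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact rank-2 two-clone observation pattern: block structure with disjoint
# cell/variant supports, all entries fully observed.
make_rank2 <- function(n1 = 6, n2 = 5, v1 = 4, v2 = 3) {
    Ctrue <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
    Vtrue <- rbind(c(rep(0.5, v1), rep(0, v2)), c(rep(0, v1), rep(1, v2)))
    M <- Ctrue %*% Vtrue
    list(M = M, W = matrix(1, nrow(M), ncol(M)), C = Ctrue, V = Vtrue)
}

# Random (M, W) pair consistent with the discretized observation model.
random_obs <- function(n_cells, n_vars, seed) {
    set.seed(seed)
    cases <- matrix(sample(1:4, n_cells * n_vars, replace = TRUE,
                           prob = c(0.45, 0.3, 0.15, 0.1)),
                    n_cells, n_vars)
    M <- matrix(c(0, 0, 0.5, 1)[cases], n_cells, n_vars)
    W <- matrix(c(0, 0.5, 1, 0.5)[cases], n_cells, n_vars)
    list(M = M, W = W)
}

# Brute-force best column permutation by total cosine similarity; the
# independent oracle for the bipartite-matching alignment.
brute_force_align <- function(ref, cand) {
    K <- ncol(ref)
    cosine <- function(a, b) {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }
    perms <- .all_perms(K)
    tot <- vapply(perms, function(p)
        sum(vapply(seq_len(K), function(i) cosine(ref[, i], cand[, p[i]]),
                   numeric(1))), numeric(1))
    perms[[which.max(tot)]]
}

.all_perms <- function(K) {
    if (K == 1) return(list(1L))
    out <- list()
    for (i in seq_len(K)) {
        rest <- .all_perms(K - 1)
        out <- c(out, lapply(rest, function(p) {
            q <- seq_len(K)[-i]
            c(i, q[p])
        }))
    }
    out
}

# Adjusted Rand index computed from the contingency table (closed form),
# independent of any clustering package.
adjusted_rand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    expected <- sum_a * sum_b / choose(n, 2)
    maxi <- (sum_a + sum_b) / 2
    if (maxi == expected) return(1)
    (sum_ij - expected) / (maxi - expected)
}
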