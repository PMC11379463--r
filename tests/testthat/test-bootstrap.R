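test_that("factor alignment recovers identity and swaps", {
    set.seed(1)
    ref <- matrix(runif(8 * 3), 8, 3)
    expect_identical(alignFactors(ref, ref), 1:3)
    # two-column swap is its own inverse
    expect_identical(alignFactors(ref, ref[, c(2, 1, 3)]), c(2L, 1L, 3L))
    # for a 3-cycle the aligning permutation is the cycle's inverse:
    # candidate[, p] must reproduce the reference column order
    p <- alignFactors(ref, ref[, c(2, 3, 1)])
    expect_identical(p, c(3L, 1L, 2L))
    expect_equal(ref[, c(2, 3, 1)][, p], ref)
})

test_that("bipartite-matching alignment equals the brute-force optimum", {
    set.seed(99)
    for (i in 1:30) {
        K <- sample(2:6, 1)
        ref <- matrix(runif(8 * K), 8, K)
        cand <- matrix(runif(8 * K), 8, K)
        expect_identical(alignFactors(ref, cand),
                         as.integer(brute_force_align(ref, cand)))
    }
    # zero-norm candidate columns are handled (similarity 0 to everything)
    cand <- matrix(runif(8 * 3), 8, 3)
    cand[, 2] <- 0
    ref <- matrix(runif(8 * 3), 8, 3)
    expect_identical(sort(alignFactors(ref, cand)), 1:3)
})

test_that("orthogonality score matches its closed forms", {
    # disjoint supports: exactly orthogonal
    expect_equal(orthogonalityScore(cbind(c(1, 1, 0), c(0, 0, 2))), 0)
    # identical columns
    expect_equal(orthogonalityScore(cbind(c(1, 2), c(1, 2))), -1)
    # cosine([1,1],[1,0]) = 1/sqrt(2)
    expect_equal(orthogonalityScore(cbind(c(1, 1), c(1, 0))), -1 / sqrt(2))
    expect_error(orthogonalityScore(cbind(c(1, 1))), "at least 2")
})

test_that("orthogonality score is scale-invariant and bounded for
           non-negative factors", {
    set.seed(3)
    for (i in 1:10) {
        C <- matrix(runif(20 * 4), 20, 4)
        s <- orthogonalityScore(C)
        expect_gte(s, -1)
        expect_lte(s, 0)
        scales <- runif(4, 0.1, 10)
        expect_equal(orthogonalityScore(sweep(C, 2, scales, "*")), s)
    }
    # K = 2: s is exactly minus the cosine of the two columns
    C <- matrix(runif(12 * 2), 12, 2)
    expect_equal(orthogonalityScore(C),
                 -sum(C[, 1] * C[, 2]) /
                     (sqrt(sum(C[, 1]^2)) * sqrt(sum(C[, 2]^2))))
})

test_that("bootstrap is deterministic and degenerates correctly at one
           replicate", {
    o <- random_obs(30, 20, seed = 8)
    b1 <- bootstrapWNMF(o$M, o$W, K = 2, n_bootstrap = 3, seed = 4)
    b2 <- bootstrapWNMF(o$M, o$W, K = 2, n_bootstrap = 3, seed = 4)
    expect_identical(b1@meanC, b2@meanC)
    expect_identical(b1@meanV, b2@meanV)
    expect_identical(b1@varC, b2@varC)

    # single replicate: mean equals that fit up to positive column scale,
    # variance zero
    b <- bootstrapWNMF(o$M, o$W, K = 2, n_bootstrap = 1, seed = 4)
    expect_true(all(b@varC == 0))
    set.seed(CloneNMF:::deriveSeed(4, "draw", 1))
    cols <- sort(sample.int(20, 18))
    f <- fitWNMF(o$M[, cols], o$W[, cols], K = 2,
                 seed = CloneNMF:::deriveSeed(4, "fit", 1))
    scale <- sqrt(colSums(f@C^2))
    expect_equal(b@meanC, sweep(f@C, 2, scale, "/"), ignore_attr = TRUE)
    expect_equal(b@meanV[, cols], sweep(f@V, 1, scale, "*"),
                 ignore_attr = TRUE)
})

test_that("replicates agree on a noiseless two-clone pattern", {
    r2 <- make_rank2(n1 = 12, n2 = 10, v1 = 8, v2 = 6)
    b <- bootstrapWNMF(r2$M, r2$W, K = 2, n_bootstrap = 8, seed = 2)
    expect_lt(max(b@varC), 1e-3)
    expect_false(any(b@lowConfidence & b@timesSampled > 0 &
                     b@timesSampled >= 5))
})

test_that("variants drawn in few replicates are flagged low-confidence", {
    o <- random_obs(20, 12, seed = 5)
    b <- bootstrapWNMF(o$M, o$W, K = 2, n_bootstrap = 3, seed = 9)
    expect_true(all(b@lowConfidence))  # 3 < 5 replicates for every variant
    expect_true(all(b@timesSampled <= 3))
    expect_error(bootstrapWNMF(o$M[, 1:5], o$W[, 1:5], K = 2, seed = 1),
                 "fewer than 10 variants")
})

test_that("selection keeps the score closest to zero and breaks ties by
           parsimony", {
    mk <- function(C, name, K, n = 10) {
        sub <- methods::new("VariantSubset", mask = rep(TRUE, n),
                            includeGermline = TRUE, mafThreshold = 0.02,
                            name = name)
        boot <- methods::new("BootstrapResult", meanC = C,
                             varC = C * 0, meanV = matrix(0.1, ncol(C), n),
                             varV = matrix(0, ncol(C), n),
                             nBootstrap = 1L, subsampleFraction = 0.9,
                             seeds = 1L, timesSampled = rep(1L, n),
                             lowConfidence = rep(FALSE, n),
                             permutations = list(seq_len(ncol(C))),
                             flagged = FALSE)
        list(subset = sub, K = K, boot = boot)
    }
    near <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))            # s = 0
    far <- cbind(c(1, 1, 0, 0), c(1, 1, 0.1, 0.1))         # s close to -1
    sel <- selectBestModel(list(a = mk(far, "a", 2), b = mk(near, "b", 2)))
    expect_identical(sel@best, "b_K2")

    # tie on score (both exactly orthogonal): smaller K wins
    tie <- selectBestModel(list(
        k3 = mk(diag(3) * 1.0, "x", 3, n = 12),
        k2 = mk(near, "x", 2, n = 12)))
    expect_identical(tie@bestK, 2L)

    # degenerate candidates cannot win
    dead <- cbind(c(1, 1, 0, 0), c(0, 0, 0, 0))
    sel2 <- selectBestModel(list(a = mk(far, "a", 2), z = mk(dead, "z", 2)))
    expect_identical(sel2@best, "a_K2")
    expect_error(selectBestModel(list(z = mk(dead, "z", 2))), "degenerate")
})
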