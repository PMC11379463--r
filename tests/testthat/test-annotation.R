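test_that("cells are assigned to the dominant factor with an undetermined
           band", {
    C <- rbind(c(0.9, 0.1),    # diff 0.8 -> clone 1
               c(0.55, 0.45),  # diff 0.1 -> undetermined
               c(0, 0),        # no evidence -> undetermined
               c(1, 9))        # diff 0.8 -> clone 2
    rownames(C) <- paste0("c", 1:4)
    a <- assignCells(C)
    expect_identical(unname(cloneLabels(a)),
                     c("1", "undetermined", "undetermined", "2"))
    # clone sizes plus undetermined account for every cell
    expect_identical(sum(table(cloneLabels(a))), 4L)
})

test_that("assignment is invariant to positive row rescaling", {
    set.seed(6)
    C <- matrix(runif(30 * 3), 30, 3)
    a1 <- assignCells(C)
    a2 <- assignCells(C * rep(runif(30, 0.2, 8), 3))
    expect_identical(cloneLabels(a1), cloneLabels(a2))
})

test_that("factors with no known-healthy cells are labelled cancer", {
    C <- rbind(matrix(rep(c(1, 0), each = 50), 50),
               matrix(rep(c(0, 1), each = 50), 50))
    rownames(C) <- paste0("c", 1:100)
    types <- rep("unknown", 100)
    types[1:20] <- "T-cell"   # 40% of factor-1 cells
    a <- labelFactors(assignCells(C), types, healthy_types = "T-cell")
    expect_identical(factorLabels(a), c("healthy", "cancer"))
    expect_true(assignmentSuccess(a))
})

test_that("a model whose factors all contain healthy cells fails", {
    C <- rbind(matrix(rep(c(1, 0), each = 50), 50),
               matrix(rep(c(0, 1), each = 50), 50))
    rownames(C) <- paste0("c", 1:100)
    types <- rep("unknown", 100)
    types[c(1:15, 51:65)] <- "T-cell"  # both factors > 1% T-cells
    a <- labelFactors(assignCells(C), types, healthy_types = "T-cell")
    expect_identical(factorLabels(a), c("healthy", "healthy"))
    expect_false(assignmentSuccess(a))
})

test_that("with insufficient healthy priors the cancer-type fallback
           applies inverted logic", {
    C <- rbind(matrix(rep(c(1, 0), each = 50), 50),
               matrix(rep(c(0, 1), each = 50), 50))
    rownames(C) <- paste0("c", 1:100)
    types <- rep("unknown", 100)
    types[1:30] <- "Blast"  # only cancer-type priors available
    a <- labelFactors(assignCells(C), types, healthy_types = "T-cell",
                      cancer_types = "Blast")
    expect_identical(factorLabels(a), c("cancer", "healthy"))
    expect_true(assignmentSuccess(a))

    expect_error(
        labelFactors(assignCells(C), rep("unknown", 100),
                     healthy_types = "T-cell", cancer_types = "Blast"),
        "manually")
})

test_that("clone-associated variants need both weight spread and per-clone
           coverage", {
    # 10 cells: 5 in clone 1, 5 in clone 2
    C <- rbind(matrix(rep(c(1, 0), each = 5), 5),
               matrix(rep(c(0, 1), each = 5), 5))
    rownames(C) <- paste0("c", 1:10)
    a <- assignCells(C)
    # V columns: spread 0.6 / spread 0.2 / spread 0.8
    V <- cbind(c(0.8, 0.2), c(0.6, 0.4), c(0.9, 0.1))
    W <- matrix(1, 10, 3)
    W[1:9, 3] <- 0                   # variant 3: clone-1 coverage 20%...
    W[1:4, 3] <- 1                   # ...covered in 4/5 of clone 1? set 80%
    W[6:10, 3] <- 0                  # clone 2 coverage 0% -> fails coverage
    M <- W * 0.5
    tab <- selectCloneVariants(V, M, W, a)
    tab <- tab[order(tab$variant), ]
    expect_identical(tab$selected, c(TRUE, FALSE, FALSE))
    expect_identical(tab$enriched_factor[order(tab$variant)][1], 1L)
})

test_that("variant selection requires two non-empty clones", {
    C <- matrix(rep(c(1, 0), each = 5), 5)
    rownames(C) <- paste0("c", 1:5)
    a <- assignCells(cbind(C, 0))
    V <- cbind(c(0.8, 0.2))
    expect_error(
        selectCloneVariants(V, matrix(0.5, 5, 1), matrix(1, 5, 1), a),
        "two non-empty clones")
})
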