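test_that("the noiseless limit reproduces the planted genotypes exactly", {
    sim <- simulateClonalData(n_cells = 60, n_somatic = 6, n_germline = 5,
                              n_loh = 4, n_noise = 0, p_expr = 1,
                              mean_depth = 30, dropout = 0, error_rate = 0,
                              noise_rate = 0, seed = 11)
    M <- buildM(sim$counts)
    cancer <- sim$clones == "cancer"
    som <- sim$variant_class == "somatic"
    loh <- sim$variant_class == "loh"
    # somatic: heterozygous in every cancer cell, absent in healthy cells
    expect_true(all(M[cancer, som] == 0.5))
    expect_true(all(M[!cancer, som] == 0))
    # germline heterozygous everywhere
    expect_true(all(M[, sim$variant_class == "germline"] == 0.5))
    # LOH: healthy heterozygous; cancer lost (0) or fixated (1) as planted
    expect_true(all(M[!cancer, loh] == 0.5))
    states <- sim$loh_state[loh]
    for (j in seq_along(states))
        expect_true(all(M[cancer, which(loh)[j]] == states[j]))
    # and M equals the planted genotype on expressed sites wholesale
    expect_equal(M, t(sim$genotype_vaf), ignore_attr = TRUE)
})

test_that("coverage sparsity matches the expression probability", {
    sim <- simulateClonalData(n_cells = 200, n_somatic = 20,
                              n_germline = 20, n_loh = 5, n_noise = 55,
                              p_expr = 0.3, dropout = 0, seed = 7)
    frac <- Matrix::nnzero(dpCounts(sim$counts)) /
        length(dpCounts(sim$counts))
    se <- sqrt(0.3 * 0.7 / length(dpCounts(sim$counts)))
    expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("the generator is deterministic by seed and respects AD <= DP", {
    s1 <- simulateClonalData(n_cells = 50, n_somatic = 5, n_germline = 5,
                             n_loh = 2, n_noise = 10, seed = 13)
    s2 <- simulateClonalData(n_cells = 50, n_somatic = 5, n_germline = 5,
                             n_loh = 2, n_noise = 10, seed = 13)
    expect_identical(as.matrix(adCounts(s1$counts)),
                     as.matrix(adCounts(s2$counts)))
    expect_identical(s1$clones, s2$clones)
    expect_true(all(adCounts(s1$counts) <= dpCounts(s1$counts)))
    expect_true(all(adCounts(s1$counts) >= 0))
})

test_that("cell types mark the configured fractions of each clone", {
    sim <- simulateClonalData(n_cells = 400, seed = 5)
    ct <- cellTypes(sim$counts)
    healthy <- sim$clones == "healthy"
    expect_true(all(ct[healthy] %in% c("T-cell", "unknown")))
    expect_true(all(ct[!healthy] %in% c("Blast", "unknown")))
    expect_gt(mean(ct[healthy] == "T-cell"), 0.15)
    expect_lt(mean(ct[healthy] == "T-cell"), 0.45)
})

test_that("planted germline variants are flagged dbSNP-common", {
    sim <- simulateClonalData(n_cells = 40, n_somatic = 4, n_germline = 6,
                              n_loh = 2, n_noise = 5, seed = 3)
    rd <- SummarizedExperiment::rowData(sim$counts)
    expect_identical(unname(rd$is_germline_common),
                     sim$variant_class == "germline")
})

test_that("binomial thinning preserves structure and concentration", {
    sim <- simulateClonalData(n_cells = 100, n_somatic = 10,
                              n_germline = 10, n_loh = 4, n_noise = 30,
                              mean_depth = 8, seed = 21)
    # fraction 1 is the identity
    expect_identical(
        as.matrix(dpCounts(subsampleCounts(sim$counts, 1, seed = 2))),
        as.matrix(dpCounts(sim$counts)))

    thin <- subsampleCounts(sim$counts, 0.5, seed = 2)
    expect_true(all(adCounts(thin) <= dpCounts(thin)))
    total <- sum(dpCounts(sim$counts))
    kept <- sum(dpCounts(thin))
    sd3 <- 3 * sqrt(total * 0.5 * 0.5)
    expect_lt(abs(kept - 0.5 * total), sd3)
    # metadata untouched
    expect_identical(variantKeys(thin), variantKeys(sim$counts))
    expect_identical(cellBarcodes(thin), cellBarcodes(sim$counts))
})

test_that("simulation export writes the cellsnp trio plus truth tables that
           read back consistently", {
    sim <- simulateClonalData(n_cells = 30, n_somatic = 4, n_germline = 4,
                              n_loh = 2, n_noise = 6, seed = 17)
    dir <- withr::local_tempdir()
    paths <- writeSimulation(sim, dir)
    expect_true(all(file.exists(paths)))
    back <- readCellsnp(paths["vcf"], paths["ad"], paths["dp"],
                        paths["barcodes"],
                        cell_types_path = paths["cell_types"])
    expect_equal(as.matrix(adCounts(back)),
                 as.matrix(adCounts(sim$counts)), ignore_attr = TRUE)
    back <- readVariantAnnotations(paths["annotations"], back)
    expect_identical(
        unname(SummarizedExperiment::rowData(back)$is_germline_common),
        sim$variant_class == "germline")
})
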