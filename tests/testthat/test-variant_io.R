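test_that("cellsnp trio round-trips counts, variant keys and barcodes exactly", {
    ad <- matrix(c(1, 0, 0, 0, 2, 0), 3, 2, byrow = TRUE)
    dp <- matrix(c(2, 0, 1, 3, 3, 0), 3, 2, byrow = TRUE)
    counts <- make_counts(ad, dp, chrom = c("chr1", "chr2", "chr2"))
    dir <- withr::local_tempdir()
    writeCellsnp(counts, dir)
    back <- readCellsnp(file.path(dir, "cellSNP.base.vcf"),
                        file.path(dir, "cellSNP.tag.AD.mtx"),
                        file.path(dir, "cellSNP.tag.DP.mtx"),
                        file.path(dir, "cellSNP.samples.tsv"))
    expect_equal(as.matrix(adCounts(back)), ad, ignore_attr = TRUE)
    expect_equal(as.matrix(dpCounts(back)), dp, ignore_attr = TRUE)
    expect_identical(variantKeys(back), variantKeys(counts))
    expect_identical(cellBarcodes(back), cellBarcodes(counts))
    expect_equal(sum(adCounts(back)), sum(ad))
    expect_equal(sum(dpCounts(back)), sum(dp))
})

test_that("zero-variant datasets are valid objects", {
    counts <- make_counts(matrix(0, 0, 2), matrix(0, 0, 2))
    expect_s4_class(counts, "AlleleCounts")
    expect_identical(nrow(counts), 0L)
    expect_identical(ncol(counts), 2L)
})

test_that("AD exceeding DP is rejected with coordinates", {
    ad <- matrix(c(3, 0), 1, 2)
    dp <- matrix(c(2, 0), 1, 2)
    expect_error(make_counts(ad, dp), "variant 1, cell 1")
})

test_that("reader reports dimension mismatches naming the offending file", {
    ad <- matrix(c(1, 0, 0, 2), 2, 2)
    dp <- matrix(c(2, 0, 1, 3), 2, 2)
    counts <- make_counts(ad, dp)
    dir <- withr::local_tempdir()
    paths <- writeCellsnp(counts, dir)
    writeLines(c(readLines(paths["barcodes"]), "bc_extra"),
               paths["barcodes"])
    expect_error(
        readCellsnp(paths["vcf"], paths["ad"], paths["dp"],
                    paths["barcodes"]),
        "barcodes")
    vcf <- readLines(paths["vcf"])
    writeLines(vcf[-length(vcf)], paths["vcf"])
    expect_error(
        readCellsnp(paths["vcf"], paths["ad"], paths["dp"],
                    paths["barcodes"]),
        "variants")
})

test_that("gzipped matrix and barcode inputs are read transparently", {
    ad <- matrix(c(1, 0, 0, 2), 2, 2)
    dp <- matrix(c(2, 1, 1, 3), 2, 2)
    counts <- make_counts(ad, dp)
    dir <- withr::local_tempdir()
    paths <- writeCellsnp(counts, dir)
    for (p in paths[c("ad", "dp", "barcodes")]) {
        con <- gzfile(paste0(p, ".gz"), "w")
        writeLines(readLines(p), con)
        close(con)
    }
    back <- readCellsnp(paths["vcf"], paste0(paths["ad"], ".gz"),
                        paste0(paths["dp"], ".gz"),
                        paste0(paths["barcodes"], ".gz"))
    expect_equal(as.matrix(adCounts(back)), ad, ignore_attr = TRUE)
})

test_that("annotation table sets flags, defaults absentees, skips bad rows", {
    counts <- make_counts(matrix(1, 3, 2), matrix(2, 3, 2),
                          chrom = c("chr1", "chr1", "chr2"))
    rd <- SummarizedExperiment::rowData(counts)
    tab <- data.frame(chrom = c("chr1", "chr9", "chr2"),
                      pos = c(rd$pos[1], "10x", rd$pos[3]),
                      ref = "A", alt = "G",
                      is_germline_common = c(TRUE, TRUE, FALSE),
                      is_rna_edit = c(FALSE, FALSE, TRUE))
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_warning(out <- readVariantAnnotations(path, counts),
                   "malformed position")
    rd2 <- SummarizedExperiment::rowData(out)
    expect_identical(rd2$is_germline_common, c(TRUE, FALSE, FALSE))
    expect_identical(rd2$is_rna_edit, c(FALSE, FALSE, TRUE))
    expect_identical(rd2$in_repeat_region, rep(FALSE, 3))
})

test_that("conflicting duplicate annotation keys are an error", {
    counts <- make_counts(matrix(1, 1, 2), matrix(2, 1, 2))
    rd <- SummarizedExperiment::rowData(counts)
    tab <- data.frame(chrom = "chr1", pos = rd$pos[1], ref = "A", alt = "G",
                      is_germline_common = c(TRUE, FALSE))
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readVariantAnnotations(path, counts), "conflicting")
})

test_that("cell-type table maps missing barcodes to unknown and accepts
           consistent duplicates", {
    counts <- make_counts(matrix(1, 1, 3), matrix(2, 1, 3))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("bc001\tT-cell", "bc002\tT-cell", "bc002\tT-cell"), path)
    ct <- readCellTypes(path, counts)
    expect_identical(unname(ct), c("T-cell", "T-cell", "unknown"))
    writeLines(c("other1\tT-cell", "other2\tBlast"), path)
    expect_error(readCellTypes(path, counts), "overlap")
})

test_that("repeat-region BED intervals flag overlapping variants", {
    counts <- make_counts(matrix(1, 3, 2), matrix(2, 3, 2),
                          chrom = c("chr1", "chr1", "chr2"))
    pos <- SummarizedExperiment::rowData(counts)$pos
    bed <- withr::local_tempfile(fileext = ".bed")
    # 0-based half-open interval covering exactly the first variant
    writeLines(sprintf("chr1\t%d\t%d\trep1", pos[1] - 1L, pos[1]), bed)
    out <- flagRepeatRegions(counts, bed)
    expect_identical(SummarizedExperiment::rowData(out)$in_repeat_region,
                     c(TRUE, FALSE, FALSE))
})
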