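#' @importFrom Matrix readMM writeMM Matrix t
#' @importFrom VariantAnnotation readVcf
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges overlapsAny
NULL

.open_maybe_gz <- function(path) {
    if (grepl("\\.gz$", path)) gzfile(path) else path
}

#' Read a cellsnp-lite output trio into an AlleleCounts object
#'
#' Assembles the variant list (VCF), the sparse alternative-allele (AD) and
#' total-depth (DP) Matrix Market matrices and the cell barcode list emitted
#' by cellsnp-lite. Matrices are kept in the native variants x cells
#' orientation; counts are preserved exactly. Gzipped inputs are accepted
#' transparently.
#'
#' @param base_vcf_path variant list VCF (genotype fields ignored).
#' @param ad_mtx_path,dp_mtx_path sparse integer Matrix Market files,
#'   variants x cells.
#' @param barcodes_path one barcode per line.
#' @param cell_types_path optional two-column TSV (barcode, type).
#' @return An \linkS4class{AlleleCounts}.
#' @export
readCellsnp <- function(base_vcf_path, ad_mtx_path, dp_mtx_path,
                        barcodes_path, cell_types_path = NULL) {
    vcf <- suppressWarnings(readVcf(base_vcf_path, genome = "unknown"))
    rr <- rowRanges(vcf)
    alt <- as.character(unlist(rr$ALT))
    if (length(alt) != length(rr))
        stop("multi-allelic rows in ", base_vcf_path,
             "; expand to one ALT per row first")
    variants <- DataFrame(
        chrom = as.character(seqnames(rr)),
        pos = start(rr),
        ref = as.character(rr$REF),
        alt = alt)

    ad <- readMM(.open_maybe_gz(ad_mtx_path))
    dp <- readMM(.open_maybe_gz(dp_mtx_path))
    barcodes <- readLines(.open_maybe_gz(barcodes_path))
    barcodes <- barcodes[nzchar(barcodes)]

    if (nrow(ad) != nrow(variants))
        stop("row count of ", ad_mtx_path, " (", nrow(ad),
             ") does not match the ", nrow(variants), " variants in ",
             base_vcf_path)
    if (!identical(dim(ad), dim(dp)))
        stop("dimensions of ", ad_mtx_path, " and ", dp_mtx_path, " differ")
    if (ncol(ad) != length(barcodes))
        stop("column count of ", ad_mtx_path, " (", ncol(ad),
             ") does not match the ", length(barcodes), " barcodes in ",
             barcodes_path)

    cell_types <- NULL
    if (!is.null(cell_types_path))
        cell_types <- readCellTypes(cell_types_path, barcodes)
    AlleleCounts(ad, dp, variants, barcodes, cell_types = cell_types)
}

#' Write an AlleleCounts object as a cellsnp-lite-compatible trio
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, default \code{"cellSNP"}.
#' @return Invisibly, the named vector of written paths.
#' @export
writeCellsnp <- function(counts, dir, prefix = "cellSNP") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rd <- rowData(counts)
    paths <- c(
        vcf = file.path(dir, paste0(prefix, ".base.vcf")),
        ad = file.path(dir, paste0(prefix, ".tag.AD.mtx")),
        dp = file.path(dir, paste0(prefix, ".tag.DP.mtx")),
        barcodes = file.path(dir, paste0(prefix, ".samples.tsv")))

    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s>", unique(rd$chrom)),
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", sep = "\t"))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                    rd$chrom, rd$pos, rd$ref, rd$alt)
    writeLines(c(header, body), paths["vcf"])
    writeMM(adCounts(counts), paths["ad"])
    writeMM(dpCounts(counts), paths["dp"])
    writeLines(cellBarcodes(counts), paths["barcodes"])
    invisible(paths)
}

#' Attach variant annotation flags from a local table
#'
#' The table is keyed by (chrom, pos, ref, alt) and carries the three boolean
#' flags used for filtering: \code{is_germline_common} (dbSNP-common, MAF >=
#' 0.01 in at least one major population), \code{is_rna_edit} (REDIdb) and
#' \code{in_repeat_region} (RepeatMasker). Variants absent from the table
#' keep all flags FALSE. Rows with unparseable positions are skipped with a
#' warning; duplicate keys with conflicting flags are an error.
#'
#' @param annotation_table_path TSV with columns chrom, pos, ref, alt and the
#'   flag columns (any subset; missing flags default to FALSE). An optional
#'   \code{consequence} column is carried through.
#' @param counts an \linkS4class{AlleleCounts}.
#' @return The counts with updated rowData flags.
#' @export
readVariantAnnotations <- function(annotation_table_path, counts) {
    tab <- utils::read.delim(.open_maybe_gz(annotation_table_path),
                             colClasses = "character",
                             check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(tab)))
        stop("annotation table must have columns chrom, pos, ref, alt")
    pos <- suppressWarnings(as.integer(tab$pos))
    bad <- is.na(pos) | pos < 1
    if (any(bad)) {
        warning(sum(bad), " annotation row(s) with malformed position skipped")
        tab <- tab[!bad, , drop = FALSE]
        pos <- pos[!bad]
    }
    key <- paste(tab$chrom, pos, tab$ref, tab$alt, sep = "_")
    flags <- c("is_germline_common", "is_rna_edit", "in_repeat_region")
    for (fl in flags) {
        tab[[fl]] <- if (is.null(tab[[fl]])) FALSE else
            toupper(tab[[fl]]) %in% c("TRUE", "T", "1", "YES")
    }
    if (anyDuplicated(key)) {
        payload <- do.call(paste, tab[flags])
        if (any(tapply(payload, key, function(x) length(unique(x))) > 1))
            stop("duplicate annotation keys with conflicting flags")
        keep <- !duplicated(key)
        tab <- tab[keep, , drop = FALSE]
        key <- key[keep]
    }
    idx <- match(variantKeys(counts), key)
    rd <- rowData(counts)
    for (fl in flags) {
        val <- tab[[fl]][idx]
        val[is.na(val)] <- FALSE
        rd[[fl]] <- val
    }
    if (!is.null(tab$consequence)) rd$consequence <- tab$consequence[idx]
    rowData(counts) <- rd
    methods::validObject(counts)
    counts
}

#' Read a two-column cell-type table restricted to known barcodes
#'
#' @param tsv_path TSV with columns barcode, cell type (header optional when
#'   named \code{barcode}/\code{cell_type}); duplicate barcodes with the same
#'   type are accepted.
#' @param cells barcodes of the dataset (or an \linkS4class{AlleleCounts}).
#' @return Named character vector over \code{cells}; barcodes absent from
#'   the table map to \code{"unknown"}. Zero overlap between table and
#'   dataset barcodes is an error.
#' @export
readCellTypes <- function(tsv_path, cells) {
    if (methods::is(cells, "AlleleCounts")) cells <- cellBarcodes(cells)
    tab <- utils::read.delim(.open_maybe_gz(tsv_path),
                             colClasses = "character", header = FALSE)
    if (identical(tolower(tab[1, 1]), "barcode"))
        tab <- tab[-1, , drop = FALSE]
    if (ncol(tab) < 2) stop("cell-type table needs two columns")
    bc <- tab[[1]]
    ty <- tab[[2]]
    dup <- duplicated(bc)
    if (any(dup)) {
        conflict <- tapply(ty, bc, function(x) length(unique(x)) > 1)
        if (any(conflict))
            stop("duplicate barcodes with conflicting cell types")
        bc <- bc[!dup]
        ty <- tab[[2]][!dup]
    }
    if (!any(bc %in% cells))
        stop("no overlap between cell-type table and dataset barcodes; ",
             "is this the right file?")
    out <- ty[match(cells, bc)]
    out[is.na(out)] <- "unknown"
    stats::setNames(out, cells)
}

#' Flag variants overlapping repeat regions from a BED file
#'
#' BED intervals (0-based half-open) are converted on import; a variant is
#' flagged when its 1-based position overlaps any interval.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param bed_path RepeatMasker-style BED file.
#' @return The counts with \code{in_repeat_region} updated.
#' @export
flagRepeatRegions <- function(counts, bed_path) {
    repeats <- rtracklayer::import(bed_path, format = "BED")
    rd <- rowData(counts)
    sites <- GRanges(rd$chrom, IRanges(rd$pos, width = 1))
    rd$in_repeat_region <- overlapsAny(sites, repeats)
    rowData(counts) <- rd
    counts
}
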