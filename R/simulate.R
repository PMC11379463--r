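#' Simulate a clone-structured single-cell variant-call dataset
#'
#' Generates cellsnp-lite-compatible allele counts with planted clonal
#' structure and full ground truth. Cells split into a healthy and a cancer
#' clone; variants fall into four classes:
#' \itemize{
#'   \item somatic: heterozygous (true VAF 0.5) in cancer cells only;
#'   \item germline: heterozygous in every cell (dbSNP-common in the
#'     emitted annotation table);
#'   \item LOH: heterozygous in healthy cells, lost (VAF 0) or fixated
#'     (VAF 1) in the cancer clone, half each;
#'   \item noise: true VAF 0 everywhere, with sporadic per-cell ALT
#'     observations at rate \code{noise_rate} imitating sequencing and
#'     processing artefacts.
#' }
#' Each cell x variant site is expressed with probability \code{p_expr};
#' expressed sites draw a total depth of 1 + Poisson(\code{mean_depth} - 1).
#' For heterozygous sites each allele drops out independently with
#' probability \code{dropout} (both dropped = site unobserved); reads then
#' flip allele independently with probability \code{error_rate}. A fraction
#' of each clone's cells carries a known cell-type name for factor
#' labelling; the rest are "unknown".
#'
#' @param n_cells number of cells (default 500).
#' @param clone_fractions named fractions summing to 1
#'   (default \code{c(healthy = 0.6, cancer = 0.4)}).
#' @param n_somatic,n_germline,n_loh,n_noise variant class sizes
#'   (defaults 30, 50, 10, 200).
#' @param p_expr per-site expression probability (default 0.3).
#' @param mean_depth mean depth of expressed sites (default 4).
#' @param dropout per-allele dropout probability (default 0.2).
#' @param error_rate per-read allele flip probability (default 0.01).
#' @param noise_rate per-cell sporadic ALT rate at noise variants
#'   (default 0.02).
#' @param healthy_type_fraction,cancer_type_fraction fractions of each
#'   clone's cells carrying the known type name (defaults 0.3).
#' @param healthy_type_name,cancer_type_name emitted known cell-type names
#'   (defaults "T-cell", "Blast").
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return List with components \code{counts}
#'   (\linkS4class{AlleleCounts}, cell types attached), \code{clones}
#'   (per-cell "healthy"/"cancer"), \code{variant_class} (per-variant
#'   somatic/germline/loh/noise), \code{loh_state} (cancer VAF of LOH
#'   variants), \code{cell_types} (barcode/cell_type data.frame) and
#'   \code{genotype_vaf} (the planted true-VAF matrix, variants x cells).
#' @export
simulateClonalData <- function(n_cells = 500,
                               clone_fractions = c(healthy = 0.6,
                                                   cancer = 0.4),
                               n_somatic = 30, n_germline = 50,
                               n_loh = 10, n_noise = 200,
                               p_expr = 0.3, mean_depth = 4,
                               dropout = 0.2, error_rate = 0.01,
                               noise_rate = 0.02,
                               healthy_type_fraction = 0.3,
                               cancer_type_fraction = 0.3,
                               healthy_type_name = "T-cell",
                               cancer_type_name = "Blast",
                               seed = 1) {
    stopifnot(abs(sum(clone_fractions) - 1) < 1e-8,
              all(clone_fractions >= 0),
              p_expr > 0, p_expr <= 1, mean_depth >= 1,
              dropout >= 0, dropout < 1,
              error_rate >= 0, error_rate < 0.5,
              n_cells >= 2)
    set.seed(seed)
    n_cancer <- round(n_cells * clone_fractions[["cancer"]])
    clones <- rep("healthy", n_cells)
    clones[sample.int(n_cells, n_cancer)] <- "cancer"

    n_vars <- n_somatic + n_germline + n_loh + n_noise
    if (n_vars < 1) stop("no variants requested")
    variant_class <- rep(c("somatic", "germline", "loh", "noise"),
                         c(n_somatic, n_germline, n_loh, n_noise))
    loh_state <- rep(NA_real_, n_vars)
    if (n_loh > 0)
        loh_state[variant_class == "loh"] <-
            rep_len(c(0, 1), n_loh)[sample.int(n_loh)]

    # planted true VAF, variants x cells
    vaf <- matrix(0, n_vars, n_cells)
    cancer <- clones == "cancer"
    vaf[variant_class == "somatic", cancer] <- 0.5
    vaf[variant_class == "germline", ] <- 0.5
    if (n_loh > 0) {
        vaf[variant_class == "loh", !cancer] <- 0.5
        vaf[variant_class == "loh", cancer] <-
            loh_state[variant_class == "loh"]
    }
    genotype_vaf <- vaf

    # sporadic ALT observations at noise variants
    if (n_noise > 0) {
        noise_hits <- matrix(
            stats::rbinom(n_noise * n_cells, 1, noise_rate) == 1,
            n_noise, n_cells)
        noise_vaf <- vaf[variant_class == "noise", , drop = FALSE]
        noise_vaf[noise_hits] <- 0.5
        vaf[variant_class == "noise", ] <- noise_vaf
    }

    expressed <- matrix(stats::rbinom(n_vars * n_cells, 1, p_expr) == 1,
                        n_vars, n_cells)
    depth <- matrix(0L, n_vars, n_cells)
    n_expr <- sum(expressed)
    if (n_expr == 0) stop("configuration implies zero covered entries")
    depth[expressed] <- 1L + stats::rpois(n_expr, max(mean_depth - 1, 0))

    # per-allele dropout turns heterozygous sites into effective VAF 0/1,
    # or removes coverage entirely when both alleles drop
    eff_vaf <- vaf
    het <- expressed & vaf == 0.5
    n_het <- sum(het)
    if (n_het > 0 && dropout > 0) {
        drop_alt <- stats::rbinom(n_het, 1, dropout) == 1
        drop_ref <- stats::rbinom(n_het, 1, dropout) == 1
        v <- rep(0.5, n_het)
        v[drop_alt & !drop_ref] <- 0
        v[!drop_alt & drop_ref] <- 1
        eff_vaf[het] <- v
        both <- which(het)[drop_alt & drop_ref]
        depth[both] <- 0L
    }

    # per-read error flips REF<->ALT independently
    p_alt <- eff_vaf * (1 - error_rate) + (1 - eff_vaf) * error_rate
    ad <- matrix(0L, n_vars, n_cells)
    covered <- depth > 0
    ad[covered] <- stats::rbinom(sum(covered), depth[covered],
                                 p_alt[covered])

    barcodes <- sprintf("cell%04d", seq_len(n_cells))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_vars, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                  character(1))
    variants <- DataFrame(
        chrom = paste0("chr", 1 + (seq_len(n_vars) - 1) %% 22),
        pos = 1000L + 10L * seq_len(n_vars),
        ref = ref, alt = unname(alt),
        is_germline_common = variant_class == "germline",
        is_rna_edit = FALSE, in_repeat_region = FALSE)

    type <- rep("unknown", n_cells)
    type[!cancer & stats::runif(n_cells) < healthy_type_fraction] <-
        healthy_type_name
    type[cancer & stats::runif(n_cells) < cancer_type_fraction] <-
        cancer_type_name
    cell_types <- data.frame(barcode = barcodes, cell_type = type)

    counts <- AlleleCounts(Matrix(ad, sparse = TRUE),
                           Matrix(depth, sparse = TRUE),
                           variants, barcodes,
                           cell_types = stats::setNames(type, barcodes))
    list(counts = counts,
         clones = stats::setNames(clones, barcodes),
         variant_class = variant_class,
         loh_state = loh_state,
         cell_types = cell_types,
         genotype_vaf = genotype_vaf)
}

#' Binomially thin the allele counts
#'
#' Each alternative-allele count and each reference count is independently
#' thinned as Binomial(count, fraction); the depth is recomputed as their
#' sum, so thinning can never produce AD > DP and the expected total count
#' is \code{fraction} times the original. This is the perturbation used to
#' probe how clone recovery degrades with sequencing depth.
#'
#' @param counts an \linkS4class{AlleleCounts}.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return A thinned \linkS4class{AlleleCounts} with identical metadata.
#' @export
subsampleCounts <- function(counts, fraction, seed = 1) {
    stopifnot(fraction > 0, fraction <= 1)
    if (fraction == 1) return(counts)
    set.seed(seed)
    ad <- methods::as(adCounts(counts), "TsparseMatrix")
    dp <- methods::as(dpCounts(counts), "TsparseMatrix")
    key_dp <- paste(dp@i, dp@j)
    alt_at_dp <- integer(length(dp@x))
    alt_at_dp[match(paste(ad@i, ad@j), key_dp)] <- as.integer(ad@x)
    ref_at_dp <- as.integer(dp@x) - alt_at_dp
    new_alt <- stats::rbinom(length(dp@x), alt_at_dp, fraction)
    new_ref <- stats::rbinom(length(dp@x), ref_at_dp, fraction)
    new_dp <- Matrix::sparseMatrix(
        i = dp@i + 1L, j = dp@j + 1L, x = new_alt + new_ref,
        dims = dim(dp))
    new_ad <- Matrix::sparseMatrix(
        i = dp@i + 1L, j = dp@j + 1L, x = new_alt, dims = dim(dp))
    ct <- colData(counts)$cell_type
    ct <- if (all(is.na(ct))) NULL else
        stats::setNames(ct, cellBarcodes(counts))
    AlleleCounts(Matrix::drop0(new_ad), Matrix::drop0(new_dp),
                 rowData(counts), cellBarcodes(counts), cell_types = ct)
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits the cellsnp-lite trio (VCF + AD/DP Matrix Market + barcode TSV), an
#' annotation table flagging the planted germline variants as dbSNP-common,
#' the cell-type table and truth TSVs (per-cell clone, per-variant class).
#'
#' @param sim result of \code{\link{simulateClonalData}}.
#' @param dir output directory.
#' @return Invisibly, the vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- writeCellsnp(sim$counts, dir)
    rd <- rowData(sim$counts)
    ann <- data.frame(chrom = rd$chrom, pos = rd$pos, ref = rd$ref,
                      alt = rd$alt,
                      is_germline_common = rd$is_germline_common,
                      is_rna_edit = rd$is_rna_edit,
                      in_repeat_region = rd$in_repeat_region)
    p_ann <- file.path(dir, "annotations.tsv")
    utils::write.table(ann, p_ann, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_ct <- file.path(dir, "cell_types.tsv")
    utils::write.table(sim$cell_types, p_ct, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_cells <- data.frame(barcode = names(sim$clones),
                              clone = unname(sim$clones))
    p_tc <- file.path(dir, "truth_cells.tsv")
    utils::write.table(truth_cells, p_tc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_vars <- data.frame(variant = variantKeys(sim$counts),
                             class = sim$variant_class,
                             loh_state = sim$loh_state)
    p_tv <- file.path(dir, "truth_variants.tsv")
    utils::write.table(truth_vars, p_tv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(paths, annotations = p_ann, cell_types = p_ct,
                truth_cells = p_tc, truth_variants = p_tv))
}
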