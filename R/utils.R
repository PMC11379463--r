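#' @importFrom Rcpp evalCpp
#' @useDynLib CloneNMF, .registration = TRUE
NULL

# Deterministic 31-bit seed derivation: fold the master seed and any number
# of string/integer tokens so that per-(subset, K, replicate) streams are
# independent of grid order and always fit a 32-bit R integer.
deriveSeed <- function(master, ...) {
    tokens <- unlist(lapply(list(...), function(x) {
        if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else
            as.integer(x)
    }))
    h <- as.numeric(master) %% 2147483647
    for (t in c(tokens, 0)) {
        h <- (h * 69069 + as.numeric(t) + 1) %% 2147483647
    }
    as.integer(h)
}

.cosine <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
}

# Pairwise cosine similarity between columns of A and columns of B
# (zero-norm columns get similarity 0 to everything).
.cosine_matrix <- function(A, B) {
    na <- sqrt(colSums(A^2))
    nb <- sqrt(colSums(B^2))
    S <- crossprod(A, B)
    denom <- outer(na, nb)
    out <- ifelse(denom > 0, S / denom, 0)
    matrix(out, nrow = ncol(A))
}

.log_stage <- function(verbose, fmt, ...) {
    if (verbose) message(sprintf(paste0("[%s] ", fmt),
                                 format(Sys.time(), "%H:%M:%S"), ...))
}
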