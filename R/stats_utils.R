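# Shared statistical utilities used by all analysis stages.

#' Benjamini-Hochberg false discovery rates
#'
#' Shared FDR utility used by every stage of the package (a thin wrapper
#' around \code{stats::p.adjust(method = "BH")} so the procedure is defined in
#' exactly one place).
#'
#' @param p numeric vector of p-values (NAs preserved).
#' @return adjusted p-values (q-values).
#' @export
adjustFDR <- function(p) p.adjust(p, method = "BH")

# Vectorized two-sided Wilcoxon rank-sum test across matrix rows.
# Normal approximation with tie correction and continuity correction,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE).
# x: numeric matrix (features x samples); idxA/idxB: disjoint column indices.
# Returns data.frame(statistic = U for group A, p).
rowWilcoxon <- function(x, idxA, idxB) {
    nA <- length(idxA)
    nB <- length(idxB)
    if (nA < 2 || nB < 2) stop("each group needs at least 2 samples")
    n <- nA + nB
    sub <- x[, c(idxA, idxB), drop = FALSE]
    res <- t(apply(sub, 1L, function(v) {
        r <- rank(v)
        U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
        ties <- rle(sort.int(v))$lengths
        tieTerm <- sum(as.numeric(ties)^3 - ties)
        sigma2 <- (nA * nB / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
        if (sigma2 <= 0) return(c(U, 1))  # all values tied
        z <- U - nA * nB / 2
        z <- (z - sign(z) * 0.5) / sqrt(sigma2)
        c(U, min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))))
    }))
    data.frame(statistic = res[, 1], p = res[, 2],
               row.names = rownames(x))
}

# Pearson correlation of each matrix row with a vector, with the two-sided
# p-value of stats::cor.test. Constant rows yield NA.
rowPearson <- function(x, y) {
    n <- length(y)
    xc <- x - rowMeans(x)
    yc <- y - mean(y)
    denom <- sqrt(rowSums(xc^2)) * sqrt(sum(yc^2))
    r <- as.vector(xc %*% yc) / denom
    r[denom == 0 | !is.finite(r)] <- NA
    df <- n - 2
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df)
    p[!is.na(r) & abs(r) >= 1] <- 0
    data.frame(r = r, p = p, row.names = rownames(x))
}

# Rank-based AUC of scores for the positive class against the negative class.
rankAUC <- function(scores, positive) {
    r <- rank(scores)
    nP <- sum(positive)
    nN <- sum(!positive)
    (sum(r[positive]) - nP * (nP + 1) / 2) / (nP * nN)
}

# log2 fold change as difference of group means of log2-normalized values
log2FCMeans <- function(x, idxA, idxB) {
    rowMeans(x[, idxA, drop = FALSE]) - rowMeans(x[, idxB, drop = FALSE])
}

#' Overlap of two gene sets
#'
#' Exact set arithmetic between two gene lists.
#'
#' @param listA,listB character vectors (duplicates ignored).
#' @return a list with \code{nA_only}, \code{n_shared}, \code{nB_only} and
#'   \code{shared}, the common genes.
#' @examples
#' overlapSets(c("a", "b", "c"), c("b", "c", "d"))
#' @export
overlapSets <- function(listA, listB) {
    a <- unique(listA)
    b <- unique(listB)
    shared <- intersect(a, b)
    list(nA_only = length(setdiff(a, b)),
         n_shared = length(shared),
         nB_only = length(setdiff(b, a)),
         shared = shared)
}
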