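suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(IRanges)
})

## Hand-built 10-row QC fixture on the 3 vs 3 design: 2 high-PEP rows, 1
## reverse, 1 contaminant, 2 rows with more missing cells than the larger
## group size (> 3 of 6), 4 clean rows.
makeFilterFixture <- function() {
    d <- sampleDesign()
    m <- matrix(2^20, 10, 6, dimnames = list(sprintf("FIXPEP%02d", 1:10),
                                             d$sample_id))
    m[5, 1:4] <- NA  # 4 of 6 missing -> removed
    m[6, 1:5] <- NA  # 5 of 6 missing -> removed
    m[7, 1:3] <- NA  # 3 of 6 missing -> retained (boundary)
    pep <- c(0.2, 0.15, rep(0.01, 8))
    reverse <- c(rep(FALSE, 2), TRUE, rep(FALSE, 7))
    contaminant <- c(rep(FALSE, 3), TRUE, rep(FALSE, 6))
    PeptideExperiment(m, as.list(sprintf("P%02d", 1:10)), pep, reverse,
                      contaminant, d)
}

## Minimal well-formed peptide TSV written from raw text (independent of the
## package's writer), for parser tests.
writePeptideFixtureTSV <- function(path) {
    hdr <- paste(c("Sequence", "Proteins", "PEP", "Reverse", "Contaminant",
                   paste("Reporter intensity", 126:131)), collapse = "\t")
    rows <- c(
        paste(c("AAAK", "P1", "0.01", "", "",
                c("1000", "2000", "3000", "4000", "5000", "6000")),
              collapse = "\t"),
        paste(c("CCCK", "P1;P2", "0.02", "", "",
                c("0", "150.5", "200", "", "300", "400")),
              collapse = "\t"),
        paste(c("DDDK", "P3", "0.2", "+", "",
                c("10", "20", "30", "40", "50", "60")), collapse = "\t"),
        paste(c("EEEK", "", "0.03", "", "+",
                c("7", "8", "9", "10", "11", "12")), collapse = "\t"),
        paste(c("FFFK", "P4", "0.04", "", "",
                c("1", "2", "3", "4", "5", "0")), collapse = "\t"))
    writeLines(c(hdr, rows), path)
    path
}

## Directly-coded one-step biweight (the independent oracle for the rollup).
oracleBiweight <- function(x, c = 5, epsilon = 1e-4) {
    x <- x[!is.na(x)]
    M <- median(x)
    S <- median(abs(x - M))
    num <- 0; den <- 0
    for (xi in x) {
        u <- (xi - M) / (c * S + epsilon)
        if (abs(u) < 1) {
            w <- (1 - u^2)^2
            num <- num + w * xi
            den <- den + w
        }
    }
    if (den == 0) M else num / den
}

## Closed-form Welch statistics (independent oracle).
oracleWelch <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vx <- var(x); vy <- var(y)
    se2 <- vx / nx + vy / ny
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## Exhaustive-permutation two-sided Mann-Whitney p (depends only on ranks).
oracleRankSumExact <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- rank(c(x, y))
    u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) sum(pooled[ix]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu))
}

## Razor-rule oracle: assign each peptide to the parent with most peptides
## (alphabetical tie-break), then sum linear intensities per protein/sample.
oracleRazor <- function(m, pairs) {
    counts <- table(pairs$protein)
    assign <- vapply(split(pairs$protein, pairs$peptide), function(ps) {
        ps[order(-counts[ps], ps)][1]
    }, "")
    lin <- 2^m
    prots <- sort(unique(assign))
    out <- matrix(NA_real_, length(prots), ncol(m),
                  dimnames = list(prots, colnames(m)))
    for (p in prots) {
        sub <- lin[names(assign)[assign == p], , drop = FALSE]
        s <- colSums(sub, na.rm = TRUE)
        s[colSums(!is.na(sub)) == 0] <- NA
        out[p, ] <- s
    }
    out
}
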