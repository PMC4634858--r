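test_that("the QC cascade removes and attributes rows as designed", {
    pe <- makeFilterFixture()
    res <- filterPeptides(pe)
    expect_equal(res$report$removed_pep, 2L)
    expect_equal(res$report$removed_reverse, 1L)
    expect_equal(res$report$removed_contaminant, 1L)
    expect_equal(res$report$removed_missingness, 2L)
    expect_equal(res$report$retained, 4L)
    expect_setequal(rownames(res$peptides),
                    c("FIXPEP07", "FIXPEP08", "FIXPEP09", "FIXPEP10"))
    ## conservation and idempotence
    with(res$report, expect_equal(
        removed_pep + removed_reverse + removed_contaminant +
        removed_missingness + retained, n_input))
    again <- filterPeptides(res$peptides)
    expect_identical(assay(again$peptides, "intensity"),
                     assay(res$peptides, "intensity"))
    expect_equal(again$report$retained, 4L)
    expect_equal(again$report$removed_pep, 0L)
})

test_that("PEP and missingness boundaries are strict / literal", {
    d <- sampleDesign()
    m <- matrix(100, 3, 6, dimnames = list(c("A", "B", "C"), d$sample_id))
    pe <- PeptideExperiment(m, as.list(c("P1", "P2", "P3")),
                            pep = c(0.10, 0.05, 0.2),
                            reverse = rep(FALSE, 3),
                            contaminant = rep(FALSE, 3), design = d)
    res <- filterPeptides(pe, pep_threshold = 0.1)
    expect_setequal(rownames(res$peptides), c("A", "B"))  # 0.10 kept, 0.2 out

    m2 <- matrix(100, 2, 6, dimnames = list(c("X", "Y"), d$sample_id))
    m2[1, 1:4] <- NA  # 4 missing > max(3, 3) -> removed
    m2[2, 1:3] <- NA  # 3 missing -> retained
    pe2 <- PeptideExperiment(m2, as.list(c("P1", "P2")), c(0.01, 0.01),
                             c(FALSE, FALSE), c(FALSE, FALSE), d)
    res2 <- filterPeptides(pe2)
    expect_identical(rownames(res2$peptides), "Y")
    expect_equal(res2$report$removed_missingness, 1L)
})

test_that("log2 transform maps values and preserves missingness", {
    m <- matrix(c(8, 1, NA, 0.5), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    lg <- log2Transform(m)
    expect_equal(lg["a", "s1"], 3)
    expect_equal(lg["b", "s1"], 0)
    expect_true(is.na(lg["a", "s2"]))
    expect_equal(lg["b", "s2"], -1)
    m[1, 2] <- -4
    expect_error(log2Transform(m), "'a'.*'s2'")
})

test_that("reference selection picks the median-mean sample, ties early", {
    mk <- function(means) {
        m <- matrix(rep(means, each = 4), 4,
                    dimnames = list(paste0("f", 1:4),
                                    paste0("s", seq_along(means))))
        m
    }
    expect_equal(selectReferenceSample(mk(c(10, 11, 15))), "s2")
    expect_equal(selectReferenceSample(mk(7)), "s1")
    ## median of {10,12,12,20} is 12; two candidates at distance 0 -> earlier
    expect_equal(selectReferenceSample(mk(c(10, 12, 12, 20))), "s2")
    m <- mk(c(10, 11, 15))
    m[, 3] <- NA
    expect_warning(ref <- selectReferenceSample(m), "all-missing")
    expect_equal(ref, "s1")  # means {10, 11}, median 10.5, tie -> earlier
})

test_that("a pure log2 shift is removed exactly and the reference untouched", {
    set.seed(77)
    ref <- rnorm(500, 20, 2)
    shifts <- c(0, 1.5, -2, 0.25)
    m <- sapply(shifts, function(s) ref + s)
    dimnames(m) <- list(paste0("f", 1:500), paste0("s", 1:4))
    res <- normalizeToReference(m, "s1")
    expect_identical(res$matrix[, "s1"], m[, "s1"])   # bit-for-bit
    expect_equal(unname(res$offsets), shifts, tolerance = 1e-9)
    expect_lt(max(abs(res$matrix - ref)), 1e-9)
})

test_that("offset recovery resists contaminated features", {
    set.seed(78)
    ref <- rnorm(400, 20, 2)
    s <- ref + 1.5
    idx <- sample(400, 40)                      # 10% contamination
    s[idx] <- s[idx] + sample(c(-5, 5), 40, TRUE)
    m <- cbind(s1 = ref, s2 = s)
    rownames(m) <- paste0("f", 1:400)
    res <- normalizeToReference(m, "s1")
    expect_lt(abs(res$offsets["s2"] - 1.5), 0.05)
})

test_that("normalization is equivariant to feature order", {
    set.seed(79)
    m <- cbind(s1 = rnorm(200, 20, 2), s2 = rnorm(200, 20, 2) + 0.8)
    rownames(m) <- paste0("f", 1:200)
    res1 <- normalizeToReference(m, "s1")
    perm <- sample(200)
    res2 <- normalizeToReference(m[perm, ], "s1")
    expect_equal(res2$offsets, res1$offsets)
    expect_equal(res2$matrix, res1$matrix[perm, ])
})

test_that("sparse overlap falls back to a median-difference offset", {
    m <- cbind(s1 = c(rnorm(10, 20), rep(NA, 10)),
               s2 = c(rep(NA, 10), rnorm(10, 20)))
    m[1:5, 2] <- m[1:5, 1] + 2
    rownames(m) <- paste0("f", 1:20)
    expect_warning(res <- normalizeToReference(m, "s1"), "median-difference")
    expect_equal(unname(res$offsets["s2"]), 2, tolerance = 1e-9)
})
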