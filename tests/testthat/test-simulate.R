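test_that("ground truth is seeded-deterministic with exact DE allocation", {
    p <- simParams(n_proteins = 1000, frac_de = 0.1, seed = 9)
    t1 <- generateGroundTruth(p)
    t2 <- generateGroundTruth(p)
    expect_identical(t1, t2)
    expect_equal(sum(t1$delta != 0), 100L)  # round(frac_de * n)
    expect_true(all(abs(t1$delta[t1$delta != 0]) == p$de_log2fc))

    p0 <- simParams(n_proteins = 50, frac_de = 0, seed = 2)
    expect_true(all(generateGroundTruth(p0)$delta == 0))
    expect_error(simParams(n_proteins = 0), "n_proteins")
})

test_that("peptide and microarray simulation are reproducible", {
    p <- simParams(n_proteins = 30, seed = 13)
    tr <- generateGroundTruth(p)
    expect_identical(assay(simulatePeptideTable(tr, p), "intensity"),
                     assay(simulatePeptideTable(tr, p), "intensity"))
    expect_identical(simulateMicroarray(tr, p)$exprs,
                     simulateMicroarray(tr, p)$exprs)
})

test_that("noise-free unshared simulation reproduces truth exactly", {
    p <- simParams(n_proteins = 25, frac_shared = 0,
                   peptide_efficiency_sd = 0, channel_noise_sd = 0,
                   missingness = c(-50, 0), frac_decoy = 0,
                   frac_contaminant = 0, seed = 3)
    tr <- generateGroundTruth(p)
    pe <- simulatePeptideTable(tr, p)
    lg <- log2Transform(pe)
    parent <- vapply(peptideProteins(pe), `[`, "", 1L)
    expect_lt(max(abs(lg - tr$abundance[parent, ])), 1e-9)
    ## full rollup recovers the truth to machine precision
    pq <- rollupProteins(lg, buildPeptideProteinMap(pe))
    expect_lt(max(abs(assay(pq, "log2intensity") -
                      tr$abundance[rownames(pq), ])), 1e-9)
})

test_that("a peptide shared by two equal-abundance proteins doubles signal", {
    p <- simParams(n_proteins = 2, frac_shared = 1,
                   protein_baseline = c(12, 0), peptide_efficiency_sd = 0,
                   channel_noise_sd = 0, missingness = c(-50, 0),
                   frac_decoy = 0, frac_contaminant = 0, frac_de = 0,
                   seed = 4)
    tr <- generateGroundTruth(p)
    lg <- log2Transform(simulatePeptideTable(tr, p))
    expect_equal(unname(lg[1, 1]), 13, tolerance = 1e-12)  # log2(2 * 2^12)
})

test_that("realized MCAR missingness and row fractions match parameters", {
    rate <- 0.2
    p <- simParams(n_proteins = 150, missingness = c(qlogis(rate), 0),
                   frac_decoy = 0.05, frac_contaminant = 0.02, seed = 21)
    tr <- generateGroundTruth(p)
    pe <- simulatePeptideTable(tr, p)
    x <- assay(pe, "intensity")
    n_cells <- length(x)
    ## 99% binomial band for the realized missing fraction
    band <- qbinom(c(0.005, 0.995), n_cells, rate) / n_cells
    expect_gte(mean(is.na(x)), band[1])
    expect_lte(mean(is.na(x)), band[2])
    n_true <- nrow(tr$peptides)
    expect_equal(sum(isReverse(pe)), round(0.05 * n_true))
    expect_equal(sum(isContaminant(pe)), round(0.02 * n_true))
    expect_true(all(peptidePEP(pe)[isReverse(pe)] > 0.1))
})

test_that("microarray construction honours the correlation target", {
    ## rho = 1, no array noise: every per-pair correlation is exactly 1
    p1 <- simParams(n_proteins = 40, bio_sd = 1, gene_protein_corr = 1,
                    array_noise_sd = 0, frac_de = 0, seed = 6)
    tr1 <- generateGroundTruth(p1)
    arr1 <- simulateMicroarray(tr1, p1)
    pairs1 <- matchProbesToProteins(arr1$exprs, arr1$map, tr1$abundance)
    pp <- perPairConcordance(pairs1)
    expect_equal(pp$mean_pearson_r, 1, tolerance = 1e-12)
    expect_equal(pp$n_undefined, 0L)

    ## rho = 0: mean per-pair r near 0 (99% Monte-Carlo band, n genes = 300)
    p0 <- simParams(n_proteins = 300, bio_sd = 1, gene_protein_corr = 0,
                    frac_de = 0, seed = 7)
    tr0 <- generateGroundTruth(p0)
    arr0 <- simulateMicroarray(tr0, p0)
    pairs0 <- matchProbesToProteins(arr0$exprs, arr0$map, tr0$abundance)
    m0 <- perPairConcordance(pairs0)$mean_pearson_r
    ## per-pair r at n=6 has sd ~ 1/sqrt(5); mean over 300 pairs
    expect_lt(abs(m0), 2.6 / sqrt(5) / sqrt(300) * 3)
})

test_that("fixed probes-per-gene yields exactly 2 pairs per gene", {
    p <- simParams(n_proteins = 30, probes_per_gene_mean = 2,
                   probes_per_gene_model = "fixed", seed = 8)
    tr <- generateGroundTruth(p)
    arr <- simulateMicroarray(tr, p)
    expect_equal(nrow(arr$map), 60L)
    expect_true(all(table(arr$map$protein_id) == 2L))
})

test_that("simulated studies land in the printed dataset-summary ranges", {
    p <- simParams(seed = 31)   # defaults = study conditions
    tr <- generateGroundTruth(p)
    pe <- simulatePeptideTable(tr, p)
    flt <- filterPeptides(pe)
    x <- assay(flt$peptides, "intensity")
    expect_lt(mean(is.na(x)), 0.01)          # reporter-ion-like missingness
    pq <- rollupProteins(log2Transform(flt$peptides),
                         buildPeptideProteinMap(flt$peptides))
    frac_single <- mean(isSinglePeptide(pq))
    expect_gt(frac_single, 0.16)
    expect_lt(frac_single, 0.31)
    expect_gt(mean(nPeptides(pq)), 5)
    expect_lt(mean(nPeptides(pq)), 9)
})
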