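mkPairsFixture <- function() {
    ## 3 proteins x 6 samples; gene profiles constructed from protein rows
    set.seed(70)
    prot <- matrix(rnorm(18, 10), 3, 6,
                   dimnames = list(c("P1", "P2", "P3"), paste0("s", 1:6)))
    exprs <- rbind(pA = prot["P1", ] + 1,
                   pB = prot["P1", ] + 3,
                   pC = prot["P2", ] - 2,
                   pD = prot["P3", ] * 0 + 5)
    colnames(exprs) <- colnames(prot)
    map <- data.frame(probe_id = c("pA", "pB", "pC", "pD"),
                      protein_id = c("P1", "P1", "P2", "P3"))
    list(prot = prot, exprs = exprs, map = map)
}

test_that("probe selection follows highest mean intensity with stable ties", {
    f <- mkPairsFixture()
    pairs <- matchProbesToProteins(f$exprs, f$map, f$prot)
    expect_equal(pairs$probe[pairs$protein == "P1"], "pB")  # mean +3 > +1
    ## protein without probe excluded; probe without protein row ignored
    map2 <- rbind(f$map, data.frame(probe_id = "pZ", protein_id = "P9"))
    pairs2 <- matchProbesToProteins(f$exprs, map2, f$prot)
    expect_setequal(pairs2$protein, c("P1", "P2", "P3"))
    ## exact tie -> lexicographically smaller probe id, order-invariant
    exprs_tie <- rbind(f$exprs, pAA = f$exprs["pB", ])
    map_tie <- rbind(f$map, data.frame(probe_id = "pAA", protein_id = "P1"))
    for (perm in list(1:5, 5:1, c(3, 1, 5, 2, 4))) {
        p3 <- matchProbesToProteins(exprs_tie[perm, ], map_tie, f$prot)
        expect_equal(p3$probe[p3$protein == "P1"], "pAA")
    }
    expect_error(matchProbesToProteins(f$exprs, f$map[0, ], f$prot),
                 "empty|intersection")
})

test_that("global concordance pools pairs and reduces to per-pair for one", {
    f <- mkPairsFixture()
    ## genes identical to proteins -> pooled r = 1
    exprs_eq <- f$prot
    rownames(exprs_eq) <- c("gA", "gB", "gC")
    map_eq <- data.frame(probe_id = c("gA", "gB", "gC"),
                         protein_id = c("P1", "P2", "P3"))
    pairs <- matchProbesToProteins(exprs_eq, map_eq, f$prot)
    gc <- globalConcordance(pairs)
    expect_equal(gc$pearson$r, 1, tolerance = 1e-12)
    expect_equal(gc$spearman$r, 1, tolerance = 1e-12)
    ## a single pair equals the per-pair correlation
    one <- matchProbesToProteins(f$exprs, f$map[3, , drop = FALSE], f$prot)
    expect_equal(globalConcordance(one)$pearson$r,
                 perPairConcordance(one)$per_pair$pearson_r, tolerance = 1e-12)
})

test_that("per-pair concordance means, counts and significance rules", {
    f <- mkPairsFixture()
    exprs_eq <- f$prot
    rownames(exprs_eq) <- c("gA", "gB", "gC")
    map_eq <- data.frame(probe_id = c("gA", "gB", "gC"),
                         protein_id = c("P1", "P2", "P3"))
    cp <- perPairConcordance(matchProbesToProteins(exprs_eq, map_eq, f$prot))
    expect_equal(cp$mean_pearson_r, 1, tolerance = 1e-12)
    expect_equal(cp$n_sig_pearson, 3L)
    expect_equal(cp$n_undefined, 0L)

    ## constant probe -> undefined, excluded from mean, counted
    cpd <- perPairConcordance(matchProbesToProteins(f$exprs, f$map, f$prot))
    expect_equal(cpd$n_undefined, 1L)  # pD is constant
    expect_equal(cpd$n_pairs, 3L)

    ## r = 0.55 at n = 6 is NOT significant (r > 0.5 alone insufficient)
    x <- scale(rnorm(6))[, 1]
    e <- residuals(lm(rnorm(6) ~ x)); e <- e / sqrt(sum(e^2) / 5)
    y <- 0.55 * x + sqrt(1 - 0.55^2) * e
    prot1 <- matrix(x, 1, dimnames = list("P1", paste0("s", 1:6)))
    expr1 <- matrix(y, 1, dimnames = list("g1", paste0("s", 1:6)))
    cp1 <- perPairConcordance(matchProbesToProteins(
        expr1, data.frame(probe_id = "g1", protein_id = "P1"), prot1))
    expect_equal(cp1$per_pair$pearson_r, 0.55, tolerance = 1e-9)
    expect_gt(cp1$per_pair$pearson_p, 0.05)
    expect_equal(cp1$n_sig_pearson, 0L)
})

test_that("overlap regions partition the union, directions split correctly", {
    ov <- overlapSets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
    expect_equal(unname(ov$regions["A"]), 1L)
    expect_equal(unname(ov$regions["B"]), 1L)
    expect_equal(unname(ov$regions["A&B"]), 2L)
    expect_equal(sum(ov$regions), ov$union_size)

    s <- c("x", "y", "z")
    ov3 <- overlapSets(list(A = s, B = s, C = s))
    expect_equal(unname(ov3$regions["A&B&C"]), 3L)
    expect_equal(sum(ov3$regions[c("A", "B", "C", "A&B", "A&C", "B&C")]), 0L)

    ovd <- overlapSets(list(A = c("u", "v"), B = c("u", "v")),
                       log2fc = list(A = c(u = 1, v = 2),
                                     B = c(u = 0.5, v = -1)))
    expect_equal(ovd$direction[["A&B"]]$same_direction, 1L)
    expect_equal(ovd$direction[["A&B"]]$opposite, 1L)
})

test_that("overlap conservation holds across random instances", {
    set.seed(71)
    for (i in 1:50) {
        k <- sample(2:3, 1)
        sets <- setNames(lapply(seq_len(k), function(j)
            sample(letters, sample(3:20, 1))), LETTERS[seq_len(k)])
        ov <- overlapSets(sets)
        expect_equal(sum(ov$regions), length(unique(unlist(sets))))
    }
})

test_that("cross-study comparison recovers construction-known overlap", {
    p1 <- simParamsTMT(n_proteins = 60, seed = 80)
    p2 <- simParamsLabelFree(n_proteins = 60, seed = 80,
                             channel_noise_sd = 0.4)
    tr <- generateGroundTruth(p1)
    mkStudy <- function(params) {
        pe <- filterPeptides(simulatePeptideTable(tr, params))$peptides
        pq <- rollupProteins(log2Transform(pe), buildPeptideProteinMap(pe))
        dt <- callSignificant(differentialExpression(
            assay(pq, "log2intensity"),
            setNames(tr$design$group, tr$design$sample_id),
            c("ADC", "SCC")))
        list(peptides = pe, differential = dt)
    }
    s1 <- mkStudy(p1); s2 <- mkStudy(p2)
    rep <- crossStudyCompare(list(tmt = s1, lf = s2))

    expect_equal(nrow(rep$per_study), 2L)
    ## label-free-like preset has far more missingness
    expect_gt(rep$per_study$missing_fraction[2],
              10 * rep$per_study$missing_fraction[1])
    ## same truth -> shared peptides = intersection of retained sequences
    pw <- rep$pairwise[[1]]
    expect_equal(pw$n_shared_peptides,
                 length(intersect(rownames(s1$peptides),
                                  rownames(s2$peptides))))
    expect_gt(pw$intensity_pearson_r, 0.5)
    expect_gte(pw$de_same_direction, pw$de_opposite)
    ## DE counts are monotone across nested p thresholds
    expect_true(all(rep$per_study$de_p05 >= rep$per_study$de_p01))
    expect_true(all(rep$per_study$de_p01 >= rep$per_study$de_p001))

    ## self-comparison: overlap is the study's own set, intensity r = 1
    self <- crossStudyCompare(list(a = s1, b = s1))
    expect_equal(self$pairwise[[1]]$n_shared_peptides, nrow(s1$peptides))
    expect_equal(self$pairwise[[1]]$intensity_pearson_r, 1,
                 tolerance = 1e-12)
    expect_error(crossStudyCompare(list(a = s1)), "two studies")
})
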