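two_type_profiles <- function() {
    ExpressionProfiles(matrix(c(10, 0, 0, 10), 2, 2,
        dimnames = list(c("gA", "gB"), c("T1", "T2"))), dispersion = 2)
}

test_that("the NB typer reproduces a hand likelihood ratio", {
    pr <- two_type_profiles()
    counts <- matrix(c(8L, 0L), 2, 1, dimnames = list(c("gA", "gB"), "c1"))
    res <- typeCells(counts, pr)
    expect_identical(res$type, "T1")
    expect_gt(res$posterior[1, "T1"], 0.99)
    # hand computation with the same floored means
    ll1 <- dnbinom(8, mu = 10, size = 2, log = TRUE) +
        dnbinom(0, mu = 1e-6, size = 2, log = TRUE)
    ll2 <- dnbinom(8, mu = 1e-6, size = 2, log = TRUE) +
        dnbinom(0, mu = 10, size = 2, log = TRUE)
    expect_equal(unname(res$posterior[1, "T1"]),
                 1 / (1 + exp(ll2 - ll1)), tolerance = 1e-12)
})

test_that("identical profiles give uniform posteriors and a stable tie-break", {
    mu <- matrix(5, 2, 3, dimnames = list(c("g1", "g2"),
                                          c("zT", "aT", "mT")))
    pr <- ExpressionProfiles(mu)
    counts <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("g1", "g2"), "c"))
    res <- typeCells(counts, pr)
    expect_equal(unname(res$posterior[1, ]), rep(1 / 3, 3))
    expect_identical(res$type, "aT")   # lexicographically first type
})

test_that("posteriors sum to one for every cell", {
    pp <- plantedProfiles()
    fld <- simulateField(pp$profiles, rownames(profileMeans(pp$profiles)),
                         300, seed = 2)
    res <- typeCells(fld$counts, pp$profiles)
    expect_equal(unname(rowSums(res$posterior)), rep(1, 300),
                 tolerance = 1e-12)
})

test_that("simulated fields stay in bounds and match profile means", {
    pr <- two_type_profiles()
    fld <- simulateField(pr, c("gA", "gB"), 5000,
                         field_size = c(800, 600), seed = 3)
    expect_true(all(fld$positions[, "x"] >= 0 & fld$positions[, "x"] <= 800))
    expect_true(all(fld$positions[, "y"] >= 0 & fld$positions[, "y"] <= 600))
    for (t in c("T1", "T2")) {
        idx <- fld$labels == t
        g <- if (t == "T1") "gA" else "gB"
        se <- sqrt((10 + 100 / 2) / sum(idx))
        expect_lt(abs(mean(fld$counts[g, idx]) - 10), 3 * se)
    }
    fld2 <- simulateField(pr, c("gA", "gB"), 50, seed = 3)
    fld3 <- simulateField(pr, c("gA", "gB"), 50, seed = 3)
    expect_identical(fld2$counts, fld3$counts)
    expect_error(simulateField(pr, character(0), 10), "empty")
    expect_error(simulateField(pr, "nope", 10), "absent")
})

test_that("single-type fields are labelled with that type", {
    pr <- ExpressionProfiles(matrix(4, 1, 1, dimnames = list("g", "only")))
    fld <- simulateField(pr, "g", 20, seed = 1)
    expect_true(all(fld$labels == "only"))
})

test_that("uninformative genes contribute ~0; sole discriminators carry all", {
    # gSame identical across types; gA/gB discriminate
    mu <- matrix(c(10, 0, 0, 10, 5, 5), 3, 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gSame"), c("T1", "T2")))
    pr <- ExpressionProfiles(mu)
    gc_ <- geneContributions(pr, c("gA", "gB", "gSame"), n_cells = 3000,
                             n_rep = 5, seed = 4)
    expect_true(all(abs(gc_$contribution["gSame", ]) < 0.02))

    # with a single discriminating gene, removing it leaves chance accuracy
    mu2 <- matrix(c(10, 0, 5, 5), 2, 2, byrow = TRUE,
                  dimnames = list(c("gOnly", "gSame"), c("T1", "T2")))
    gc2 <- geneContributions(ExpressionProfiles(mu2), c("gOnly", "gSame"),
                             n_cells = 2000, n_rep = 3, seed = 5)
    # accuracy(panel) - accuracy(without gOnly) is large for both types
    expect_gt(sum(gc2$contribution["gOnly", ]), 0.5)
})

test_that("planted markers have positive own-type contribution", {
    pp <- plantedProfiles()
    panel <- rownames(profileMeans(pp$profiles))
    markers <- names(pp$marker_map)
    own <- matrix(0, length(markers), 10, dimnames = list(markers, NULL))
    for (seed in 1:10) {
        gc_ <- geneContributions(pp$profiles, panel, n_cells = 3000,
                                 n_rep = 5, seed = seed)
        own[, seed] <- vapply(markers, function(g)
            gc_$contribution[g, pp$marker_map[g]], numeric(1))
    }
    # sign check: marker redundancy keeps each leave-one-out effect small
    # relative to Monte-Carlo noise, so assert the positive-sign rate over
    # (marker, seed) draws and the per-marker mean across seeds
    expect_gte(mean(own > 0), 0.9)
    expect_true(all(rowMeans(own) > 0))
})

test_that("a perfect candidate panel converges immediately", {
    pp <- plantedProfiles(n_noise = 0, base_mean = 0.25)
    candidates <- names(pp$marker_map)   # exactly 5 markers per type
    res <- curatePanel(candidates, pp$profiles, n_cells = 1500, n_rep = 2,
                       accuracy_target = 0.9, seed = 6)
    expect_true(res$converged)
    expect_identical(res$trace$iteration[nrow(res$trace)], 1L)
    expect_setequal(res$panel, candidates)
})

test_that("panel size is bounded by keep_per_type x types", {
    pp <- plantedProfiles(n_types = 2, markers_per_type = 8, n_noise = 10)
    res <- curatePanel(rownames(profileMeans(pp$profiles)), pp$profiles,
                       keep_per_type = 5, n_cells = 800, n_rep = 2,
                       max_iters = 4, seed = 7)
    expect_lte(length(res$panel), 10)
})

test_that("typing accuracy does not decrease with profile separation", {
    acc <- function(fold, seed) {
        pp <- plantedProfiles(fold = fold)
        fld <- simulateField(pp$profiles,
                             rownames(profileMeans(pp$profiles)), 500,
                             seed = seed)
        mean(typeCells(fld$counts, pp$profiles)$type == fld$labels)
    }
    a4 <- vapply(1:10, function(s) acc(4, s), numeric(1))
    a8 <- vapply(1:10, function(s) acc(8, s), numeric(1))
    se <- sd(a4) / sqrt(length(a4))
    expect_gte(mean(a8), mean(a4) - se)
})

test_that("typing ignores geometry: permuting positions changes nothing", {
    pp <- plantedProfiles()
    fld <- simulateField(pp$profiles, rownames(profileMeans(pp$profiles)),
                         200, seed = 8)
    r1 <- typeCells(fld$counts, pp$profiles)
    fld$positions <- fld$positions[sample(nrow(fld$positions)), ]
    r2 <- typeCells(fld$counts, pp$profiles)
    expect_identical(r1$type, r2$type)
})
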