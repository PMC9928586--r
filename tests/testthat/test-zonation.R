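reads_from_points <- function(x, y, gene = "G", panel = unique(gene)) {
    SpatialReads(data.frame(x = x, y = y, gene = gene), panel = panel)
}

test_that("square binning assigns reads to the nearest lattice centre", {
    # a read exactly at a centre lands in that bin
    rd <- reads_from_points(c(40, 41, -39), c(0, 2, 1))
    grid <- binReads(rd, "square", radius = 20)
    expect_equal(sum(binCounts(grid)), 3)
    expect_true(any(binCenters(grid)[, "x"] == 40 &
                    binCenters(grid)[, "y"] == 0))

    # brute-force nearest-centre oracle on random points
    set.seed(1)
    n <- 500
    x <- runif(n, -500, 500); y <- runif(n, -500, 500)
    rd <- reads_from_points(x, y, gene = paste0("g", seq_len(n)),
                            panel = paste0("g", seq_len(n)))
    grid <- binReads(rd, "square", radius = 20)
    cts <- binCounts(grid)
    ctr <- binCenters(grid)
    for (i in seq_len(n)) {
        b <- which(cts[, paste0("g", i)] == 1)
        expect_length(b, 1)
        d2 <- (ctr[, 1] - x[i])^2 + (ctr[, 2] - y[i])^2
        # assigned centre is (one of) the closest materialised centres
        expect_lte(d2[b], min(d2) + 1e-9)
        # and the point lies inside the bin square
        expect_lte(max(abs(ctr[b, 1] - x[i]), abs(ctr[b, 2] - y[i])),
                   20 + 1e-9)
    }
    expect_equal(sum(cts), n)
    expect_error(binReads(SpatialReads(
        data.frame(x = numeric(0), y = numeric(0),
                   gene = character(0)), panel = "g"), "square", 20),
        "empty")
})

test_that("airway detection is strictly greater-than on marker counts", {
    cts <- matrix(c(3L, 4L, 0L), 3, 1, dimnames = list(NULL, "EPCAM"))
    grid <- methods::new("BinGrid", geometry = "square", radius = 20,
                         centers = cbind(x = c(0, 40, 80), y = c(0, 0, 0)),
                         counts = cts, axial = matrix(integer(0), 0, 2))
    mask <- airwayBins(grid, "EPCAM", min_count = 3)
    expect_identical(unname(mask), c(FALSE, TRUE, FALSE))
    expect_error(airwayBins(grid, "SOX2"), "absent")

    # spot mode: summed epithelial markers, more-than-eight rule
    counts <- matrix(c(4L, 4L, 4L, 5L), 2, 2,
                     dimnames = list(c("m1", "m2"), c("s8", "s9")))
    sm <- toy_spot_matrix(counts)
    expect_identical(unname(airwaySpots(sm, c("m1", "m2"), 8)),
                     c(FALSE, TRUE))
})

test_that("radial distances equal hand geometry and apply the 140 um cutoff", {
    centers <- cbind(x = c(0, 100, 30, 0, 0, 200),
                     y = c(0, 0, 40, 150, 100, 0))
    mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
    ax <- radialAxis(centers, mask, max_radial = 140)
    expect_equal(ax$radial, c(0, 0, 50, 150, 100, 100))
    expect_identical(ax$excluded, c(FALSE, FALSE, FALSE, TRUE,
                                    FALSE, FALSE))
    expect_identical(ax$nearest[3], 1L)    # sqrt(30^2+40^2) from bin 1
    expect_error(radialAxis(centers, rep(FALSE, 6)), "empty")
})

test_that("spot-mode proximal-distal scores hit the printed endpoints", {
    counts <- matrix(c(9L, 7L, 0L, 0L,    # pure proximal spot
                       0L, 0L, 5L, 8L,    # pure distal spot
                       4L, 4L, 4L, 4L,    # balanced
                       0L, 0L, 0L, 0L),   # silent
                     4, 4, dimnames = list(
                         c("SOX2", "SCGB3A2", "ETV5", "TPPP3"),
                         paste0("s", 1:4)))
    pd <- unname(pdScoreST(counts, airway_mask = rep(TRUE, 4)))
    expect_identical(pd[1], -1)
    expect_identical(pd[2], 1)
    expect_equal(pd[4], 0)
    expect_true(all(pd >= -1 & pd <= 1))
    expect_error(pdScoreST(counts, rep(TRUE, 4),
                           proximal_genes = "SOX2",
                           distal_genes = "SOX2"), "disjoint")
})

test_that("balanced marker expression scores zero by symmetry", {
    set.seed(2)
    counts <- matrix(rpois(4 * 30, 5), 4, 30,
                     dimnames = list(c("SOX2", "SCGB3A2", "ETV5", "TPPP3"),
                                     paste0("s", 1:30)))
    counts[3:4, ] <- counts[1:2, ]    # distal mirrors proximal exactly
    pd <- pdScoreST(counts, rep(TRUE, 30))
    expect_equal(unname(pd), rep(0, 30))
})

test_that("the 1-D embedding recovers a planted gradient up to sign", {
    for (seed in 1:10) {
        sim <- simulateAirwayTissue(n_mesench_cells = 0, seed = seed)
        grid <- binReads(sim$reads, "square", radius = 20)
        mask <- airwayBins(grid, "EPCAM", 3)
        pd <- pdEmbeddingISS(grid, mask)
        # true pd of each airway bin from its centre's arc position
        true_pd <- 2 * binCenters(grid)[mask, "x"] / 2000 - 1
        rho <- cor(pd[mask], true_pd, method = "spearman")
        expect_gte(rho, 0.9)   # sign fixed by the proximal-marker rule
    }
    grid1 <- binReads(reads_from_points(rep(1:12 * 40, 2), rep(0, 24),
                                        gene = "EPCAM"), "square", 20)
    expect_error(pdEmbeddingISS(grid1, rep(TRUE, 12)), "constant")
})

test_that("scores propagate from the nearest airway bin with stable ties", {
    centers <- cbind(x = c(0, 100, 50, 300), y = c(0, 0, 0, 0))
    mask <- c(TRUE, TRUE, FALSE, FALSE)
    pd <- c(-1, 1, NA, NA)
    out <- propagatePD(pd, mask, centers)
    expect_identical(out[1], -1)      # airway bins keep their own score
    expect_identical(out[2], 1)
    expect_identical(out[3], -1)      # equidistant: lowest index wins
    expect_identical(out[4], 1)
    # brute-force nearest-airway oracle on random layouts
    set.seed(3)
    centers <- cbind(x = runif(40, 0, 500), y = runif(40, 0, 500))
    mask <- c(rep(TRUE, 10), rep(FALSE, 30))
    pd <- c(runif(10, -1, 1), rep(NA, 30))
    out <- propagatePD(pd, mask, centers)
    for (i in 11:40) {
        d <- sqrt((centers[1:10, 1] - centers[i, 1])^2 +
                  (centers[1:10, 2] - centers[i, 2])^2)
        expect_identical(out[i], pd[which.min(d)])
    }
})

test_that("ST-mode density maps equal a group-by oracle", {
    set.seed(4)
    n <- 200
    pd <- runif(n, -1, 1)
    radial <- sample(c(0, 40, 80, 120), n, replace = TRUE)
    fr <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("k1", "k2")))
    maps <- densityMap(pd, radial, fractions = fr, pd_bin = 0.1,
                       radial_bin = 40)
    grid <- attr(maps, "grid")
    ip <- round(pd / 0.1)
    ir <- round(radial / 40)
    for (cl in c("k1", "k2")) {
        agg <- tapply(fr[, cl], list(ip, ir), mean)
        agg[is.na(agg)] <- 0
        agg <- agg / max(agg)
        got <- maps[[cl]][rownames(agg), colnames(agg)]
        expect_equal(unname(got), unname(agg), tolerance = 1e-12)
    }
})

test_that("a point mass occupies a single density cell", {
    maps <- densityMap(pd = rep(-0.5, 7), radial = rep(40, 7),
                       labels = rep("k", 7), pd_bin = 0.1, radial_bin = 40)
    m <- maps$k
    expect_identical(sum(m == 1), 1L)
    expect_identical(sum(m), 1)
    expect_identical(m["-5", "1"], 1)
})

test_that("planted mesenchymal types are recovered on both axes", {
    for (seed in 1:3) {
        sim <- simulateAirwayTissue(seed = seed)
        grid <- binReads(sim$reads, "square", radius = 20)
        mask <- airwayBins(grid, "EPCAM", 3)
        pd_air <- pdEmbeddingISS(grid, mask,
            genes = c("SOX2", "SCGB3A2", "ETV5", "TPPP3"))
        pd_all <- propagatePD(pd_air, mask, grid)
        ax <- radialAxis(grid, mask)
        # locate every mesenchymal cell's bin
        mes <- sim$truth[sim$truth$compartment == "mesenchymal", ]
        idx <- lungSpatial:::.squareIndex(mes$x, mes$y, 20)
        key <- paste(idx[, 1], idx[, 2])
        bin <- match(key, rownames(binCounts(grid)))
        keep <- !is.na(bin)
        expect_gt(mean(keep), 0.95)
        rec_rad <- ax$radial[bin[keep]]
        rec_pd <- pd_all[bin[keep]]
        expect_gte(cor(rec_rad, mes$radial[keep]), 0.9)
        expect_gte(cor(rec_pd, mes$pd[keep]), 0.9)
    }
})
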