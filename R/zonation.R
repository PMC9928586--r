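## lattice helpers ----------------------------------------------------------

# nearest square-lattice centre (spacing 2 * radius); indices are
# round(x / spacing), which IS the nearest-centre assignment
.squareIndex <- function(x, y, radius) {
    cbind(i = round(x / (2 * radius)), j = round(y / (2 * radius)))
}

# pointy-top hexagon containing a point, axial coordinates, via cube
# rounding; size = circumradius
.hexIndex <- function(x, y, size) {
    q <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
    r <- (2 / 3 * y) / size
    xq <- q; xr <- r; xs <- -q - r
    rq <- round(xq); rr <- round(xr); rs <- round(xs)
    dq <- abs(rq - xq); dr <- abs(rr - xr); ds <- abs(rs - xs)
    fixq <- dq > dr & dq > ds
    fixr <- !fixq & dr > ds
    rq[fixq] <- -rr[fixq] - rs[fixq]
    rr[fixr] <- -rq[fixr] - rs[fixr]
    cbind(q = rq, r = rr)
}

.hexCenter <- function(q, r, size) {
    cbind(x = size * sqrt(3) * (q + r / 2), y = size * 3 / 2 * r)
}

#' Bin molecule reads on a square or hexagonal lattice
#'
#' Assigns every read to the lattice bin containing it (equivalently the
#' nearest bin centre): squares of side 2*radius, or pointy-top regular
#' hexagons of circumradius \code{radius}. The total read count is
#' conserved exactly; only bins that receive at least one read are
#' materialised.
#'
#' @param reads a \linkS4class{SpatialReads}.
#' @param geometry "square" or "hex".
#' @param radius bin radius in micrometres: half the square side, or the
#'   hexagon circumradius.
#' @return A \linkS4class{BinGrid} with one gene column per panel gene.
#' @export
binReads <- function(reads, geometry = c("square", "hex"), radius = 20) {
    geometry <- match.arg(geometry)
    if (radius <= 0) stop("radius must be positive")
    rd <- readTable(reads)
    if (!nrow(rd)) stop("empty read table")
    if (geometry == "square") {
        idx <- .squareIndex(rd$x, rd$y, radius)
        key <- paste(idx[, 1], idx[, 2])
        ctr <- function(ij) cbind(x = ij[, 1] * 2 * radius,
                                  y = ij[, 2] * 2 * radius)
    } else {
        idx <- .hexIndex(rd$x, rd$y, radius)
        key <- paste(idx[, 1], idx[, 2])
        ctr <- function(ij) .hexCenter(ij[, 1], ij[, 2], radius)
    }
    ukey <- sort(unique(key))
    genes <- readPanel(reads)
    counts <- matrix(0L, length(ukey), length(genes),
                     dimnames = list(ukey, genes))
    tb <- table(factor(key, ukey), factor(rd$gene, genes))
    counts[] <- as.integer(tb)
    ij <- do.call(rbind, lapply(strsplit(ukey, " "), as.numeric))
    methods::new("BinGrid", geometry = geometry, radius = radius,
                 centers = ctr(ij), counts = counts,
                 axial = if (geometry == "hex") {
                     storage.mode(ij) <- "integer"
                     colnames(ij) <- c("q", "r"); ij
                 } else matrix(integer(0), 0, 2))
}

#' Airway-related bins by marker count
#'
#' Flags bins whose summed count over \code{genes} is strictly greater
#' than \code{min_count}. With the defaults this is the in-situ rule
#' (more than 3 EPCAM molecules); for spot data use the summed top
#' epithelial markers with \code{min_count = 8} (more than 8 UMIs).
#'
#' @param grid a \linkS4class{BinGrid}, or a genes x spots count matrix.
#' @param genes marker gene(s); all must be present.
#' @param min_count strict lower bound on the summed count (default 3).
#' @return logical mask, one entry per bin (or spot).
#' @export
airwayBins <- function(grid, genes = "EPCAM", min_count = 3) {
    cts <- if (methods::is(grid, "BinGrid")) binCounts(grid) else t(as.matrix(grid))
    missing <- setdiff(genes, colnames(cts))
    if (length(missing))
        stop("marker genes absent from panel: ",
             paste(missing, collapse = ", "))
    rowSums(cts[, genes, drop = FALSE]) > min_count
}

#' Airway-related spots of a SpotMatrix
#'
#' Convenience wrapper of [airwayBins()] for Visium-like data: a spot is
#' airway-related when the summed UMIs of the epithelial marker genes
#' exceed \code{min_count} (default: more than 8).
#'
#' @param x a \linkS4class{SpotMatrix}.
#' @param genes epithelial marker genes (e.g. the top differentially
#'   expressed epithelial markers).
#' @param min_count strict lower bound (default 8).
#' @return logical mask over spots.
#' @export
airwaySpots <- function(x, genes, min_count = 8) {
    airwayBins(SummarizedExperiment::assay(x, "counts"), genes, min_count)
}

#' Radial axis: distance to the nearest airway bin
#'
#' Euclidean centre-to-centre distance from every bin (or spot) to the
#' closest airway-flagged bin. Distances beyond \code{max_radial} are
#' flagged excluded (the published analyses drop positions more than
#' 140 um from an airway).
#'
#' @param centers n x 2 coordinate matrix, or a \linkS4class{BinGrid}.
#' @param mask logical airway mask over the same bins (non-empty).
#' @param max_radial exclusion distance in micrometres (default 140,
#'   strict ">").
#' @return data.frame with \code{radial}, \code{nearest} (index of the
#'   nearest airway bin) and \code{excluded}.
#' @export
radialAxis <- function(centers, mask, max_radial = 140) {
    if (methods::is(centers, "BinGrid")) centers <- binCenters(centers)
    if (!any(mask)) stop("airway mask is empty")
    nn <- .nearestAirway(centers, centers[mask, , drop = FALSE])
    data.frame(radial = nn$dist,
               nearest = which(mask)[nn$index],
               excluded = nn$dist > max_radial)
}

# for each query row the index and distance of the nearest reference row;
# ties resolved to the lowest reference index
.nearestAirway <- function(query, ref) {
    d2 <- outer(rowSums(query^2), rep(1, nrow(ref))) -
        2 * query %*% t(ref) + outer(rep(1, nrow(query)), rowSums(ref^2))
    d2[d2 < 0] <- 0
    idx <- apply(d2, 1, which.min)
    list(index = idx, dist = sqrt(d2[cbind(seq_len(nrow(query)), idx)]))
}

#' Proximal-distal score from marker expression (spot mode)
#'
#' Each airway spot receives a score in [-1, 1]: each marker gene's
#' expression is min-max scaled across airway spots; p and d are the
#' means of the scaled proximal and distal markers; the score is
#' (d - p) / (d + p), defined as 0 when both aggregates vanish. A spot
#' expressing only proximal markers scores exactly -1, only distal
#' markers exactly +1.
#'
#' @param counts genes x spots expression matrix (any monotone scale), or
#'   a \linkS4class{SpotMatrix}.
#' @param airway_mask logical airway mask over spots.
#' @param proximal_genes,distal_genes disjoint, non-empty marker sets
#'   present in the matrix. Defaults: SOX2/SCGB3A2 vs ETV5/TPPP3.
#' @param method "ratio" (default, (d-p)/(d+p)) or "difference" (d - p,
#'   clipped to [-1, 1]).
#' @return numeric vector over all spots: the score on airway spots, NA
#'   elsewhere (propagate with [propagatePD()]).
#' @export
pdScoreST <- function(counts, airway_mask,
                      proximal_genes = c("SOX2", "SCGB3A2"),
                      distal_genes = c("ETV5", "TPPP3"),
                      method = c("ratio", "difference")) {
    method <- match.arg(method)
    if (methods::is(counts, "SpotMatrix"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    if (!length(proximal_genes) || !length(distal_genes))
        stop("both marker sets must be non-empty")
    if (length(intersect(proximal_genes, distal_genes)))
        stop("marker sets must be disjoint")
    missing <- setdiff(c(proximal_genes, distal_genes), rownames(counts))
    if (length(missing))
        stop("marker genes absent: ", paste(missing, collapse = ", "))
    aw <- counts[, airway_mask, drop = FALSE]
    scale01 <- function(v) {
        rng <- range(v)
        if (rng[2] == rng[1]) rep(0, length(v)) else (v - rng[1]) / diff(rng)
    }
    sc <- t(apply(aw[c(proximal_genes, distal_genes), , drop = FALSE], 1,
                  scale01))
    p <- colMeans(sc[proximal_genes, , drop = FALSE])
    d <- colMeans(sc[distal_genes, , drop = FALSE])
    pd <- if (method == "ratio") {
        ifelse(p + d == 0, 0, (d - p) / (d + p))
    } else {
        pmin(1, pmax(-1, d - p))
    }
    out <- rep(NA_real_, ncol(counts))
    names(out) <- colnames(counts)
    out[airway_mask] <- pd
    out
}

#' Proximal-distal score by 1-D embedding of airway bins (in-situ mode)
#'
#' Embeds airway-bin expression on its first principal component, which
#' recapitulates the proximal-distal patterning of a continuous airway.
#' Bin count vectors are library-size normalised to the median airway-bin
#' total and log1p-transformed, and the component is computed on
#' unit-variance columns so no single high-count gene dominates. The
#' component is oriented so that the proximal-marker aggregate correlates
#' negatively with the score, then used as a pseudotime: by default the
#' empirical rank of each bin is mapped onto [-1, 1] (robust to the
#' compression a plain min-max rescaling suffers at the axis ends), with
#' plain min-max rescaling available.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param mask logical airway mask (>= 10 airway bins required).
#' @param proximal_genes markers used only to orient the axis.
#' @param genes genes the embedding is computed on. Default NULL uses the
#'   whole panel; restricting to the epithelial markers that define the
#'   axis shields the embedding from non-epithelial reads spilling into
#'   airway bins.
#' @param rescale "rank" (default) or "minmax".
#' @return numeric vector over all bins: score on airway bins, NA
#'   elsewhere.
#' @export
pdEmbeddingISS <- function(grid, mask,
                           proximal_genes = c("SOX2", "SCGB3A2"),
                           genes = NULL,
                           rescale = c("rank", "minmax")) {
    rescale <- match.arg(rescale)
    cts <- binCounts(grid)[mask, , drop = FALSE]
    if (!is.null(genes)) {
        missing <- setdiff(genes, colnames(cts))
        if (length(missing))
            stop("genes absent from panel: ",
                 paste(missing, collapse = ", "))
        cts <- cts[, genes, drop = FALSE]
    }
    if (nrow(cts) < 10) stop("at least 10 airway bins are required")
    tot <- rowSums(cts)
    x <- log1p(cts / ifelse(tot == 0, 1, tot) * stats::median(tot))
    keep <- apply(x, 2, stats::sd) > 0
    if (!any(keep)) stop("airway-bin expression is constant")
    pc1 <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                         scale. = TRUE)$x[, 1]
    prox <- intersect(proximal_genes, colnames(cts))
    if (length(prox)) {
        or <- stats::cor(pc1, rowSums(cts[, prox, drop = FALSE]))
        if (isTRUE(or > 0)) pc1 <- -pc1
    }
    n <- length(pc1)
    pd <- if (rescale == "rank") {
        if (n == 1) 0 else 2 * (rank(pc1, ties.method = "average") - 1) /
            (n - 1) - 1
    } else {
        rng <- range(pc1)
        if (rng[2] == rng[1]) rep(0, n) else
            2 * (pc1 - rng[1]) / diff(rng) - 1
    }
    out <- rep(NA_real_, nrow(binCounts(grid)))
    out[mask] <- pd
    out
}

#' Propagate proximal-distal scores to non-airway positions
#'
#' Airway bins keep their own score; every other bin or spot inherits
#' the score of its nearest airway bin (Euclidean centre-to-centre
#' distance, ties to the lowest bin index).
#'
#' @param pd numeric vector with scores on airway positions (as returned
#'   by [pdScoreST()] / [pdEmbeddingISS()]).
#' @param mask logical airway mask (non-empty).
#' @param centers n x 2 coordinates of all positions, or a
#'   \linkS4class{BinGrid}.
#' @return numeric vector of scores for every position.
#' @export
propagatePD <- function(pd, mask, centers) {
    if (methods::is(centers, "BinGrid")) centers <- binCenters(centers)
    if (!any(mask)) stop("airway mask is empty")
    nn <- .nearestAirway(centers, centers[mask, , drop = FALSE])
    out <- pd[which(mask)[nn$index]]
    out[mask] <- pd[mask]
    out
}

#' Per-cluster density over the (proximal-distal, radial) plane
#'
#' Coordinates are discretised to a grid (\code{pd} rounded to the
#' \code{pd_bin} grid, \code{radial} to \code{radial_bin}); excluded
#' entries are dropped. In "iss" mode the entities carry cluster labels
#' and each cluster's cell counts are histogrammed, with optional
#' Gaussian smoothing; in "st" mode the entities carry per-cluster
#' fractions which are averaged within each occupied grid cell. Each
#' cluster's grid is normalised to maximum 1.
#'
#' @param pd,radial per-entity coordinates.
#' @param labels per-entity cluster labels ("iss" mode) — or —
#' @param fractions entities x clusters matrix ("st" mode).
#' @param pd_bin proximal-distal grid step (default 0.1).
#' @param radial_bin radial grid step in micrometres (default 40).
#' @param excluded optional logical of entities to drop.
#' @param smooth_sd Gaussian smoothing sd in grid cells, "iss" mode only
#'   (default 0: plain histogram).
#' @return list of per-cluster matrices (rows: pd grid, columns: radial
#'   grid), with an attribute \code{grid} holding the cell centres.
#' @export
densityMap <- function(pd, radial, labels = NULL, fractions = NULL,
                       pd_bin = 0.1, radial_bin = 40, excluded = NULL,
                       smooth_sd = 0) {
    if (is.null(labels) == is.null(fractions))
        stop("supply exactly one of labels or fractions")
    keep <- if (is.null(excluded)) rep(TRUE, length(pd)) else !excluded
    pd <- pd[keep]; radial <- radial[keep]
    if (!length(pd)) stop("no entities left after exclusion")
    # integer grid indices avoid floating-point level mismatches
    ip <- as.integer(round(pd / pd_bin))
    ir <- as.integer(round(radial / radial_bin))
    iplv <- seq(as.integer(round(-1 / pd_bin)), as.integer(round(1 / pd_bin)))
    irlv <- sort(unique(ir))
    fp <- factor(ip, iplv)
    fr <- factor(ir, irlv)
    if (!is.null(labels)) {
        labels <- as.character(labels)[keep]
        maps <- lapply(sort(unique(labels)), function(cl) {
            m <- table(fp[labels == cl], fr[labels == cl])
            m <- matrix(as.numeric(m), nrow(m), ncol(m),
                        dimnames = dimnames(m))
            if (smooth_sd > 0) m <- .gaussSmooth(m, smooth_sd)
            if (max(m) > 0) m <- m / max(m)
            m
        })
        names(maps) <- sort(unique(labels))
    } else {
        fractions <- fractions[keep, , drop = FALSE]
        maps <- lapply(colnames(fractions), function(cl) {
            mu <- tapply(fractions[, cl], list(fp, fr), mean)
            mu[is.na(mu)] <- 0
            if (max(mu) > 0) mu <- mu / max(mu)
            mu
        })
        names(maps) <- colnames(fractions)
    }
    attr(maps, "grid") <- list(pd = iplv * pd_bin, radial = irlv * radial_bin)
    maps
}

# separable Gaussian blur on a matrix, sd in cells
.gaussSmooth <- function(m, sd) {
    half <- max(1L, ceiling(3 * sd))
    k <- stats::dnorm(-half:half, sd = sd)
    k <- k / sum(k)
    blur1 <- function(v) {
        n <- length(v)
        vp <- c(rep(0, half), v, rep(0, half))
        vapply(seq_len(n), function(i) sum(vp[i:(i + 2 * half)] * k),
               numeric(1))
    }
    dn <- dimnames(m)
    m <- apply(m, 2, blur1)
    m <- t(apply(t(m), 2, blur1))
    dimnames(m) <- dn
    m
}
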