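#' Hexagonal binning of decoded molecule reads
#'
#' Segments the section into pointy-top regular hexagons of circumradius
#' \code{circumradius} (default 7 um, approximating an epithelial cell)
#' and counts the reads of each panel gene per hexagon. Thin wrapper of
#' [binReads()] with hexagonal geometry.
#'
#' @param reads a \linkS4class{SpatialReads}.
#' @param circumradius hexagon circumradius in micrometres (default 7).
#'   To interpret the radius as the hexagon width (flat-to-flat
#'   distance w), pass \code{circumradius = w / sqrt(3)}.
#' @return A \linkS4class{BinGrid} with axial (q, r) coordinates.
#' @export
hexBin <- function(reads, circumradius = 7) {
    binReads(reads, geometry = "hex", radius = circumradius)
}

#' Proximal-epithelial bin filter
#'
#' Retains bins with a clear proximal epithelial component: strictly
#' more than \code{sox2_min} SOX2 molecules AND strictly more than
#' \code{epcam_min} EPCAM molecules.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param sox2_min,epcam_min strict lower bounds (default 3).
#' @param sox2,epcam gene column names (must be present in the panel).
#' @return logical mask over bins.
#' @export
epithelialFilter <- function(grid, sox2_min = 3, epcam_min = 3,
                             sox2 = "SOX2", epcam = "EPCAM") {
    cts <- binCounts(grid)
    missing <- setdiff(c(sox2, epcam), colnames(cts))
    if (length(missing))
        stop("genes absent from panel: ", paste(missing, collapse = ", "))
    cts[, sox2] > sox2_min & cts[, epcam] > epcam_min
}

#' Neuroendocrine bin filter
#'
#' Retains bins with at least \code{sum_min} summed molecules of the
#' neuroendocrine gene set (inclusive bound) OR strictly more than
#' \code{ascl1_min} ASCL1 molecules (which flags NE progenitors).
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param ne_genes neuroendocrine gene set; genes absent from the panel
#'   contribute zero.
#' @param sum_min inclusive lower bound on the summed NE count
#'   (default 12).
#' @param ascl1_min strict lower bound on ASCL1 (default 10).
#' @param ascl1 ASCL1 column name.
#' @return logical mask over bins.
#' @export
neFilter <- function(grid,
                     ne_genes = c("ARX", "NKX2-2", "GHRL", "ACSL1",
                                  "CALCA", "GRP", "RFX6", "CFC1",
                                  "PCSK1", "ASCL1"),
                     sum_min = 12, ascl1_min = 10, ascl1 = "ASCL1") {
    cts <- binCounts(grid)
    present <- intersect(ne_genes, colnames(cts))
    if (!length(present)) stop("no NE genes present in panel")
    ne_sum <- rowSums(cts[, present, drop = FALSE])
    ascl1_n <- if (ascl1 %in% colnames(cts)) cts[, ascl1] else 0
    ne_sum >= sum_min | ascl1_n > ascl1_min
}

#' Leiden clustering of retained bins
#'
#' Library-size normalises the retained bin count vectors to the median
#' bin total, log1p-transforms them, builds a symmetrised k-nearest-
#' neighbour graph on Euclidean distances and partitions it with the
#' Leiden algorithm (modularity objective). Deterministic for a fixed
#' seed.
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param mask logical mask of retained bins (>= 2 must be TRUE).
#' @param resolution Leiden resolution (default 0.1).
#' @param k neighbours in the bin graph (default 15).
#' @param seed integer RNG seed.
#' @param normalize if FALSE, cluster raw counts (default TRUE).
#' @return data.frame with the retained bins' index, axial coordinates
#'   (hex grids), centre coordinates and \code{cluster} label.
#' @export
clusterBins <- function(grid, mask, resolution = 0.1, k = 15, seed = 1,
                        normalize = TRUE) {
    idx <- which(mask)
    if (length(idx) < 2) stop("at least 2 retained bins are required")
    x <- binCounts(grid)[idx, , drop = FALSE]
    if (normalize) {
        tot <- rowSums(x)
        x <- log1p(x / ifelse(tot == 0, 1, tot) * stats::median(tot))
    }
    k <- min(k, length(idx) - 1)
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
    edges <- unique(t(apply(cbind(rep(seq_along(idx), k), as.vector(nn)),
                            1, sort)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = 5)
    out <- data.frame(bin = idx,
                      x = binCenters(grid)[idx, 1],
                      y = binCenters(grid)[idx, 2],
                      cluster = as.integer(igraph::membership(cl)))
    if (nrow(grid@axial)) {
        out$q <- grid@axial[idx, 1]
        out$r <- grid@axial[idx, 2]
    }
    out
}

#' Gene-gene Pearson correlation across retained bins
#'
#' @param grid a \linkS4class{BinGrid}.
#' @param mask logical mask of retained bins.
#' @param genes genes to correlate (default: all panel genes).
#' @return symmetric correlation matrix; genes constant across the
#'   retained bins are reported as NA.
#' @export
geneCorrelation <- function(grid, mask, genes = NULL) {
    cts <- binCounts(grid)[mask, , drop = FALSE]
    if (is.null(genes)) genes <- colnames(cts)
    missing <- setdiff(genes, colnames(cts))
    if (length(missing))
        stop("genes absent from panel: ", paste(missing, collapse = ", "))
    x <- cts[, genes, drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    r <- suppressWarnings(stats::cor(x))
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
    diag(r)[sds > 0] <- 1
    r
}
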