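#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' SpotMatrix: spot-level counts with spatial coordinates
#'
#' A \linkS4class{SummarizedExperiment} holding a non-negative integer
#' count matrix (genes in rows, spots in columns) together with per-spot
#' x/y coordinates in micrometres, stored in \code{colData} columns
#' \code{x} and \code{y}. Coordinates follow the image convention: origin
#' at the top-left, y increasing downward.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; the \code{"counts"}
#'   assay and \code{colData} columns \code{x}, \code{y} are mandatory.
#'
#' @seealso [SpotMatrix()] for construction, [qcFilterSpots()] for QC.
#' @export
setClass("SpotMatrix", contains = "SummarizedExperiment")

setValidity("SpotMatrix", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(cts)
        if (any(v < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(v != floor(v))) msg <- c(msg, "counts must be integers")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("x", "y") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'x' and 'y' coordinates")
    else if (!all(is.finite(cd$x)) || !all(is.finite(cd$y)))
        msg <- c(msg, "spot coordinates must be finite")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate spot ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpotMatrix
#'
#' @param counts non-negative integer matrix, genes x spots (dense or
#'   \pkg{Matrix} sparse). Must have row and column names.
#' @param coords data.frame with columns \code{x}, \code{y} (micrometres)
#'   and rownames (or a \code{spot} column) matching \code{colnames(counts)}.
#' @return A \linkS4class{SpotMatrix}.
#' @examples
#' cts <- matrix(rpois(6, 5), 2, 3,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' sm <- SpotMatrix(cts, data.frame(x = 1:3 * 10, y = c(0, 0, 10),
#'                                  row.names = colnames(cts)))
#' sm
#' @export
SpotMatrix <- function(counts, coords) {
    if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
        (ncol(counts) > 0 && is.null(colnames(counts))))
        stop("counts must have gene rownames and spot colnames")
    if (is.null(rownames(counts))) rownames(counts) <- character(0)
    if (is.null(colnames(counts))) colnames(counts) <- character(0)
    coords <- as.data.frame(coords)
    if ("spot" %in% colnames(coords) && !all(colnames(counts) %in% rownames(coords)))
        rownames(coords) <- coords$spot
    missing <- setdiff(colnames(counts), rownames(coords))
    if (length(missing))
        stop("missing coordinates for spots: ", paste(head(missing, 5), collapse = ", "))
    unknown <- setdiff(rownames(coords), colnames(counts))
    if (length(unknown))
        stop("coordinates refer to unknown spot ids: ",
             paste(head(unknown, 5), collapse = ", "))
    coords <- coords[colnames(counts), c("x", "y"), drop = FALSE]
    methods::new("SpotMatrix", SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(x = coords$x, y = coords$y,
                                       row.names = colnames(counts))))
}

#' SpatialReads: decoded molecule coordinates
#'
#' Molecule-level output of in-situ methods (HybISS, SCRINSHOT): one record
#' per decoded rolling-circle product, with x/y position in micrometres and
#' the gene identity, restricted to a declared gene panel.
#'
#' @slot reads data.frame with columns \code{x}, \code{y}, \code{gene} and
#'   optionally \code{section}.
#' @slot panel character vector of admissible gene names.
#' @export
setClass("SpatialReads",
         representation(reads = "data.frame", panel = "character"))

setValidity("SpatialReads", function(object) {
    msg <- NULL
    rd <- object@reads
    if (!all(c("x", "y", "gene") %in% colnames(rd)))
        msg <- c(msg, "reads must have columns x, y, gene")
    else {
        if (!all(is.finite(rd$x)) || !all(is.finite(rd$y)))
            msg <- c(msg, "read coordinates must be finite")
        if (!all(rd$gene %in% object@panel))
            msg <- c(msg, "reads contain genes outside the declared panel")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpatialReads table
#'
#' @param reads data.frame with columns \code{x}, \code{y} (micrometres)
#'   and \code{gene}.
#' @param panel gene panel; defaults to the genes present. Records whose
#'   gene is outside the panel are dropped with a message.
#' @return A \linkS4class{SpatialReads}.
#' @export
SpatialReads <- function(reads, panel = NULL) {
    reads <- as.data.frame(reads)
    if (!all(c("x", "y", "gene") %in% colnames(reads)))
        stop("reads must have columns x, y, gene")
    reads$gene <- as.character(reads$gene)
    if (is.null(panel)) panel <- sort(unique(reads$gene))
    out <- !(reads$gene %in% panel)
    if (any(out)) {
        message(sum(out), " reads with genes outside the panel dropped")
        reads <- reads[!out, , drop = FALSE]
        rownames(reads) <- NULL
    }
    methods::new("SpatialReads", reads = reads, panel = panel)
}

#' ExpressionProfiles: reference mean expression per cell type
#'
#' Mean expression of each gene in each cell type, plus a shared
#' negative-binomial size (dispersion) parameter. Drives both the
#' synthetic-data simulators and the probabilistic cell typer.
#'
#' @slot means non-negative matrix, genes x cell types, dimnames required.
#' @slot dispersion positive scalar: NB size parameter shared across genes.
#' @export
setClass("ExpressionProfiles",
         representation(means = "matrix", dispersion = "numeric"))

setValidity("ExpressionProfiles", function(object) {
    msg <- NULL
    m <- object@means
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "means must have gene rownames and type colnames")
    if (!all(is.finite(m)) || any(m < 0))
        msg <- c(msg, "means must be finite and non-negative")
    if (length(object@dispersion) != 1L || object@dispersion <= 0)
        msg <- c(msg, "dispersion must be a positive scalar")
    if (is.null(msg)) TRUE else msg
})

#' Construct ExpressionProfiles
#'
#' @param means genes x types matrix of mean counts.
#' @param dispersion NB size parameter (default 2).
#' @return An \linkS4class{ExpressionProfiles}.
#' @export
ExpressionProfiles <- function(means, dispersion = 2) {
    methods::new("ExpressionProfiles", means = as.matrix(means),
                 dispersion = as.numeric(dispersion))
}

#' SpotFractions: per-spot cell-type proportions
#'
#' Output of spot deconvolution (e.g. stereoscope): spots in rows, cell
#' types in columns, entries in [0, 1] with row sums at most 1.
#'
#' @slot fractions matrix spots x types.
#' @slot section factor of per-spot section ids (may be length 0).
#' @export
setClass("SpotFractions",
         representation(fractions = "matrix", section = "factor"))

setValidity("SpotFractions", function(object) {
    msg <- NULL
    f <- object@fractions
    if (any(f < 0) || any(f > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (any(rowSums(f) > 1 + 1e-6))
        msg <- c(msg, "row sums must not exceed 1")
    if (length(object@section) && length(object@section) != nrow(f))
        msg <- c(msg, "section must have one entry per spot")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SpotFractions matrix
#'
#' @param fractions spots x types matrix in [0, 1].
#' @param section optional per-spot section ids.
#' @return A \linkS4class{SpotFractions}.
#' @export
SpotFractions <- function(fractions, section = character(0)) {
    methods::new("SpotFractions", fractions = as.matrix(fractions),
                 section = as.factor(section))
}

#' BinGrid: spatially binned molecule counts
#'
#' Counts of reads falling into bins on a square or pointy-top hexagonal
#' lattice. Square bins are squares of side 2*radius centred on the lattice
#' points; hexagonal bins are regular hexagons of circumradius \code{radius}.
#' Binning conserves the total read count exactly.
#'
#' @slot geometry "square" or "hex".
#' @slot radius bin radius in micrometres (half side for squares,
#'   circumradius for hexagons).
#' @slot centers n-bins x 2 matrix of bin centre coordinates (x, y).
#' @slot counts n-bins x n-genes matrix of read counts.
#' @slot axial n-bins x 2 integer matrix of axial hex coordinates (q, r);
#'   0-row matrix for square grids.
#' @export
setClass("BinGrid",
         representation(geometry = "character", radius = "numeric",
                        centers = "matrix", counts = "matrix",
                        axial = "matrix"))

setValidity("BinGrid", function(object) {
    msg <- NULL
    if (!object@geometry %in% c("square", "hex"))
        msg <- c(msg, "geometry must be 'square' or 'hex'")
    if (length(object@radius) != 1L || object@radius <= 0)
        msg <- c(msg, "radius must be a positive scalar")
    if (nrow(object@centers) != nrow(object@counts))
        msg <- c(msg, "centers and counts must agree on the number of bins")
    if (any(object@counts < 0))
        msg <- c(msg, "bin counts must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn BinGrid-accessors bin centre coordinates
#' @export
binCenters <- function(x) x@centers

#' Accessors for BinGrid
#'
#' @param x a \linkS4class{BinGrid}.
#' @name BinGrid-accessors
#' @return \code{binCounts}: bins x genes count matrix;
#'   \code{binCenters}: bins x 2 coordinate matrix.
#' @export
binCounts <- function(x) x@counts

#' ClusterGraph: cluster-level abstraction of a cell graph
#'
#' Summary of a shared-nearest-neighbour cell graph at cluster resolution:
#' shared-edge counts E, row-normalised transition probabilities P (after
#' pruning) and inverse-probability edge weights W used for shortest-path
#' trajectory search.
#'
#' @slot E k x k shared-edge count matrix.
#' @slot P k x k pruned transition probabilities.
#' @slot W k x k weights, Inf where no edge survives.
#' @slot pMin pruning threshold applied to P.
#' @seealso [clusterGraph()], [optimalPaths()].
#' @export
setClass("ClusterGraph",
         representation(E = "matrix", P = "matrix", W = "matrix",
                        pMin = "numeric"))

setMethod("show", "ClusterGraph", function(object) {
    k <- nrow(object@E)
    ne <- sum(is.finite(object@W) & object@W > 0)
    cat("ClusterGraph with", k, "clusters,", ne,
        "directed weighted edges (p >=", format(object@pMin), ")\n")
    iso <- rownames(object@E)[rowSums(object@E) == 0]
    if (length(iso))
        cat("isolated clusters:", paste(iso, collapse = ", "), "\n")
})

setMethod("show", "SpatialReads", function(object) {
    cat("SpatialReads:", nrow(object@reads), "decoded molecules,",
        length(object@panel), "panel genes\n")
})

setMethod("show", "ExpressionProfiles", function(object) {
    cat("ExpressionProfiles:", nrow(object@means), "genes x",
        ncol(object@means), "cell types, NB dispersion",
        format(object@dispersion), "\n")
})

setMethod("show", "SpotFractions", function(object) {
    cat("SpotFractions:", nrow(object@fractions), "spots x",
        ncol(object@fractions), "cell types")
    if (length(object@section))
        cat(",", nlevels(object@section), "sections")
    cat("\n")
})

setMethod("show", "BinGrid", function(object) {
    cat("BinGrid (", object@geometry, ", radius ", format(object@radius),
        " um): ", nrow(object@counts), " bins x ", ncol(object@counts),
        " genes, ", sum(object@counts), " reads\n", sep = "")
})

#' @describeIn SpatialReads-accessors the molecule table
#' @export
readTable <- function(x) x@reads

#' Accessors for SpatialReads and ExpressionProfiles
#'
#' @param x a \linkS4class{SpatialReads} or \linkS4class{ExpressionProfiles}.
#' @name SpatialReads-accessors
#' @return \code{readTable}: data.frame of molecules; \code{readPanel}:
#'   the declared gene panel; \code{profileMeans}: genes x types mean
#'   matrix; \code{profileDispersion}: NB size parameter;
#'   \code{spotCoords}: spots x 2 coordinate matrix;
#'   \code{fractionMatrix}: spots x types proportion matrix.
#' @export
readPanel <- function(x) x@panel

#' @rdname SpatialReads-accessors
#' @export
profileMeans <- function(x) x@means

#' @rdname SpatialReads-accessors
#' @export
profileDispersion <- function(x) x@dispersion

#' @rdname SpatialReads-accessors
#' @export
spotCoords <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- cbind(x = cd$x, y = cd$y)
    rownames(m) <- colnames(x)
    m
}

#' @rdname SpatialReads-accessors
#' @export
fractionMatrix <- function(x) x@fractions

#' Accessors for ClusterGraph
#'
#' @param x a \linkS4class{ClusterGraph}.
#' @name ClusterGraph-accessors
#' @return \code{sharedEdgeCounts}: the k x k shared-edge matrix E;
#'   \code{transitionProbs}: the pruned transition matrix P;
#'   \code{pathWeights}: the inverse-probability weight matrix W.
#' @export
sharedEdgeCounts <- function(x) x@E

#' @rdname ClusterGraph-accessors
#' @export
transitionProbs <- function(x) x@P

#' @rdname ClusterGraph-accessors
#' @export
pathWeights <- function(x) x@W
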