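#' Read a spot-level count matrix with coordinates
#'
#' Reads either a Matrix Market triple (\code{<prefix>.mtx} with
#' \code{<prefix>_barcodes.tsv} spot ids and \code{<prefix>_features.tsv}
#' gene ids, genes in rows) or a dense CSV (genes in rows, spots in
#' columns, first column gene ids), together with a coordinate CSV mapping
#' spot ids to x/y positions in micrometres.
#'
#' @param path path to the \code{.mtx} file or dense CSV.
#' @param coords_path CSV with columns \code{spot}, \code{x}, \code{y}.
#' @return A \linkS4class{SpotMatrix}.
#' @export
readSpotMatrix <- function(path, coords_path) {
    if (grepl("\\.mtx$", path)) {
        lines <- readLines(path)
        body <- lines[!startsWith(lines, "%")]
        hdr <- scan(text = body[1], quiet = TRUE)
        if (length(body) - 1L != hdr[3])
            stop("malformed MTX header: ", hdr[3], " entries declared, ",
                 length(body) - 1L, " found")
        counts <- as.matrix(Matrix::readMM(path))
        if (all(counts == floor(counts)))
            storage.mode(counts) <- "integer"
        prefix <- sub("\\.mtx$", "", path)
        genes <- readLines(paste0(prefix, "_features.tsv"))
        spots <- readLines(paste0(prefix, "_barcodes.tsv"))
        if (length(genes) != nrow(counts) || length(spots) != ncol(counts))
            stop("feature/barcode files do not match matrix dimensions")
        dimnames(counts) <- list(genes, spots)
    } else {
        df <- utils::read.csv(path, check.names = FALSE)
        counts <- as.matrix(df[, -1, drop = FALSE])
        rownames(counts) <- df[[1]]
    }
    coords <- utils::read.csv(coords_path)
    if (!all(c("spot", "x", "y") %in% colnames(coords)))
        stop("coordinate file must have columns spot, x, y")
    rownames(coords) <- coords$spot
    SpotMatrix(counts, coords)
}

#' Write a SpotMatrix to disk
#'
#' Writes \code{<prefix>.mtx}, \code{<prefix>_barcodes.tsv},
#' \code{<prefix>_features.tsv} and \code{<prefix>_coords.csv}, the layout
#' [readSpotMatrix()] reads back. Counts round-trip bit-exactly.
#'
#' @param x a \linkS4class{SpotMatrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeSpotMatrix <- function(x, prefix) {
    cts <- SummarizedExperiment::assay(x, "counts")
    Matrix::writeMM(methods::as(Matrix::Matrix(cts, sparse = TRUE), "generalMatrix"),
                    paste0(prefix, ".mtx"))
    writeLines(rownames(cts), paste0(prefix, "_features.tsv"))
    writeLines(colnames(cts), paste0(prefix, "_barcodes.tsv"))
    xy <- spotCoords(x)
    utils::write.csv(
        data.frame(spot = rownames(xy), x = xy[, "x"], y = xy[, "y"]),
        paste0(prefix, "_coords.csv"), row.names = FALSE)
    invisible(prefix)
}

#' Quality-control filter for spot matrices
#'
#' Excludes spots with fewer than \code{min_umi} total counts or fewer
#' than \code{min_genes} detected genes, then excludes genes detected in
#' fewer than \code{min_spots_per_gene} of the surviving spots. "Fewer
#' than" is strict: a spot with exactly \code{min_umi} UMIs is kept.
#' Optionally drops an exclusion list first (e.g. mitochondrial,
#' ribosomal and non-coding genes). The filter is idempotent.
#'
#' @param x a \linkS4class{SpotMatrix}.
#' @param min_umi minimum total UMI count per spot (default 300).
#' @param min_genes minimum detected genes per spot (default 100).
#' @param min_spots_per_gene minimum spots a gene must be detected in
#'   (default 5).
#' @param exclude_genes character vector of gene ids to drop before
#'   filtering.
#' @return The filtered \linkS4class{SpotMatrix}; a warning (not an
#'   error) is raised if nothing survives.
#' @export
qcFilterSpots <- function(x, min_umi = 300, min_genes = 100,
                          min_spots_per_gene = 5,
                          exclude_genes = character(0)) {
    cts <- SummarizedExperiment::assay(x, "counts")
    if (length(exclude_genes))
        cts <- cts[!(rownames(cts) %in% exclude_genes), , drop = FALSE]
    keep_spot <- colSums(cts) >= min_umi & colSums(cts > 0) >= min_genes
    cts <- cts[, keep_spot, drop = FALSE]
    keep_gene <- rowSums(cts > 0) >= min_spots_per_gene
    cts <- cts[keep_gene, , drop = FALSE]
    if (ncol(cts) == 0L || nrow(cts) == 0L)
        warning("no spots or genes survive QC")
    xy <- spotCoords(x)[colnames(cts), , drop = FALSE]
    SpotMatrix(cts, data.frame(x = xy[, "x"], y = xy[, "y"],
                               row.names = colnames(cts)))
}

#' Read a decoded molecule table
#'
#' Reads a CSV with columns \code{x}, \code{y}, \code{gene} (and
#' optionally \code{section}). Coordinates are multiplied by
#' \code{scale} (micrometres per input unit), so pixel-space decoder
#' output can be converted on ingestion. Records with genes outside the
#' declared panel are dropped with a message reporting the count.
#'
#' @param path CSV path.
#' @param panel gene panel; defaults to the genes present in the file.
#' @param scale micrometres per coordinate unit (default 1).
#' @return A \linkS4class{SpatialReads}.
#' @export
readReadTable <- function(path, panel = NULL, scale = 1) {
    df <- utils::read.csv(path)
    miss <- setdiff(c("x", "y", "gene"), colnames(df))
    if (length(miss))
        stop("read table is missing columns: ", paste(miss, collapse = ", "))
    df$x <- df$x * scale
    df$y <- df$y * scale
    SpatialReads(df, panel = panel)
}

#' Write a molecule table as CSV
#'
#' @param x a \linkS4class{SpatialReads}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeReadTable <- function(x, path) {
    utils::write.csv(readTable(x), path, row.names = FALSE)
    invisible(path)
}

#' Read a spot-by-type fraction matrix
#'
#' CSV with spot ids in the first column, one column per cell type and an
#' optional \code{section} column.
#'
#' @param path CSV path.
#' @return A \linkS4class{SpotFractions}.
#' @export
readSpotFractions <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    section <- if ("section" %in% colnames(df)) df$section else character(0)
    df$section <- NULL
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    SpotFractions(m, section = section)
}

#' Pipeline configuration with published defaults
#'
#' Returns the full set of tunable thresholds, initialised to the values
#' used in the developing-lung atlas analyses, optionally overridden from
#' a YAML file and/or \code{...}. All thresholds must be non-negative.
#'
#' @param yaml_path optional YAML file of overrides.
#' @param ... named overrides applied after the YAML file.
#' @return Named list of configuration values.
#' @export
runConfig <- function(yaml_path = NULL, ...) {
    cfg <- list(
        min_umi = 300, min_genes = 100, min_spots_per_gene = 5,
        r_min = 0.04, p_min = 1e-4,
        bin_radius = 20, max_radial = 140, hex_radius = 7,
        airway_min_iss = 3, airway_min_st = 8,
        sox2_min = 3, epcam_min = 3, ne_sum_min = 12, ascl1_min = 10,
        leiden_resolution = 0.1, nb_dispersion = 2,
        min_pct_in = 0.25, min_logfc = 0.1, min_delta_pct = 0.10,
        alpha = 0.001, min_mean = 0.3,
        seed = 1L)
    if (!is.null(yaml_path)) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the yaml package is required to read configuration files")
        over <- yaml::read_yaml(yaml_path)
        cfg[names(over)] <- over
    }
    dots <- list(...)
    if (length(dots)) {
        bad <- setdiff(names(dots), names(cfg))
        if (length(bad)) stop("unknown configuration keys: ",
                              paste(bad, collapse = ", "))
        cfg[names(dots)] <- dots
    }
    num <- vapply(cfg, is.numeric, logical(1))
    if (any(unlist(cfg[num]) < 0))
        stop("configuration thresholds must be non-negative")
    cfg
}
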