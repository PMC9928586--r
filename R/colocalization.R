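#' Pairwise Pearson correlation of cell-type fractions across spots
#'
#' Correlates the per-spot frequencies of every cell-type pair across all
#' spots, pooled over sections by default. Cell types may be merged
#' (e.g. all neuronal states into one group, by summing their fractions)
#' or excluded (e.g. immune types) beforehand. Constant types have
#' undefined correlation and are reported as NA.
#'
#' @param x a \linkS4class{SpotFractions}.
#' @param pool_sections if TRUE (default) spots from all sections are
#'   pooled; standardisation per section is available instead.
#' @param standardize_per_section z-score fractions within each section
#'   before pooling (default FALSE: raw fractions).
#' @param exclude character vector of type names to drop.
#' @param merge named list: each element's types are summed into a new
#'   type named after the element.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
fractionCorrelations <- function(x, pool_sections = TRUE,
                                 standardize_per_section = FALSE,
                                 exclude = character(0), merge = list()) {
    f <- fractionMatrix(x)
    for (nm in names(merge)) {
        grp <- intersect(merge[[nm]], colnames(f))
        if (!length(grp)) next
        f <- cbind(f[, setdiff(colnames(f), grp), drop = FALSE],
                   rowSums(f[, grp, drop = FALSE]))
        colnames(f)[ncol(f)] <- nm
    }
    if (length(exclude))
        f <- f[, setdiff(colnames(f), exclude), drop = FALSE]
    if (nrow(f) < 3) stop("at least 3 spots are required")
    if (standardize_per_section && length(x@section)) {
        for (s in levels(x@section)) {
            idx <- x@section == s
            f[idx, ] <- scale(f[idx, , drop = FALSE])
        }
        f[!is.finite(f)] <- 0
    } else if (!pool_sections && length(x@section)) {
        # mean of per-section correlation matrices
        rs <- lapply(levels(x@section), function(s)
            suppressWarnings(stats::cor(f[x@section == s, , drop = FALSE])))
        r <- Reduce(`+`, rs) / length(rs)
        diag(r) <- 1
        return(r)
    }
    sds <- apply(f, 2, stats::sd)
    r <- suppressWarnings(stats::cor(f))
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
    diag(r) <- 1
    r
}

#' Cell-type co-localization neighbourhood graph
#'
#' Thresholds the fraction-correlation matrix: an undirected edge joins
#' two types whose Pearson r is strictly greater than \code{r_min}.
#' Neighbourhoods are the connected components of the thresholded graph;
#' types with no edge are reported as singletons. An optional Leiden
#' community step is available for graphs that threshold into one
#' component.
#'
#' @param corr symmetric correlation matrix (NA entries yield no edge).
#' @param r_min edge threshold in [-1, 1] (default 0.04, strict ">").
#' @param communities "components" (default) or "leiden".
#' @param resolution Leiden resolution if \code{communities = "leiden"}.
#' @return list with \code{edges} (data.frame from, to, r),
#'   \code{membership} (named neighbourhood id per connected type),
#'   \code{neighbourhoods} (list of type sets) and \code{singletons}.
#' @export
neighbourhoodGraph <- function(corr, r_min = 0.04,
                               communities = c("components", "leiden"),
                               resolution = 1) {
    communities <- match.arg(communities)
    if (r_min < -1 || r_min > 1) stop("r_min must lie in [-1, 1]")
    if (!isSymmetric(unname(as.matrix(corr))))
        stop("corr must be symmetric")
    types <- colnames(corr)
    adj <- !is.na(corr) & corr > r_min
    diag(adj) <- FALSE
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = types[idx[, 1]], to = types[idx[, 2]],
                        r = corr[idx])
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = types)
    membership <- if (communities == "components") {
        igraph::components(g)$membership
    } else {
        gw <- igraph::set_edge_attr(g, "weight", value = pmax(edges$r, 1e-12))
        igraph::membership(igraph::cluster_leiden(
            gw, objective_function = "modularity", resolution = resolution))
    }
    singletons <- types[igraph::degree(g) == 0]
    membership <- membership[setdiff(types, singletons)]
    hoods <- if (length(membership))
        unname(split(names(membership), membership)) else list()
    list(edges = edges, membership = membership,
         neighbourhoods = hoods, singletons = singletons)
}
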