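#' Simulate a cell x gene count dataset from expression profiles
#'
#' Cell types are drawn from \code{type_props}; counts for gene g in a
#' cell of type t are negative-binomial with mean \code{means[g, t]} and
#' shared size (dispersion) parameter. Pure function of its arguments and
#' the seed.
#'
#' @param n_cells number of cells (>= 1).
#' @param profiles an \linkS4class{ExpressionProfiles}.
#' @param type_props per-type sampling proportions (sum to 1); default
#'   uniform.
#' @param seed integer RNG seed.
#' @return list with \code{counts} (genes x cells integer matrix) and
#'   \code{labels} (per-cell type, character).
#' @examples
#' pr <- ExpressionProfiles(matrix(c(10, 0, 0, 10), 2, 2,
#'     dimnames = list(c("gA", "gB"), c("T1", "T2"))))
#' sim <- simulateCellDataset(50, pr, seed = 1)
#' table(sim$labels)
#' @export
simulateCellDataset <- function(n_cells, profiles, type_props = NULL,
                                seed = 1) {
    stopifnot(n_cells >= 1)
    methods::validObject(profiles)
    mu <- profileMeans(profiles)
    types <- colnames(mu)
    if (is.null(type_props)) type_props <- rep(1 / length(types), length(types))
    if (abs(sum(type_props) - 1) > 1e-8)
        stop("type_props must sum to 1")
    set.seed(seed)
    labels <- sample(types, n_cells, replace = TRUE, prob = type_props)
    counts <- matrix(0L, nrow(mu), n_cells,
                     dimnames = list(rownames(mu),
                                     paste0("cell", seq_len(n_cells))))
    for (t in types) {
        idx <- which(labels == t)
        if (!length(idx)) next
        counts[, idx] <- stats::rnbinom(nrow(mu) * length(idx),
                                        mu = mu[, t],
                                        size = profileDispersion(profiles))
    }
    list(counts = counts, labels = labels)
}

#' Simulate a shared-nearest-neighbour cell graph with planted
#' cluster connectivity
#'
#' Each cell pair (i, j), i < j, receives an edge independently with
#' probability \code{edge_prob[labels[i], labels[j]]}. The graph is
#' undirected and simple (no self-loops).
#'
#' @param labels per-cell cluster labels.
#' @param edge_prob symmetric k x k matrix of edge probabilities with
#'   dimnames matching the cluster labels.
#' @param seed integer RNG seed.
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
simulateSnnGraph <- function(labels, edge_prob, seed = 1) {
    edge_prob <- as.matrix(edge_prob)
    if (!isSymmetric(unname(edge_prob)))
        stop("edge_prob must be symmetric")
    if (any(edge_prob < 0 | edge_prob > 1))
        stop("edge probabilities must lie in [0, 1]")
    labels <- as.character(labels)
    n <- length(labels)
    set.seed(seed)
    p <- edge_prob[labels, labels]
    u <- matrix(0, n, n)
    u[upper.tri(u)] <- stats::runif(n * (n - 1) / 2)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(u[upper.tri(u)] < p[upper.tri(p)])
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("cell", seq_len(n)), paste0("cell", seq_len(n)))
    adj
}

#' Simulate a spot x cell-type fraction matrix with planted
#' co-occurrence blocks
#'
#' Each spot is assigned to one block of co-occurring cell types; the
#' types of that block share Dirichlet(1) mass while all other types
#' receive only truncated-normal noise. Rows are renormalised to sum
#' exactly to 1. This emulates deconvolution output in which anatomically
#' co-localised cell types rise and fall together across spots.
#'
#' @param n_spots number of spots.
#' @param blocks list of character vectors of type names; may overlap.
#' @param noise_sd standard deviation of the half-normal background
#'   noise added to out-of-block types (>= 0).
#' @param seed integer RNG seed.
#' @return list with \code{fractions} (a \linkS4class{SpotFractions}) and
#'   \code{block} (per-spot planted block index).
#' @export
simulateSpotFractions <- function(n_spots, blocks, noise_sd = 0, seed = 1) {
    if (!length(blocks) || any(!lengths(blocks)))
        stop("blocks must be a non-empty list of non-empty type sets")
    stopifnot(noise_sd >= 0)
    types <- unique(unlist(blocks))
    set.seed(seed)
    which_block <- sample(length(blocks), n_spots, replace = TRUE)
    f <- matrix(0, n_spots, length(types),
                dimnames = list(paste0("spot", seq_len(n_spots)), types))
    for (b in seq_along(blocks)) {
        idx <- which(which_block == b)
        if (!length(idx)) next
        k <- length(blocks[[b]])
        # Dirichlet(1) via normalised Exp(1) draws
        g <- matrix(stats::rexp(length(idx) * k), length(idx), k)
        f[idx, blocks[[b]]] <- g / rowSums(g)
    }
    if (noise_sd > 0)
        f <- f + abs(matrix(stats::rnorm(length(f), sd = noise_sd),
                            nrow(f), ncol(f)))
    f <- f / rowSums(f)
    list(fractions = SpotFractions(f), block = which_block)
}

#' Default mesenchymal placement for the synthetic airway tissue
#'
#' Four mesenchymal cell types at planted (radial, proximal-distal)
#' positions spanning airway-adjacent to peripheral and proximal to
#' distal locations, mimicking airway smooth muscle versus adventitial
#' fibroblast arrangements around an embryonic airway.
#'
#' @return data.frame with columns \code{type}, \code{radial} (um),
#'   \code{pd}, \code{radial_sd}, \code{pd_sd}.
#' @export
defaultPlacement <- function() {
    data.frame(
        type      = c("MesA", "MesB", "MesC", "MesD"),
        radial    = c(20, 60, 40, 100),
        pd        = c(-0.8, -0.4, 0.3, 0.7),
        radial_sd = 8,
        pd_sd     = 0.05)
}

#' Simulate an airway tissue section with a planted proximal-distal
#' gradient
#'
#' Builds a straight airway trunk of length \code{trunk_length} along the
#' x axis. Epithelial cells are placed uniformly along it and express
#' EPCAM at a constant rate, proximal markers at a rate decreasing
#' linearly with arc-length and distal markers at a rate increasing
#' linearly. Mesenchymal cells of each placement type are positioned at
#' their planted (radial, proximal-distal) coordinates (radial = distance
#' from the trunk, pd = arc-length rescaled to [-1, 1]) with Gaussian
#' jitter, and express one dedicated marker gene each. Reads per cell and
#' gene are Poisson; each read lands at the cell position plus a small
#' positional jitter.
#'
#' @param trunk_length airway length in micrometres.
#' @param n_epith_cells epithelial cells along the trunk.
#' @param n_mesench_cells total mesenchymal cells (split evenly over
#'   placement types).
#' @param proximal_genes,distal_genes disjoint marker sets.
#' @param placement data.frame as [defaultPlacement()].
#' @param reads_per_cell expected total reads per cell (> 0).
#' @param seed integer RNG seed.
#' @return list with \code{reads} (a \linkS4class{SpatialReads}) and
#'   \code{truth}: data.frame of per-cell \code{cell}, \code{type},
#'   \code{compartment}, \code{x}, \code{y}, \code{radial}, \code{pd}.
#' @export
simulateAirwayTissue <- function(trunk_length = 2000, n_epith_cells = 200,
                                 n_mesench_cells = 200,
                                 proximal_genes = c("SOX2", "SCGB3A2"),
                                 distal_genes = c("ETV5", "TPPP3"),
                                 placement = defaultPlacement(),
                                 reads_per_cell = 40, seed = 1) {
    if (reads_per_cell <= 0) stop("reads_per_cell must be positive")
    if (length(intersect(proximal_genes, distal_genes)))
        stop("proximal and distal marker sets must be disjoint")
    set.seed(seed)
    # epithelium along the trunk
    s <- stats::runif(n_epith_cells, 0, trunk_length)
    u <- s / trunk_length                      # arc-length fraction in [0,1]
    ex <- s
    ey <- stats::rnorm(n_epith_cells, 0, 3)
    epith <- data.frame(
        cell = paste0("epi", seq_len(n_epith_cells)),
        type = "Epithelial", compartment = "epithelial",
        x = ex, y = ey, radial = 0, pd = 2 * u - 1)
    # mesenchyme at planted coordinates (positive-y side)
    per_type <- diff(round(seq(0, n_mesench_cells, length.out = nrow(placement) + 1)))
    mes <- do.call(rbind, lapply(seq_len(nrow(placement)), function(i) {
        n <- per_type[i]
        if (n == 0) return(NULL)
        rad <- abs(placement$radial[i] +
                   stats::rnorm(n, 0, placement$radial_sd[i]))
        pd <- pmin(1, pmax(-1, placement$pd[i] +
                           stats::rnorm(n, 0, placement$pd_sd[i])))
        data.frame(cell = paste0(placement$type[i], "_", seq_len(n)),
                   type = placement$type[i], compartment = "mesenchymal",
                   x = (pd + 1) / 2 * trunk_length, y = rad,
                   radial = rad, pd = pd)
    }))
    truth <- rbind(epith, mes)
    rownames(truth) <- NULL
    # expression rates per cell x gene
    mes_markers <- paste0(placement$type, "_marker")
    panel <- c("EPCAM", proximal_genes, distal_genes, mes_markers)
    rate <- matrix(0, nrow(truth), length(panel),
                   dimnames = list(truth$cell, panel))
    iep <- truth$compartment == "epithelial"
    uu <- (truth$pd[iep] + 1) / 2
    rate[iep, "EPCAM"] <- 0.3 * reads_per_cell
    for (g in proximal_genes)
        rate[iep, g] <- 0.35 * reads_per_cell * (1 - uu) / length(proximal_genes)
    for (g in distal_genes)
        rate[iep, g] <- 0.35 * reads_per_cell * uu / length(distal_genes)
    for (i in seq_len(nrow(placement))) {
        im <- truth$type == placement$type[i]
        rate[im, mes_markers[i]] <- 0.9 * reads_per_cell
    }
    counts <- matrix(stats::rpois(length(rate), rate), nrow(rate),
                     dimnames = dimnames(rate))
    tot <- sum(counts)
    reads <- data.frame(
        x = rep(truth$x, times = rowSums(counts)),
        y = rep(truth$y, times = rowSums(counts)),
        gene = rep(rep(panel, times = nrow(counts)), times = as.vector(t(counts))),
        cell = rep(truth$cell, times = rowSums(counts)))
    # small optical scatter of individual reads around the cell
    reads$x <- reads$x + stats::rnorm(tot, 0, 2)
    reads$y <- reads$y + stats::rnorm(tot, 0, 2)
    list(reads = SpatialReads(reads, panel = panel), truth = truth)
}

#' Expression profiles with planted cluster markers
#'
#' Builds an \linkS4class{ExpressionProfiles} in which each cell type owns
#' \code{markers_per_type} dedicated marker genes expressed at
#' \code{fold} times the base mean (base mean elsewhere), plus
#' \code{n_noise} genes expressed at the base mean in every type.
#'
#' @param n_types number of cell types.
#' @param markers_per_type planted markers per type.
#' @param n_noise uninformative genes shared by all types.
#' @param fold marker fold-change over base (default 8).
#' @param base_mean base mean count per cell (default 0.25, the sparse
#'   per-gene read depth typical of decoded in-situ data).
#' @param dispersion NB size parameter (default 2).
#' @return list with \code{profiles} and \code{marker_map} (named
#'   character vector gene -> owning type).
#' @export
plantedProfiles <- function(n_types = 3, markers_per_type = 5, n_noise = 20,
                            fold = 8, base_mean = 0.25, dispersion = 2) {
    types <- paste0("T", seq_len(n_types))
    markers <- unlist(lapply(types, function(t)
        paste0(t, "_mk", seq_len(markers_per_type))))
    noise <- if (n_noise) paste0("noise", seq_len(n_noise)) else character(0)
    genes <- c(markers, noise)
    mu <- matrix(base_mean, length(genes), n_types,
                 dimnames = list(genes, types))
    marker_map <- stats::setNames(rep(types, each = markers_per_type), markers)
    for (g in markers) mu[g, marker_map[g]] <- fold * base_mean
    list(profiles = ExpressionProfiles(mu, dispersion = dispersion),
         marker_map = marker_map)
}
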