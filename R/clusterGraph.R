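#' One-hot encode cluster labels
#'
#' @param labels length-N cluster labels (character or factor).
#' @return N x k binary matrix with one 1 per row; columns in sorted
#'   cluster order.
#' @export
oneHot <- function(labels) {
    labels <- as.character(labels)
    lv <- sort(unique(labels))
    o <- matrix(0L, length(labels), length(lv),
                dimnames = list(names(labels), lv))
    o[cbind(seq_along(labels), match(labels, lv))] <- 1L
    o
}

check_snn <- function(adjacency) {
    adjacency <- as.matrix(adjacency)
    if (nrow(adjacency) != ncol(adjacency))
        stop("adjacency must be square")
    if (!all(adjacency %in% c(0, 1)))
        stop("adjacency must be binary")
    if (any(diag(adjacency) != 0))
        stop("adjacency must have a zero diagonal (no self-loops)")
    if (!isSymmetric(unname(adjacency)))
        stop("adjacency must be symmetric")
    adjacency
}

#' Cluster shared-edge counts from a cell graph
#'
#' Counts, for every ordered cluster pair, the adjacency entries between
#' their cells: E = (G O)^T O with G the binary symmetric cell graph and
#' O the one-hot cluster assignment. Each undirected edge contributes to
#' both ordered directions, so within-cluster edges are counted twice on
#' the diagonal and the total of E equals twice the number of undirected
#' edges.
#'
#' @param adjacency binary symmetric N x N matrix, zero diagonal.
#' @param labels length-N cluster labels.
#' @return symmetric k x k integer matrix of shared-edge counts.
#' @examples
#' adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 1] <- 1
#' adj[3, 4] <- adj[4, 3] <- 1
#' sharedEdges(adj, c("a", "a", "b", "b"))
#' @export
sharedEdges <- function(adjacency, labels) {
    adjacency <- check_snn(adjacency)
    if (length(labels) != nrow(adjacency))
        stop("labels and adjacency disagree on the number of cells")
    o <- oneHot(labels)
    e <- t(adjacency %*% o) %*% o
    storage.mode(e) <- "integer"
    dimnames(e) <- list(colnames(o), colnames(o))
    e
}

#' Row-normalise shared-edge counts into transition probabilities
#'
#' P[a, b] = E[a, b] / sum_c E[a, c]: the proportion of cluster a's graph
#' edges that are shared with cluster b (Hadamard division by E J).
#' Clusters with no edges at all yield all-zero rows and are reported
#' with a warning; they are flagged, not fatal.
#'
#' @param E non-negative k x k shared-edge matrix.
#' @return k x k matrix with every nonzero row summing to 1.
#' @export
transitionMatrix <- function(E) {
    E <- as.matrix(E)
    if (any(E < 0)) stop("E must be non-negative")
    rs <- rowSums(E)
    if (any(rs == 0))
        warning("isolated clusters with no edges: ",
                paste(rownames(E)[rs == 0], collapse = ", "))
    p <- E / ifelse(rs == 0, 1, rs)
    dimnames(p) <- dimnames(E)
    p
}

#' Prune spuriously weak transitions
#'
#' Sets transition probabilities strictly below \code{p_min} to zero.
#' No renormalisation is applied afterwards, so surviving probabilities
#' (and hence the 1/p edge weights) keep their original values; an
#' optional renormalisation is available. Idempotent.
#'
#' @param P transition-probability matrix.
#' @param p_min pruning threshold (default 1e-4); entries equal to
#'   \code{p_min} are kept.
#' @param renormalize if TRUE, rows are rescaled to sum to 1 after
#'   pruning (default FALSE).
#' @return pruned matrix.
#' @export
pruneTransitions <- function(P, p_min = 1e-4, renormalize = FALSE) {
    if (p_min < 0) stop("p_min must be non-negative")
    P[P < p_min] <- 0
    if (renormalize) {
        rs <- rowSums(P)
        P <- P / ifelse(rs == 0, 1, rs)
    }
    P
}

#' Inverse-probability edge weights
#'
#' w[a, b] = 1 / P[a, b] on surviving edges (P > 0); Inf (no edge)
#' elsewhere. The resulting weighted graph is directed, since P is
#' row-normalised and generally asymmetric.
#'
#' @param P pruned transition-probability matrix.
#' @return k x k weight matrix with Inf marking absent edges.
#' @export
edgeWeights <- function(P) {
    w <- ifelse(P > 0, 1 / P, Inf)
    dimnames(w) <- dimnames(P)
    w
}

#' Full cluster-graph abstraction
#'
#' Convenience wrapper running [sharedEdges()], [transitionMatrix()],
#' [pruneTransitions()] and [edgeWeights()] in sequence.
#'
#' @inheritParams sharedEdges
#' @inheritParams pruneTransitions
#' @return A \linkS4class{ClusterGraph}.
#' @export
clusterGraph <- function(adjacency, labels, p_min = 1e-4,
                         renormalize = FALSE) {
    e <- sharedEdges(adjacency, labels)
    p <- suppressWarnings(transitionMatrix(e))
    p <- pruneTransitions(p, p_min, renormalize)
    methods::new("ClusterGraph", E = e, P = p, W = edgeWeights(p),
                 pMin = p_min)
}

#' Shortest immature-to-mature paths on the cluster graph
#'
#' Runs Dijkstra's algorithm on the directed graph weighted by inverse
#' transition probabilities, from a root (immature) cluster to each
#' target (mature) cluster. Isolated clusters (all-zero transition rows)
#' are excluded from the graph with a warning. Unreachable targets are
#' reported with an NA path.
#'
#' @param x a \linkS4class{ClusterGraph} or a weight matrix as returned
#'   by [edgeWeights()].
#' @param root root cluster id.
#' @param targets character vector of target cluster ids.
#' @return named list, one entry per target, each with \code{path}
#'   (character vector, or NA if unreachable) and \code{weight} (total
#'   path weight, Inf if unreachable).
#' @export
optimalPaths <- function(x, root, targets) {
    w <- if (methods::is(x, "ClusterGraph")) x@W else as.matrix(x)
    if (is.null(rownames(w)))
        dimnames(w) <- list(as.character(seq_len(nrow(w))),
                            as.character(seq_len(nrow(w))))
    isolated <- rownames(w)[apply(is.infinite(w), 1, all) &
                            apply(is.infinite(w), 2, all)]
    if (length(isolated))
        warning("isolated clusters excluded from the path graph: ",
                paste(isolated, collapse = ", "))
    keep <- setdiff(rownames(w), isolated)
    if (!root %in% rownames(w)) stop("root cluster not in graph")
    bad <- setdiff(targets, rownames(w))
    if (length(bad)) stop("unknown target clusters: ",
                          paste(bad, collapse = ", "))
    w <- w[keep, keep, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(
        ifelse(is.finite(w), w, 0), mode = "directed", weighted = TRUE)
    res <- lapply(targets, function(tg) {
        if (tg == root) return(list(path = root, weight = 0))
        if (!tg %in% keep || !root %in% keep)
            return(list(path = NA_character_, weight = Inf))
        sp <- suppressWarnings(
            igraph::shortest_paths(g, from = root, to = tg,
                                   mode = "out", output = "vpath",
                                   algorithm = "dijkstra"))
        v <- sp$vpath[[1]]
        if (!length(v)) return(list(path = NA_character_, weight = Inf))
        path <- names(v)
        wt <- sum(w[cbind(path[-length(path)], path[-1])])
        list(path = path, weight = wt)
    })
    names(res) <- targets
    res
}
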