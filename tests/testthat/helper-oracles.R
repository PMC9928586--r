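# Independent brute-force oracles shared across tests. These deliberately
# use explicit loops and textbook formulas, not the package's vectorised
# code paths.

oracle_shared_edges <- function(adj, labels) {
    cl <- sort(unique(labels))
    e <- matrix(0L, length(cl), length(cl), dimnames = list(cl, cl))
    n <- nrow(adj)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] == 1)
            e[labels[j], labels[i]] <- e[labels[j], labels[i]] + 1L
    }
    e
}

oracle_qc <- function(counts, min_umi, min_genes, min_spots_per_gene) {
    keep_spot <- logical(ncol(counts))
    for (s in seq_len(ncol(counts))) {
        keep_spot[s] <- sum(counts[, s]) >= min_umi &&
            sum(counts[, s] > 0) >= min_genes
    }
    sub <- counts[, keep_spot, drop = FALSE]
    keep_gene <- logical(nrow(sub))
    for (g in seq_len(nrow(sub)))
        keep_gene[g] <- sum(sub[g, ] > 0) >= min_spots_per_gene
    sub[keep_gene, , drop = FALSE]
}

# all simple paths from root to target with finite total weight
oracle_best_path <- function(w, root, target) {
    n <- nrow(w)
    best <- list(weight = Inf, paths = list())
    dfs <- function(path, wt) {
        last <- path[length(path)]
        if (last == target) {
            if (wt < best$weight - 1e-12) {
                best$weight <<- wt
                best$paths <<- list(path)
            } else if (abs(wt - best$weight) <= 1e-12) {
                best$paths <<- c(best$paths, list(path))
            }
            return()
        }
        for (nxt in seq_len(n)) {
            if (nxt %in% path || !is.finite(w[last, nxt])) next
            dfs(c(path, nxt), wt + w[last, nxt])
        }
    }
    dfs(root, 0)
    best
}

oracle_pearson <- function(a, b) {
    am <- mean(a); bm <- mean(b)
    sum((a - am) * (b - bm)) /
        sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# even-odd ray casting point-in-polygon
point_in_polygon <- function(px, py, vx, vy) {
    n <- length(vx)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
        if ((vy[i] > py) != (vy[j] > py) &&
            px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
            inside <- !inside
        j <- i
    }
    inside
}

# vertices of a pointy-top hexagon (circumradius size) centred at (cx, cy)
hex_vertices <- function(cx, cy, size) {
    ang <- pi / 180 * (60 * 0:5 + 30)
    list(x = cx + size * cos(ang), y = cy + size * sin(ang))
}

adjusted_rand_index <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    exp_ <- si * sj / choose(n, 2)
    (sij - exp_) / ((si + sj) / 2 - exp_)
}

# small random SNN instance with labels
random_snn <- function(n, k, seed) {
    set.seed(seed)
    labels <- sample(paste0("c", seq_len(k)), n, replace = TRUE)
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.3)
    adj <- adj + t(adj)
    list(adj = adj, labels = labels)
}

# toy spot matrix with coordinates on a grid
toy_spot_matrix <- function(counts) {
    n <- ncol(counts)
    SpotMatrix(counts, data.frame(x = seq_len(n) * 10, y = rep(0, n),
                                  row.names = colnames(counts)))
}
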