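#' Library-size normalise and log-transform counts
#'
#' Counts are scaled to \code{target} per cell and transformed as
#' log2(x + 1), the scale on which the marker and expression filters
#' operate.
#'
#' @param counts genes x cells count matrix.
#' @param target per-cell total after normalisation (default 10000).
#' @return transformed matrix of the same shape.
#' @export
logNormalize <- function(counts, target = 1e4) {
    cs <- colSums(counts)
    log2(t(t(counts) / ifelse(cs == 0, 1, cs)) * target + 1)
}

#' Per-gene, per-cluster positive-fraction statistics (delta-pct)
#'
#' For every gene and cluster computes the fraction of cluster cells with
#' a nonzero count (\code{pct_in}), the same fraction over all other
#' cells (\code{pct_out}), their difference \code{delta_pct}, and the log
#' fold change of the cluster mean against the rest. "Positive" is a
#' nonzero raw count, so delta-pct depends only on the zero pattern and
#' is invariant to monotone transforms of the nonzero counts. The fold
#' change is computed on log2(counts-per-10k + 1) values as
#' log(mean_in + eps) - log(mean_out + eps), natural log by default.
#'
#' @param counts genes x cells non-negative count matrix with rownames.
#' @param labels per-cell cluster labels; at least 2 clusters.
#' @param lfc_base base of the fold-change logarithm: "natural" (default,
#'   the Seurat-era convention) or "log2".
#' @param eps pseudo-count inside the fold-change logs (default 1e-9).
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{pct_in}, \code{pct_out}, \code{delta_pct}, \code{log_fc}.
#' @export
deltaPct <- function(counts, labels, lfc_base = c("natural", "log2"),
                     eps = 1e-9) {
    lfc_base <- match.arg(lfc_base)
    labels <- as.character(labels)
    if (length(labels) != ncol(counts))
        stop("one label per cell (column) is required")
    cl <- sort(unique(labels))
    if (length(cl) < 2)
        stop("at least 2 clusters are required (pct_out is undefined otherwise)")
    pos <- counts > 0
    expr <- logNormalize(counts)
    lg <- if (lfc_base == "natural") log else log2
    res <- lapply(cl, function(k) {
        ink <- labels == k
        pin <- rowMeans(pos[, ink, drop = FALSE])
        pout <- rowMeans(pos[, !ink, drop = FALSE])
        min_ <- rowMeans(expr[, ink, drop = FALSE])
        mout <- rowMeans(expr[, !ink, drop = FALSE])
        data.frame(gene = rownames(counts), cluster = k,
                   pct_in = pin, pct_out = pout, delta_pct = pin - pout,
                   log_fc = lg(min_ + eps) - lg(mout + eps))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Marker-acceptance filter
#'
#' Retains (gene, cluster) rows expressed in at least \code{min_pct_in}
#' of the cluster's cells, with at least \code{min_logfc} log-fold
#' increase and expressed in at least \code{min_delta_pct} more cells in
#' the cluster than in the remaining dataset; all three bounds are
#' inclusive. If the table carries a \code{p_value} column, the
#' Bonferroni-adjusted p-value must additionally be below \code{alpha}.
#'
#' @param tbl a marker table from [deltaPct()], optionally with a
#'   \code{p_value} column from an external test.
#' @param min_pct_in minimum in-cluster positive fraction (default 0.25).
#' @param min_logfc minimum log fold change (default 0.1).
#' @param min_delta_pct minimum delta-pct (default 0.10).
#' @param alpha adjusted-p threshold (default 0.001, strict "<").
#' @return the surviving rows of \code{tbl}.
#' @export
markerFilter <- function(tbl, min_pct_in = 0.25, min_logfc = 0.1,
                         min_delta_pct = 0.10, alpha = 0.001) {
    keep <- tbl$pct_in >= min_pct_in &
        tbl$log_fc >= min_logfc &
        tbl$delta_pct >= min_delta_pct
    if ("p_value" %in% colnames(tbl))
        keep <- keep & stats::p.adjust(tbl$p_value, "bonferroni") < alpha
    out <- tbl[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Expressed-gene filter for interactome inputs
#'
#' Keeps a gene if any cluster passes all supplied thresholds: mean
#' expression strictly above \code{min_mean} on the
#' log2(counts-per-10k + 1) scale, in-cluster positive fraction at least
#' \code{min_pct}, delta-pct at least \code{min_delta_pct} and log fold
#' change at least \code{min_logfc}. Set a threshold to \code{NULL} to
#' drop that criterion (the mean-only variant feeds ligand-receptor
#' screens; the full set feeds target-gene prediction).
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell cluster labels.
#' @param min_mean strict lower bound on the per-cluster mean (default 0.3).
#' @param min_pct,min_delta_pct,min_logfc inclusive bounds as in
#'   [markerFilter()]; any may be \code{NULL}.
#' @return character vector of surviving gene ids.
#' @export
expressionFilter <- function(counts, labels, min_mean = 0.3,
                             min_pct = 0.25, min_delta_pct = 0.10,
                             min_logfc = 0.10) {
    labels <- as.character(labels)
    cl <- sort(unique(labels))
    expr <- logNormalize(counts)
    means <- vapply(cl, function(k)
        rowMeans(expr[, labels == k, drop = FALSE]), numeric(nrow(counts)))
    pass <- means > min_mean
    if (!is.null(min_pct) || !is.null(min_delta_pct) || !is.null(min_logfc)) {
        tbl <- deltaPct(counts, labels)
        for (nm in c("pct_in", "delta_pct", "log_fc")) {
            thr <- switch(nm, pct_in = min_pct, delta_pct = min_delta_pct,
                          log_fc = min_logfc)
            if (is.null(thr)) next
            ok <- matrix(tbl[[nm]] >= thr, nrow(counts), length(cl),
                         dimnames = list(rownames(counts), cl))
            pass <- pass & ok
        }
    }
    rownames(counts)[apply(pass, 1, any)]
}

#' Candidate marker panel by top delta-pct per cluster
#'
#' Applies [markerFilter()] and takes, per cluster, the \code{top_n}
#' surviving genes by delta-pct (ties broken by higher log fold change,
#' then lexicographic gene id); returns the union over clusters. If a
#' cluster has fewer than \code{top_n} surviving genes, all of them are
#' taken and a message is emitted.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell cluster labels.
#' @param top_n markers retained per cluster (default 4).
#' @param ... thresholds passed to [markerFilter()].
#' @return sorted character vector: the candidate gene panel.
#' @export
candidatePanel <- function(counts, labels, top_n = 4, ...) {
    tbl <- markerFilter(deltaPct(counts, labels), ...)
    sel <- lapply(split(tbl, tbl$cluster), function(d) {
        d <- d[order(-d$delta_pct, -d$log_fc, d$gene), , drop = FALSE]
        if (nrow(d) < top_n)
            message("cluster ", d$cluster[1], ": only ", nrow(d),
                    " genes pass the marker filter")
        utils::head(d$gene, top_n)
    })
    sort(unique(unlist(sel)))
}
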