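#' Simulate a spatial field of typed cells
#'
#' Cells are placed uniformly at random in a rectangle, assigned a type,
#' and given negative-binomial counts for the panel genes from the
#' reference profiles — the in-silico dataset on which candidate gene
#' panels are scored. The typer ignores geometry (each simulated cell
#' owns its reads), so positions are carried for realism and plotting
#' only.
#'
#' @param profiles an \linkS4class{ExpressionProfiles}.
#' @param panel genes to simulate; must be a subset of the profile genes.
#' @param n_cells number of cells.
#' @param field_size c(width, height) in micrometres (default 1000 x 1000).
#' @param type_props optional type proportions (default uniform).
#' @param seed integer RNG seed.
#' @return list with \code{counts} (panel genes x cells), \code{labels}
#'   (true types) and \code{positions} (cells x 2).
#' @export
simulateField <- function(profiles, panel, n_cells,
                          field_size = c(1000, 1000), type_props = NULL,
                          seed = 1) {
    if (!length(panel)) stop("panel must not be empty")
    missing <- setdiff(panel, rownames(profileMeans(profiles)))
    if (length(missing))
        stop("panel genes absent from profiles: ",
             paste(missing, collapse = ", "))
    sub <- ExpressionProfiles(profileMeans(profiles)[panel, , drop = FALSE],
                              profileDispersion(profiles))
    sim <- simulateCellDataset(n_cells, sub, type_props, seed = seed)
    pos <- cbind(x = stats::runif(n_cells, 0, field_size[1]),
                 y = stats::runif(n_cells, 0, field_size[2]))
    list(counts = sim$counts, labels = sim$labels, positions = pos)
}

# per-type NB log-likelihood matrices for a panel counts matrix;
# zero profile means are floored so a stray count never yields -Inf ties
.nbLogliks <- function(counts, profiles, mu_floor = 1e-6) {
    mu <- profileMeans(profiles)[rownames(counts), , drop = FALSE]
    size <- profileDispersion(profiles)
    types <- sort(colnames(mu))
    lapply(stats::setNames(types, types), function(t)
        matrix(stats::dnbinom(counts, size = size,
                              mu = pmax(mu[, t], mu_floor), log = TRUE),
               nrow(counts), ncol(counts), dimnames = dimnames(counts)))
}

#' Probabilistic cell typing by negative-binomial likelihood
#'
#' Assigns each cell the maximum-a-posteriori type under an independent
#' negative-binomial model: the score of type t is the sum over panel
#' genes of log NB(count | mean = profile mean, size = dispersion) plus
#' the log prior (uniform by default). Posteriors are normalised over
#' types; exact ties are broken towards the lexicographically first type.
#'
#' @param counts panel genes x cells count matrix (e.g.
#'   \code{simulateField()$counts}).
#' @param profiles an \linkS4class{ExpressionProfiles} covering the panel
#'   genes.
#' @param prior optional per-type prior probabilities (named).
#' @return list with \code{type} (per-cell assignment) and
#'   \code{posterior} (cells x types matrix, rows summing to 1).
#' @export
typeCells <- function(counts, profiles, prior = NULL) {
    ll <- .nbLogliks(counts, profiles)
    types <- names(ll)
    score <- do.call(rbind, lapply(ll, colSums))   # types x cells
    if (!is.null(prior)) score <- score + log(prior[types])
    if (all(!is.finite(score))) stop("all type likelihoods degenerate")
    m <- apply(score, 2, max)
    post <- exp(t(score) - m)
    post <- post / rowSums(post)
    colnames(post) <- types
    list(type = types[apply(score, 2, which.max)], posterior = post)
}

# assignment accuracy per true type given total scores (types x cells)
.perTypeAccuracy <- function(score, labels, types) {
    assigned <- types[apply(score, 2, which.max)]
    vapply(stats::setNames(types, types), function(t) {
        idx <- labels == t
        if (!any(idx)) NA_real_ else mean(assigned[idx] == t)
    }, numeric(1))
}

#' Leave-one-gene-out contribution of panel genes to typing accuracy
#'
#' For each gene g and true type t, the contribution is the per-type
#' typing accuracy with the full panel minus the accuracy with g removed,
#' averaged over \code{n_rep} independently simulated fields. A gene with
#' identical means across types contributes approximately zero; the sole
#' discriminating gene between two types carries their whole accuracy.
#'
#' @param profiles an \linkS4class{ExpressionProfiles}.
#' @param panel gene panel (length >= 2).
#' @param n_cells cells per simulated field (default 3000).
#' @param n_rep simulation replicates averaged over (default 5).
#' @param type_props optional type proportions.
#' @param seed integer RNG seed.
#' @return list with \code{contribution} (genes x types matrix) and
#'   \code{accuracy} (per-type accuracy of the full panel, averaged over
#'   replicates).
#' @export
geneContributions <- function(profiles, panel, n_cells = 3000, n_rep = 5,
                              type_props = NULL, seed = 1) {
    if (length(panel) < 2) stop("panel must contain at least 2 genes")
    types <- sort(colnames(profileMeans(profiles)))
    contrib <- matrix(0, length(panel), length(types),
                      dimnames = list(panel, types))
    acc_full <- stats::setNames(numeric(length(types)), types)
    for (r in seq_len(n_rep)) {
        fld <- simulateField(profiles, panel, n_cells,
                             type_props = type_props,
                             seed = seed * 1000L + r)
        ll <- .nbLogliks(fld$counts, profiles)
        total <- do.call(rbind, lapply(ll, colSums))  # types x cells
        a_full <- .perTypeAccuracy(total, fld$labels, types)
        acc_full <- acc_full + a_full / n_rep
        for (g in panel) {
            reduced <- total - do.call(rbind, lapply(ll, function(m) m[g, ]))
            a_g <- .perTypeAccuracy(reduced, fld$labels, types)
            contrib[g, ] <- contrib[g, ] + (a_full - a_g) / n_rep
        }
    }
    list(contribution = contrib, accuracy = acc_full)
}

#' Simulation-driven curation of a targeted gene panel
#'
#' Iterates simulate-type-score rounds: each round simulates fields from
#' the reference profiles, types every cell with the candidate panel,
#' computes leave-one-gene-out contributions, and keeps the union over
#' cell types of the top \code{keep_per_type} genes by contribution. The
#' loop stops when every type's accuracy reaches \code{accuracy_target}
#' (converged) or after \code{max_iters} rounds; the best panel seen is
#' returned either way.
#'
#' @param candidates candidate gene list (e.g. from [candidatePanel()]).
#' @param profiles an \linkS4class{ExpressionProfiles}.
#' @param keep_per_type genes kept per type each round (default 5).
#' @param accuracy_target per-type accuracy floor declaring convergence
#'   (default 0.95).
#' @param max_iters maximum rounds (default 10).
#' @param n_cells,n_rep,type_props forwarded to [geneContributions()].
#' @param seed integer RNG seed.
#' @return list with \code{panel} (final gene list), \code{converged},
#'   \code{trace} (data.frame of per-iteration per-type accuracy and
#'   panel size), and \code{contribution} (last round's matrix).
#' @export
curatePanel <- function(candidates, profiles, keep_per_type = 5,
                        accuracy_target = 0.95, max_iters = 10,
                        n_cells = 3000, n_rep = 5, type_props = NULL,
                        seed = 1) {
    panel <- sort(unique(candidates))
    types <- sort(colnames(profileMeans(profiles)))
    trace <- list()
    converged <- FALSE
    contrib <- NULL
    best <- list(panel = panel, floor = -Inf)
    for (it in seq_len(max_iters)) {
        gc_ <- geneContributions(profiles, panel, n_cells = n_cells,
                                 n_rep = n_rep, type_props = type_props,
                                 seed = seed + 7919L * it)
        contrib <- gc_$contribution
        kept <- sort(unique(unlist(lapply(types, function(t) {
            d <- contrib[, t]
            names(sort(d, decreasing = TRUE))[seq_len(min(keep_per_type,
                                                          length(d)))]
        }))))
        trace[[it]] <- data.frame(iteration = it, t(gc_$accuracy),
                                  panel_size = length(panel),
                                  check.names = FALSE)
        floor_ <- min(gc_$accuracy, na.rm = TRUE)
        if (floor_ > best$floor) best <- list(panel = panel, floor = floor_)
        ok <- all(gc_$accuracy >= accuracy_target, na.rm = TRUE)
        stable <- setequal(kept, panel)
        # converged once the target holds for a panel that top-k
        # retention can no longer shrink (or that already survived a
        # reduction round)
        if (ok && (stable || it > 1)) {
            converged <- TRUE
            break
        }
        if (stable) break    # stalled below target: no further reduction
        panel <- kept
    }
    if (!converged) panel <- best$panel
    list(panel = panel, converged = converged,
         trace = do.call(rbind, trace), contribution = contrib)
}
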