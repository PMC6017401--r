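# Independent numerical oracle for generic body-bar rigidity: place each
# body at a random generic pose, build the bar rigidity matrix (one row
# per bar, the standard 12-entry body-bar row from the bar endpoints'
# positions and moments), and read total DOF off its rank.  Bodies u, v
# are in one rigid component iff every null-space motion assigns them the
# same (translation, angular velocity) pair.  Repeated with several
# random placements, keeping the maximum rank, to guard against
# accidental degeneracy.
rankOracle <- function(graph, reps = 3) {
    n <- graph@nNodes
    e <- graph@edges
    best <- -1
    bestNull <- NULL
    for (r in seq_len(reps)) {
        set.seed(r * 977 + nrow(e))
        centers <- matrix(rnorm(3 * n, sd = 10), n, 3)
        if (nrow(e)) {
            R <- matrix(0, nrow(e), 6 * n)
            for (k in seq_len(nrow(e))) {
                u <- e[k, 1]; v <- e[k, 2]
                pu <- centers[u, ] + rnorm(3)
                pv <- centers[v, ] + rnorm(3)
                d <- pu - pv
                R[k, (6 * (u - 1) + 1):(6 * (u - 1) + 3)] <- d
                R[k, (6 * (u - 1) + 4):(6 * (u - 1) + 6)] <-
                    c(pu[2] * d[3] - pu[3] * d[2],
                      pu[3] * d[1] - pu[1] * d[3],
                      pu[1] * d[2] - pu[2] * d[1])
                R[k, (6 * (v - 1) + 1):(6 * (v - 1) + 3)] <- -d
                R[k, (6 * (v - 1) + 4):(6 * (v - 1) + 6)] <-
                    -c(pv[2] * d[3] - pv[3] * d[2],
                       pv[3] * d[1] - pv[1] * d[3],
                       pv[1] * d[2] - pv[2] * d[1])
            }
            rk <- qr(R, tol = 1e-9)$rank
        } else {
            R <- NULL
            rk <- 0
        }
        if (rk > best) {
            best <- rk
            bestNull <- if (is.null(R)) diag(6 * n) else
                svd(R, nu = 0, nv = 6 * n)$v[, seq(best + 1, 6 * n),
                                             drop = FALSE]
        }
    }
    lab <- seq_len(n)
    if (n >= 2) for (u in seq_len(n - 1)) for (v in (u + 1):n) {
        Nu <- bestNull[(6 * (u - 1) + 1):(6 * u), , drop = FALSE]
        Nv <- bestNull[(6 * (v - 1) + 1):(6 * v), , drop = FALSE]
        if (max(abs(Nu - Nv)) < 1e-6) {
            old <- lab[v]
            lab[lab == old] <- lab[u]
        }
    }
    list(dof = 6 * n - best, labels = match(lab, unique(lab)))
}

# canonical cluster labelling of a decomposition, for partition comparison
decompLabels <- function(decomp) {
    lab <- integer(decomp@nBodies)
    for (k in seq_along(decomp@clusterIds))
        lab[decomp@clusterBodies[[k]]] <- k
    match(lab, unique(lab))
}
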