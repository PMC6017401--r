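# Correlation analyses and plot-ready exports for the cavity-rigidity
# survey.  Pearson is the default estimator throughout (Spearman behind a
# flag); the nonlinear fit quality is reported as the correlation between
# fitted and observed responses.

#' Pearson correlation of a metric pair set
#'
#' Pairs with a missing member are dropped pairwise (the dropped count is
#' attached as attribute \code{"n_dropped"}).
#'
#' @param pairs data.frame with numeric columns \code{x} and \code{y}, or
#'   the first of two numeric vectors.
#' @param y second numeric vector when \code{pairs} is a vector.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonCorrelation <- function(pairs, y = NULL, method = "pearson") {
    if (is.data.frame(pairs)) {
        x <- pairs$x
        y <- pairs$y
    } else x <- pairs
    stopifnot(length(x) == length(y))
    ok <- is.finite(x) & is.finite(y)
    dropped <- sum(!ok)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: zero variance")
    r <- cor(x, y, method = method)
    attr(r, "n_dropped") <- dropped
    attr(r, "n") <- length(x)
    r
}

.NLS_MODELS <- list(
    gaussian_peak = list(
        formula = y ~ a * exp(-(x - m)^2 / (2 * s^2)),
        starts = function(x, y) {
            qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
            expand.grid(a = max(abs(y)) * c(0.5, 1, 1.5),
                        m = qs,
                        s = diff(range(x)) * c(0.1, 0.25, 0.5))
        }),
    saturating_exponential = list(
        formula = y ~ a * (1 - exp(-x / b)),
        starts = function(x, y) {
            expand.grid(a = max(abs(y)) * c(0.5, 1, 2),
                        b = diff(range(x)) * c(0.1, 0.5, 1))
        }),
    power_law = list(
        formula = y ~ a * x^b,
        starts = function(x, y) {
            expand.grid(a = max(abs(y)) * c(0.1, 1),
                        b = c(0.25, 0.5, 1, 2))
        }))

#' Nonlinear least-squares fit with fit-quality score
#'
#' Fits one of three curve families by least squares using a
#' deterministic multi-start grid (every start is tried; the converged
#' fit with the smallest residual sum of squares wins).  The goodness
#' score is the correlation between fitted and observed y, clamped to
#' [0, 1].
#'
#' @param pairs data.frame with numeric columns \code{x}, \code{y}.
#' @param model \code{"gaussian_peak"} (default),
#'   \code{"saturating_exponential"} or \code{"power_law"}.
#' @return list with \code{model}, \code{parameters} (named numeric),
#'   \code{goodness} in [0, 1], and \code{rss}.
#' @export
nlsFit <- function(pairs, model = "gaussian_peak") {
    if (!model %in% names(.NLS_MODELS))
        stop("unknown model: ", model)
    spec <- .NLS_MODELS[[model]]
    ok <- is.finite(pairs$x) & is.finite(pairs$y)
    dat <- data.frame(x = pairs$x[ok], y = pairs$y[ok])
    npar <- length(all.vars(spec$formula)) - 2L
    if (nrow(dat) < npar + 2)
        stop("need at least ", npar + 2, " complete pairs")
    starts <- spec$starts(dat$x, dat$y)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            minpack.lm::nlsLM(spec$formula, data = dat,
                              start = as.list(starts[i, , drop = FALSE]),
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 200)),
            error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
        stop("fit failed: no start converged for model ", model,
             " (residual range ", paste(range(dat$y), collapse = " .. "),
             ")")
    fv <- fitted(best$fit)
    goodness <- if (sd(fv) == 0 || sd(dat$y) == 0) 0
                else max(0, cor(fv, dat$y))
    list(model = model, parameters = coef(best$fit),
         goodness = goodness, rss = best$rss)
}

#' Subsample survey records by chain
#'
#' Uniform without-replacement sample of \code{k} distinct chains; every
#' record of a sampled chain is kept.  Reproducible under a fixed seed
#' and isolated from the caller's RNG stream.
#'
#' @param records data.frame with a \code{chain} column.
#' @param k number of chains to keep.
#' @param seed RNG seed.
#' @return the subset of \code{records}.
#' @export
subsampleChains <- function(records, k, seed = 1) {
    chains <- unique(records$chain)
    if (k > length(chains))
        stop("k exceeds the number of distinct chains (",
             length(chains), ")")
    pick <- withSeed(seed, sample(chains, k))
    out <- records[records$chain %in% pick, , drop = FALSE]
    rownames(out) <- NULL
    out
}

.FIGURES <- list(
    fig2 = list(table = "cavities", x = "n_residues",
                y = "n_rigid_clusters", size = NA),
    fig3 = list(table = "cavities", x = "n_rigid_atoms",
                y = "n_rigid_clusters", size = "surface_area"),
    fig4 = list(table = "cavities", x = "pct_rigid_atoms_in_cavity",
                y = "n_rigid_clusters", size = "surface_area"),
    fig5 = list(table = "cavities", x = "mean_rvet",
                y = "n_rigid_clusters", size = "surface_area"),
    fig6 = list(table = "clusters", x = "n_atoms",
                y = "mean_cavity_area", size = NA),
    fig7 = list(table = "clusters", x = "n_atoms",
                y = "cavity_participation", size = "n_atoms"),
    fig8 = list(table = "clusters", x = "n_atoms",
                y = "max_cavity_area", size = "n_atoms"),
    fig9 = list(table = "clusters", x = "cavity_participation",
                y = "mean_rvet", size = "n_atoms"))

#' Export plot-ready data for one survey figure
#'
#' Projects the cavity or cluster record table onto the x/y/size axes of
#' the requested scatter plot (fig2..fig9 of the survey: e.g. fig2 plots
#' rigid clusters per cavity against residues per cavity; fig7 plots
#' cavity participation against rigid-cluster size).
#'
#' @param records list with elements \code{cavities} and \code{clusters}
#'   (record data.frames).
#' @param figureId one of \code{"fig2"} .. \code{"fig9"}.
#' @param path optional TSV output file.
#' @return data.frame with columns \code{x}, \code{y}, \code{size},
#'   \code{label}.
#' @export
exportPlotData <- function(records, figureId, path = NULL) {
    if (!figureId %in% names(.FIGURES))
        stop("unknown figure id: ", figureId)
    fig <- .FIGURES[[figureId]]
    tab <- records[[fig$table]]
    idcol <- if (fig$table == "cavities") "cavity_id" else "cluster_id"
    out <- data.frame(x = tab[[fig$x]], y = tab[[fig$y]],
                      size = if (is.na(fig$size)) NA_real_
                             else tab[[fig$size]],
                      label = paste0(tab$chain, "/", tab[[idcol]]),
                      stringsAsFactors = FALSE)
    if (!is.null(path)) {
        con <- file(path, "wb")
        write.table(out, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, na = "")
        close(con)
    }
    out
}
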