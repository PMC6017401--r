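test_that("pearson behaves on identity, null and correlated data", {
    x <- 1:10
    expect_equal(as.numeric(pearsonCorrelation(data.frame(x = x, y = x))),
                 1)
    set.seed(5)
    r0 <- pearsonCorrelation(data.frame(x = rnorm(10000),
                                        y = rnorm(10000)))
    expect_lt(abs(as.numeric(r0)), 0.05)
    z <- MASS::mvrnorm(5000, c(0, 0),
                       matrix(c(1, 0.9, 0.9, 1), 2))
    r9 <- pearsonCorrelation(data.frame(x = z[, 1], y = z[, 2]))
    expect_lt(abs(as.numeric(r9) - 0.9), 0.02)
})

test_that("pearson is symmetric, affine invariant, and errors on degeneracy", {
    set.seed(8)
    x <- rnorm(50)
    y <- rnorm(50)
    r <- as.numeric(pearsonCorrelation(data.frame(x = x, y = y)))
    expect_equal(as.numeric(pearsonCorrelation(data.frame(x = y, y = x))),
                 r)
    expect_equal(as.numeric(pearsonCorrelation(
        data.frame(x = 3 * x + 7, y = 0.5 * y - 2))), r)
    expect_error(pearsonCorrelation(data.frame(x = 1:2, y = 2:3)),
                 "at least 3")
    expect_error(pearsonCorrelation(data.frame(x = rep(1, 10),
                                               y = rnorm(10))),
                 "undefined correlation")
    # missing pairs dropped pairwise and counted
    rm <- pearsonCorrelation(data.frame(x = c(x, NA), y = c(y, 1)))
    expect_equal(attr(rm, "n_dropped"), 1)
})

test_that("nls fitting recovers known curves and rejects none", {
    x <- seq(0, 10, length.out = 500)
    y <- 3 * exp(-(x - 4)^2 / (2 * 1.5^2))
    f <- nlsFit(data.frame(x = x, y = y))
    expect_equal(unname(f$parameters), c(3, 4, 1.5), tolerance = 1e-6)
    expect_equal(f$goodness, 1, tolerance = 1e-6)

    set.seed(21)
    yn <- y + rnorm(500, 0, 0.3)
    fn <- nlsFit(data.frame(x = x, y = yn))
    expect_equal(unname(fn$parameters), c(3, 4, 1.5), tolerance = 0.1)

    noise <- nlsFit(data.frame(x = runif(1000), y = rnorm(1000)))
    expect_lt(noise$goodness, 0.2)

    sat <- nlsFit(data.frame(x = x, y = 5 * (1 - exp(-x / 2))),
                  model = "saturating_exponential")
    expect_equal(unname(sat$parameters), c(5, 2), tolerance = 1e-5)
    expect_error(nlsFit(data.frame(x = x, y = y), model = "cubic"),
                 "unknown model")
})

test_that("chain subsampling is reproducible and faithful", {
    mc <- makeMetricCorpus(100, 0.5, seed = 9)
    recs <- mc$cavities
    all_ <- subsampleChains(recs, length(unique(recs$chain)), seed = 1)
    expect_equal(nrow(all_), nrow(recs))
    one <- subsampleChains(recs, 1, seed = 3)
    expect_length(unique(one$chain), 1)
    s1 <- subsampleChains(recs, 40, seed = 11)
    s2 <- subsampleChains(recs, 40, seed = 11)
    expect_identical(s1, s2)
    expect_error(subsampleChains(recs, 1000), "exceeds")
    # distributional consistency: subsample mean within 3 SE
    se <- sd(recs$n_residues) / sqrt(nrow(s1))
    expect_lt(abs(mean(s1$n_residues) - mean(recs$n_residues)), 3 * se)
})

test_that("recovered correlation converges to the generator's rho", {
    rho <- 0.6
    err <- vapply(c(20, 200, 2000), function(nch) {
        mc <- makeMetricCorpus(nch, rho, seed = nch)
        r <- pearsonCorrelation(data.frame(x = mc$cavities$n_residues,
                                           y = mc$cavities$n_rigid_clusters))
        abs(as.numeric(r) - rho)
    }, 1)
    expect_lt(err[3], 0.02)
    expect_lt(err[3], err[1])
})

test_that("plot exports carry the documented axes for all eight figures", {
    mc <- makeMetricCorpus(30, 0.4, seed = 2)
    recs <- list(cavities = mc$cavities, clusters = mc$clusters)
    for (fig in paste0("fig", 2:9)) {
        pd <- exportPlotData(recs, fig)
        expect_named(pd, c("x", "y", "size", "label"))
        nexp <- if (fig %in% paste0("fig", 2:5)) nrow(mc$cavities)
                else nrow(mc$clusters)
        expect_equal(nrow(pd), nexp)
    }
    expect_error(exportPlotData(recs, "fig99"), "unknown figure")
    # fig2 is the (residues, rigid clusters) projection
    pd2 <- exportPlotData(recs, "fig2")
    expect_equal(pd2$x, mc$cavities$n_residues)
    expect_equal(pd2$y, mc$cavities$n_rigid_clusters)
    # fig7 is the (cluster size, participation) projection
    pd7 <- exportPlotData(recs, "fig7")
    expect_equal(pd7$x, mc$clusters$n_atoms)
    expect_equal(pd7$y, mc$clusters$cavity_participation)
    p <- withr::local_tempfile(fileext = ".tsv")
    exportPlotData(recs, "fig3", path = p)
    expect_equal(nrow(read.table(p, sep = "\t", header = TRUE)),
                 nrow(mc$cavities))
})
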