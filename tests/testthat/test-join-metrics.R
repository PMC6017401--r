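test_that("association is set intersection with a threshold", {
    cav <- list(list(cavity_id = 1L, atom_ids = 1:10, area = 100,
                     residue_keys = character()))
    clu <- list(list(cluster_id = 0L, atom_ids = 1:5),
                list(cluster_id = 1L, atom_ids = 6:8),
                list(cluster_id = 2L, atom_ids = 20:30))
    m <- associateCavities(cav, clu)
    expect_equal(nrow(m), 2)
    expect_setequal(m$cluster_id, c(0L, 1L))
    expect_equal(m$shared[m$cluster_id == 0L], 5L)

    # disjoint sets: empty map
    clu2 <- list(list(cluster_id = 0L, atom_ids = 50:60))
    expect_equal(nrow(associateCavities(cav, clu2)), 0)

    # threshold is configurable
    expect_equal(nrow(associateCavities(cav, clu, minSharedAtoms = 4)), 1)
})

test_that("association equals brute-force pairwise intersection", {
    for (seed in 1:10) {
        fx <- randomAssociationFixture(seed)
        m <- associateCavities(fx$cavities, fx$clusters)
        for (cv in fx$cavities)
            for (cl in fx$clusters) {
                s <- length(intersect(cv$atom_ids, cl$atom_ids))
                hit <- m$shared[m$cavity_id == cv$cavity_id &
                                m$cluster_id == cl$cluster_id]
                if (s >= 1) expect_equal(hit, s)
                else expect_length(hit, 0)
            }
    }
})

test_that("cavity and cluster records match the hand-computed fixture", {
    fx <- joinFixture()
    m <- associateCavities(fx$cavities, fx$clusters)
    cav <- computeCavityRecords(m, fx$cavities, fx$clusters, et = fx$et,
                                chain = "fixA")
    clu <- computeClusterRecords(m, fx$cavities, fx$clusters,
                                 structure = fx$structure, et = fx$et,
                                 chain = "fixA")
    expCav <- expectedTsv("join_fixture_expected_cavities.tsv")
    expClu <- expectedTsv("join_fixture_expected_clusters.tsv")
    for (cn in names(expCav))
        expect_equal(cav[[cn]], expCav[[cn]], info = cn)
    for (cn in names(expClu))
        expect_equal(clu[[cn]], expClu[[cn]], info = cn)
})

test_that("a cavity without clusters is flagged with pct zero", {
    cav <- list(list(cavity_id = 1L, atom_ids = 1:4, area = 60,
                     residue_keys = resKeyVec(1:2)))
    clu <- list(list(cluster_id = 0L, atom_ids = 40:50))
    m <- associateCavities(cav, clu)
    rec <- computeCavityRecords(m, cav, clu)
    expect_equal(rec$n_rigid_clusters, 0L)
    expect_equal(rec$pct_rigid_atoms_in_cavity, 0)
    expect_true(rec$no_clusters)
    crec <- computeClusterRecords(m, cav, clu)
    expect_equal(crec$cavity_participation, 0L)
    expect_true(is.na(crec$mean_cavity_area))
    expect_true(is.na(crec$max_cavity_area))
})

test_that("bipartite degrees are conserved and pct stays within [0,100]", {
    for (seed in 1:50) {
        fx <- randomAssociationFixture(seed + 100)
        m <- associateCavities(fx$cavities, fx$clusters)
        cav <- computeCavityRecords(m, fx$cavities, fx$clusters)
        clu <- computeClusterRecords(m, fx$cavities, fx$clusters)
        expect_equal(sum(cav$n_rigid_clusters),
                     sum(clu$cavity_participation))
        expect_true(all(cav$pct_rigid_atoms_in_cavity >= 0 &
                        cav$pct_rigid_atoms_in_cavity <= 100))
        full <- cav$pct_rigid_atoms_in_cavity == 100
        if (any(full)) for (i in which(full)) {
            part <- m$cluster_id[m$cavity_id == cav$cavity_id[i]]
            pa <- unique(unlist(lapply(fx$clusters, function(cl)
                if (cl$cluster_id %in% part) cl$atom_ids)))
            expect_true(all(pa %in%
                fx$cavities[[i]]$atom_ids))
        }
        expect_true(all(clu$mean_cavity_area <= clu$max_cavity_area,
                        na.rm = TRUE))
    }
})

test_that("removing a cavity never increases any cluster's participation", {
    fx <- randomAssociationFixture(7)
    m1 <- associateCavities(fx$cavities, fx$clusters)
    c1 <- computeClusterRecords(m1, fx$cavities, fx$clusters)
    for (drop in seq_along(fx$cavities)) {
        sub <- fx$cavities[-drop]
        m2 <- associateCavities(sub, fx$clusters)
        c2 <- computeClusterRecords(m2, sub, fx$clusters)
        expect_true(all(c2$cavity_participation <=
                        c1$cavity_participation))
    }
})

test_that("aggregate files round-trip through TSV and JSON", {
    fx <- joinFixture()
    m <- associateCavities(fx$cavities, fx$clusters)
    clu <- computeClusterRecords(m, fx$cavities, fx$clusters,
                                 structure = fx$structure, et = fx$et,
                                 chain = "fixA")
    prefix <- withr::local_tempfile()
    paths <- writeAggregates(clu, prefix)
    tsv <- read.table(paths[["tsv"]], sep = "\t", header = TRUE)
    expect_equal(nrow(tsv), nrow(clu))
    expect_equal(names(tsv), names(clu))
    expect_true(is.na(tsv$mean_cavity_area[tsv$cluster_id == 2]))
    back <- jsonlite::fromJSON(paths[["json"]])
    expect_equal(back$cluster_id, clu$cluster_id)
    expect_equal(back$mean_rvet, clu$mean_rvet)
    expect_true(is.na(back$mean_cavity_area[3]))
    expect_true(grepl("null",
                      paste(readLines(paths[["json"]]), collapse = "")))

    # zero records: header-only TSV, empty JSON array
    empty <- clu[0, ]
    p0 <- withr::local_tempfile()
    paths0 <- writeAggregates(empty, p0)
    expect_length(readLines(paths0[["tsv"]]), 1)
    expect_equal(paste(readLines(paths0[["json"]]), collapse = ""), "[]")
})
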