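test_that("single bodies and hinge/rigid pairs decompose correctly", {
    g0 <- makeRandomBodyBarGraph(1, 0)
    d0 <- pebbleGameDecompose(g0)
    expect_equal(length(d0@clusterIds), 1)
    expect_equal(totalFreeDof(d0), 6)

    hinge <- bodyBarGraph(data.frame(body_u = 1, body_v = 2, bars = 5),
                          nNodes = 2)
    dh <- pebbleGameDecompose(hinge)
    expect_equal(length(dh@clusterIds), 2)
    expect_equal(totalFreeDof(dh), 7)   # 6 trivial + 1 internal
    expect_equal(dofBetween(hinge, 1, 2), 1)

    rigid <- bodyBarGraph(data.frame(body_u = 1, body_v = 2, bars = 6),
                          nNodes = 2)
    dr <- pebbleGameDecompose(rigid)
    expect_equal(length(dr@clusterIds), 1)
    expect_equal(totalFreeDof(dr), 6)
    expect_equal(dofBetween(rigid, 1, 2), 0)
})

test_that("relative DOF between disconnected bodies is 6", {
    g <- makeRandomBodyBarGraph(3, 0)
    expect_equal(dofBetween(g, 1, 3), 6)
    expect_error(dofBetween(g, 1, 9), "unknown node")
})

test_that("self-loops are rejected", {
    expect_error(new("BodyBarGraph", nNodes = 2L,
                     edges = matrix(c(1L, 1L), ncol = 2)),
                 "self-loop")
})

test_that("the pebble invariant holds: free pebbles + accepted bars = 6n", {
    for (seed in 1:10) {
        g <- makeRandomBodyBarGraph(6, 18, seed = seed)
        res <- CavityRigidity:::cpp_pebble_game(g@nNodes, g@edges)
        expect_equal(sum(res$pebbles) + sum(res$accepted), 6 * g@nNodes)
        expect_equal(res$totalFreeDof, sum(res$pebbles))
    }
})

test_that("decomposition matches the rigidity-matrix rank oracle", {
    for (seed in 1:40) {
        set.seed(seed + 1000)
        n <- sample(2:8, 1)
        m <- sample(0:24, 1)
        g <- makeRandomBodyBarGraph(n, m, seed = seed)
        dec <- pebbleGameDecompose(g)
        or <- rankOracle(g)
        expect_equal(totalFreeDof(dec), or$dof)
        expect_equal(decompLabels(dec), or$labels)
    }
})

test_that("decomposition is invariant under edge insertion order", {
    for (gseed in 1:5) {
        g <- makeRandomBodyBarGraph(7, 20, seed = gseed)
        ref <- pebbleGameDecompose(g)
        for (p in 1:10) {
            set.seed(p * 31 + gseed)
            gp <- new("BodyBarGraph", nNodes = g@nNodes,
                      edges = g@edges[sample.int(nrow(g@edges)), ,
                                      drop = FALSE])
            dp <- pebbleGameDecompose(gp)
            expect_equal(totalFreeDof(dp), totalFreeDof(ref))
            expect_equal(decompLabels(dp), decompLabels(ref))
        }
    }
})

test_that("adding a bar never increases the total free DOF", {
    g <- makeRandomBodyBarGraph(6, 22, seed = 5)
    dofs <- vapply(seq_len(nrow(g@edges)), function(k) {
        gk <- new("BodyBarGraph", nNodes = g@nNodes,
                  edges = g@edges[seq_len(k), , drop = FALSE])
        totalFreeDof(pebbleGameDecompose(gk))
    }, 1L)
    expect_true(all(diff(dofs) <= 0))
})

test_that("cluster atom sets are body unions with hinge atoms shared", {
    # two locked triangles joined by one rotatable bond
    at <- simpleAtoms(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0),
                            c(3.0, 0, 0), c(4.5, 0, 0), c(3.75, 1.3, 0)))
    s <- chainStructure(at)
    bonds <- data.frame(
        atom_a = c(1L, 2L, 1L, 4L, 5L, 4L, 2L),
        atom_b = c(2L, 3L, 3L, 5L, 6L, 6L, 4L),
        kind = c(rep("covalent_locked", 6), "covalent_rotatable"),
        distance = 1.5, angle = NA_real_)
    m <- buildMechanicalModel(s, bonds)
    dec <- clustersToAtoms(pebbleGameDecompose(bodyBarGraph(m)), m)
    expect_length(dec@clusterIds, 2)
    expect_true(all(c(2L, 4L) %in% dec@clusterAtoms[[1]]))
    expect_true(all(c(2L, 4L) %in% dec@clusterAtoms[[2]]))
    # union counts the shared atoms once
    expect_equal(vapply(dec@clusterAtoms, length, 1L), c(4L, 4L))
    # every atom is in at least one cluster
    expect_setequal(unique(unlist(dec@clusterAtoms)), 1:6)
})

test_that("every polymer atom lands in at least one rigid cluster", {
    g <- makePolymerChain(8, lockedFraction = 0.5, seed = 2)
    m <- buildMechanicalModel(g$structure, g$bonds)
    dec <- clustersToAtoms(pebbleGameDecompose(bodyBarGraph(m)), m)
    expect_setequal(unique(unlist(dec@clusterAtoms)),
                    atomTable(g$structure)$atom_id)
})

test_that("cluster XML follows the body/point schema and round-trips", {
    p <- withr::local_tempfile(fileext = ".xml")
    writeClusterXml(list(list(body_id = 0L, atom_ids = c(3L, 2L))), p)
    doc <- xml2::read_xml(p)
    body <- xml2::xml_find_all(doc, ".//body")
    expect_length(body, 1)
    expect_equal(xml2::xml_attr(body, "id"), "0")
    pts <- xml2::xml_find_all(body, "./point")
    expect_equal(xml2::xml_attr(pts, "id"), c("2", "3"))

    # empty decomposition: valid XML, zero bodies
    pe <- withr::local_tempfile(fileext = ".xml")
    writeClusterXml(list(), pe)
    expect_length(readClusterXml(pe), 0)

    # random decomposition: write/read/write is byte-stable
    set.seed(77)
    rnd <- lapply(0:5, function(i)
        list(body_id = i, atom_ids = sort(sample(1:500, sample(1:30, 1)))))
    p1 <- withr::local_tempfile(fileext = ".xml")
    p2 <- withr::local_tempfile(fileext = ".xml")
    writeClusterXml(rnd, p1)
    back <- readClusterXml(p1)
    expect_equal(back, rnd)
    writeClusterXml(back, p2)
    expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed XML reports a parse error", {
    p <- withr::local_tempfile(fileext = ".xml")
    writeLines("<rigidClusters><body id='0'>", p)
    expect_error(readClusterXml(p), "parse error")
})
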