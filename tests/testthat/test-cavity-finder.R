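singleCarbon <- function() chainStructure(simpleAtoms(cbind(0, 0, 0)))

test_that("sphere surface area converges to the analytic value", {
    s <- singleCarbon()
    exact <- 4 * pi * 1.9^2
    errs <- vapply(c(0.8, 0.4, 0.2), function(sp) {
        ms <- computeMolecularSurface(s, probe = 1.4, spacing = sp,
                                      radii = 1.9, margin = 6)
        abs(meshArea(ms$mesh) - exact) / exact
    }, 1)
    expect_lt(errs[3], 0.02)
    expect_true(all(diff(errs) < 0))    # monotone refinement
})

test_that("far-apart atoms give disjoint spheres with additive area", {
    at <- simpleAtoms(cbind(c(0, 20), 0, 0))
    s <- chainStructure(at)
    ms <- computeMolecularSurface(s, probe = 1.4, spacing = 0.2,
                                  radii = 1.9, margin = 6)
    expect_equal(meshArea(ms$mesh), 2 * 4 * pi * 1.9^2,
                 tolerance = 0.02)
    # two connected components: vertices cluster around the two centres
    mid <- ms$mesh@vertices[, 1] > 5 & ms$mesh@vertices[, 1] < 15
    expect_false(any(mid))
})

test_that("zero probe yields the bare van der Waals surface", {
    s <- singleCarbon()
    ms <- computeMolecularSurface(s, probe = 0, spacing = 0.2,
                                  radii = 1.9, margin = 4)
    expect_equal(meshArea(ms$mesh), 4 * pi * 1.9^2, tolerance = 0.02)
})

test_that("degenerate grid parameters are rejected", {
    s <- singleCarbon()
    expect_error(computeMolecularSurface(s, spacing = 0), "spacing")
    expect_error(computeMolecularSurface(s, spacing = 0.01,
                                         maxVoxels = 1e4),
                 "grid too large")
})

test_that("a hollow shell holds exactly one interior void of the analytic area", {
    sh <- makeHollowShell(8, 1.5)
    ms <- computeMolecularSurface(sh$structure, spacing = 0.5)
    cavs <- detectCavities(ms$grid, sh$structure, mesh = ms$mesh)
    expect_length(cavs, sh$expectedCavities)
    expect_equal(cavs[[1]]@kind, "void")
    expect_lt(abs(surfaceArea(cavs[[1]]) - sh$expectedArea) /
              sh$expectedArea, 0.15)
    # lining residues all carry at least one lining atom
    a <- atomTable(sh$structure)
    keys <- paste0(a$resno, ":")[match(cavityAtoms(cavs[[1]]), a$atom_id)]
    expect_setequal(unique(keys), cavityResidues(cavs[[1]]))
})

test_that("a solid convex cluster has no cavities", {
    d <- 3.0
    tet <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0),
                 c(d / 2, d * sqrt(3) / 6, d * sqrt(2 / 3)))
    s <- chainStructure(simpleAtoms(tet))
    ms <- computeMolecularSurface(s, spacing = 0.5)
    expect_length(detectCavities(ms$grid, s, mesh = ms$mesh), 0)
})

test_that("an open pocket is found with its constructed lining", {
    op <- makeOpenPocket()
    ms <- computeMolecularSurface(op$structure, spacing = 0.5)
    cavs <- detectCavities(ms$grid, op$structure, mesh = ms$mesh)
    expect_length(cavs, 1)
    expect_equal(cavs[[1]]@kind, "pocket")
    det <- cavityAtoms(cavs[[1]])
    tru <- op$liningAtoms
    jac <- length(intersect(det, tru)) / length(union(det, tru))
    expect_gte(jac, 0.9)
})

test_that("cavity areas are translation invariant", {
    sh <- makeHollowShell(8, 1.5)
    a <- atomTable(sh$structure)
    a$x <- a$x + 7.3; a$y <- a$y - 2.1; a$z <- a$z + 0.4
    shifted <- chainStructure(a)
    m1 <- computeMolecularSurface(sh$structure, spacing = 0.5)
    m2 <- computeMolecularSurface(shifted, spacing = 0.5)
    a1 <- surfaceArea(detectCavities(m1$grid, sh$structure,
                                     mesh = m1$mesh)[[1]])
    a2 <- surfaceArea(detectCavities(m2$grid, shifted,
                                     mesh = m2$mesh)[[1]])
    expect_lt(abs(a1 - a2) / a1, 0.02)
})

test_that("residue assignment equals the brute-force nearest-atom scan", {
    op <- makeOpenPocket(radius = 6, atomSpacing = 2.2)
    ms <- computeMolecularSurface(op$structure, spacing = 0.6, margin = 9)
    cavs <- detectCavities(ms$grid, op$structure, envelopeProbe = 7,
                           mesh = ms$mesh)
    expect_gte(length(cavs), 1)
    cv <- cavs[[1]]
    a <- atomTable(op$structure)
    cen <- CavityRigidity:::triangleCentroids(cv@mesh)
    near <- apply(cen, 1, function(p)
        a$atom_id[which.min((a$x - p[1])^2 + (a$y - p[2])^2 +
                            (a$z - p[3])^2)])
    expect_setequal(cavityAtoms(cv), unique(near))
    keys <- unique(paste0(a$resno, ":")[match(sort(unique(near)),
                                              a$atom_id)])
    expect_setequal(cavityResidues(cv), keys)
})

test_that("SURF files round-trip with identical bytes and area", {
    tri <- new("SurfaceMesh",
               vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               triangles = matrix(1:3, 1), triCell = 0L)
    p <- withr::local_tempfile(fileext = ".surf")
    writeSurf(tri, p)
    lines <- readLines(p)
    expect_equal(lines[1], "SURF 3 1")
    expect_length(lines, 5)
    back <- readSurf(p)
    expect_equal(meshArea(back), meshArea(tri), tolerance = 1e-6)
    p2 <- withr::local_tempfile(fileext = ".surf")
    writeSurf(back, p2)
    expect_identical(readLines(p), readLines(p2))

    empty <- new("SurfaceMesh", vertices = matrix(numeric(), 0, 3),
                 triangles = matrix(integer(), 0, 3),
                 triCell = integer())
    expect_error(writeSurf(empty, withr::local_tempfile()), "empty mesh")
})

test_that("cavity invariants hold on the shell fixture", {
    sh <- makeHollowShell(8, 1.5)
    ms <- computeMolecularSurface(sh$structure, spacing = 0.5)
    cavs <- detectCavities(ms$grid, sh$structure, mesh = ms$mesh)
    a <- atomTable(sh$structure)
    for (cv in cavs) {
        expect_true(all(cavityAtoms(cv) %in% a$atom_id))
        expect_equal(surfaceArea(cv), meshArea(cv@mesh),
                     tolerance = 1e-6)
    }
})
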