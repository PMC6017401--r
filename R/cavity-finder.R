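# Volumetric cavity detection.  The solvent-excluded surface (SES) is the
# morphological closure of the van der Waals union by the probe sphere:
# dilate the atom spheres by the probe, then erode by the probe.  Both
# steps run on a signed voxel field built from (a) the analytic
# distance-to-vdW field and (b) an exact Euclidean distance transform of
# the probe-centre region, with a sub-voxel seed correction so contact
# surfaces sit on the atom spheres to second order in the grid spacing.
# Surface cavities (pockets) are non-protein voxels enclosed by the same
# closure computed with a large envelope probe; interior voids are
# non-protein voxels unreachable from the bulk solvent.

.resolveRadii <- function(structure, radii = NULL) {
    el <- structure@atoms$element
    if (is.null(radii)) return(vdwRadius(el))
    if (!is.null(names(radii))) {
        r <- unname(radii[el])
        miss <- is.na(r)
        if (any(miss)) r[miss] <- vdwRadius(el[miss])
        return(r)
    }
    if (length(radii) == 1) return(rep(radii, length(el)))
    stopifnot(length(radii) == length(el))
    radii
}

# signed SES field at `probe` from the capped distance-to-vdW field:
# positive inside the protein, zero on the molecular surface.
.sesField <- function(atomField, dims, spacing, probe) {
    # zero probe degenerates to the union-of-vdW-spheres boundary, for
    # which the atom field itself is the (negated) signed field
    if (probe <= 0) return(-atomField)
    P <- atomField >= probe
    if (!any(P))
        stop("grid too small: no solvent voxels at probe ", probe)
    if (all(P)) return(-atomField)
    # boundary voxels of the probe-centre region seed the distance
    # transform; their residual clearance (atomField - probe) corrects the
    # voxel-centre bias of the transform.
    arr <- array(P, dims)
    inner <- array(FALSE, dims)
    n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
    shift_has_false <- array(FALSE, dims)
    for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
            idx <- list(seq_len(n1), seq_len(n2), seq_len(n3))
            src <- idx
            src[[ax]] <- pmin(pmax(idx[[ax]] + dir, 1L), dims[ax])
            nb <- arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
            shift_has_false <- shift_has_false | !nb
        }
    }
    seeds <- arr & shift_has_false
    edt <- cpp_edt_sites(as.logical(seeds), dims, spacing)
    offset <- atomField[edt$site + 1L] - probe
    dcorr <- pmax(0, edt$dist - offset)
    ifelse(P, -atomField, dcorr - probe)
}

#' Compute the solvent-excluded molecular surface on a voxel grid
#'
#' Builds the signed SES field for a probe rolled over the atoms'
#' van der Waals spheres and triangulates the zero level with marching
#' tetrahedra.  \code{probe = 0} degenerates to the union-of-vdW-spheres
#' boundary.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param probe probe radius, angstrom (default 1.4, a water molecule).
#' @param spacing voxel edge, angstrom (default 0.5; use 0.2 for
#'   high-accuracy areas).
#' @param margin grid padding beyond the atoms, angstrom; must exceed the
#'   largest probe later applied to the grid (default 10, enough for the
#'   default 8 A cavity envelope).
#' @param radii vdW radii override: a named per-element vector, a single
#'   number, or one value per atom.  Defaults to the internal table
#'   (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8).
#' @param maxVoxels guard against runaway grids (error \code{"grid too
#'   large"}).
#' @return list with elements \code{grid}
#'   (\code{\linkS4class{VolumetricGrid}}) and \code{mesh}
#'   (\code{\linkS4class{SurfaceMesh}}).
#' @export
computeMolecularSurface <- function(structure, probe = 1.4, spacing = 0.5,
                                    margin = 10, radii = NULL,
                                    maxVoxels = 4e7) {
    stopifnot(is(structure, "ChainStructure"))
    if (spacing <= 0) stop("spacing must be positive")
    if (probe < 0) stop("probe must be non-negative")
    a <- structure@atoms
    r <- .resolveRadii(structure, radii)
    lo <- c(min(a$x), min(a$y), min(a$z)) - max(r) - margin
    hi <- c(max(a$x), max(a$y), max(a$z)) + max(r) + margin
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    if (prod(as.numeric(dims)) > maxVoxels)
        stop("grid too large: ", paste(dims, collapse = " x "),
             " voxels exceeds maxVoxels")
    cap <- margin
    af <- cpp_atom_field(dims, lo, spacing,
                         as.matrix(a[, c("x", "y", "z")]), r, cap)
    F <- .sesField(af, dims, spacing, probe)
    mt <- cpp_march_tet(F, dims, lo, spacing, 0)
    mesh <- .makeMesh(mt)
    grid <- new("VolumetricGrid", origin = lo, spacing = spacing,
                dims = dims, field = array(F, dims),
                atomField = array(af, dims), probe = probe, cap = cap)
    list(grid = grid, mesh = mesh)
}

.makeMesh <- function(mt) {
    v <- mt$vertices
    tr <- mt$triangles
    cell <- mt$cell
    if (nrow(tr)) {
        # drop numerically degenerate (zero-area) triangles
        a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
        b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
        ar <- sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                   (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                   (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2) / 2
        keep <- ar > 1e-8
        tr <- tr[keep, , drop = FALSE]
        cell <- cell[keep]
    }
    new("SurfaceMesh", vertices = v,
        triangles = matrix(as.integer(tr), ncol = 3),
        triCell = as.integer(cell))
}

#' Detect surface pockets and interior voids
#'
#' Pocket voxels lie outside the protein but inside the envelope (the
#' same probe closure computed with \code{envelopeProbe}); interior voids
#' are non-protein voxels unreachable from the bulk solvent.  Each
#' 26-connected component becomes a candidate cavity whose surface is the
#' protein-facing part of the molecular surface; candidates shallower
#' than half a voxel (discretisation skin) and those below \code{minArea}
#' are dropped.  Cavities are returned in descending surface-area order
#' with lining atoms and residues assigned by nearest atom.
#'
#' @param grid \code{\linkS4class{VolumetricGrid}} from
#'   \code{\link{computeMolecularSurface}}.
#' @param structure the \code{\linkS4class{ChainStructure}} the grid was
#'   built from.
#' @param envelopeProbe envelope probe radius, angstrom (default 8).
#' @param minArea minimum cavity surface area, square angstrom (default
#'   50); the unfiltered candidate table is attached as attribute
#'   \code{"allCavities"}.
#' @param mesh molecular-surface mesh (recomputed when NULL).
#' @return list of \code{\linkS4class{Cavity}} objects.
#' @export
detectCavities <- function(grid, structure, envelopeProbe = 8,
                           minArea = 50, mesh = NULL) {
    stopifnot(is(grid, "VolumetricGrid"))
    dims <- grid@dims
    spacing <- grid@spacing
    if (envelopeProbe + 2 * spacing > grid@cap)
        stop("grid margin too small for envelope probe ", envelopeProbe)
    F <- as.vector(grid@field)
    Fenv <- .sesField(as.vector(grid@atomField), dims, spacing,
                      envelopeProbe)
    if (is.null(mesh)) {
        mt <- cpp_march_tet(F, dims, grid@origin, spacing, 0)
        mesh <- .makeMesh(mt)
    }
    cavityMask <- (F < 0) & (Fenv > 0)
    labels <- cpp_components(cavityMask, dims, 26L)
    open <- F < 0
    reached <- cpp_flood_boundary(open, dims, 6L)

    emptyOut <- list()
    attr(emptyOut, "allCavities") <- data.frame(
        component = integer(), kind = character(), area = numeric(),
        depth = numeric(), kept = logical())
    ncomp <- max(labels)
    if (ncomp == 0 || nrow(mesh@triangles) == 0) return(emptyOut)

    # assign every surface triangle to the cavity component of the
    # deepest cavity-side corner of its generating cube
    corner_off <- c(0L, 1L, dims[1], dims[1] + 1L,
                    dims[1] * dims[2], dims[1] * dims[2] + 1L,
                    dims[1] * dims[2] + dims[1],
                    dims[1] * dims[2] + dims[1] + 1L)
    cube <- mesh@triCell
    corn <- outer(cube, corner_off, `+`)
    labs8 <- matrix(labels[corn], nrow = length(cube))
    f8 <- matrix(F[corn], nrow = length(cube))
    f8[labs8 == 0] <- Inf
    pick <- max.col(-f8, ties.method = "first")
    triLabel <- labs8[cbind(seq_along(cube), pick)]
    triLabel[!is.finite(f8[cbind(seq_along(cube), pick)])] <- 0L

    info <- lapply(seq_len(ncomp), function(cc) {
        vox <- which(labels == cc)
        depth <- max(-F[vox])
        kind <- if (any(reached[vox])) "pocket" else "void"
        tri <- which(triLabel == cc)
        list(vox = vox, depth = depth, kind = kind, tri = tri)
    })
    areas <- vapply(info, function(x) {
        if (!length(x$tri)) return(0)
        sub <- .subMesh(mesh, x$tri)
        meshArea(sub)
    }, numeric(1))
    depths <- vapply(info, `[[`, numeric(1), "depth")
    kinds <- vapply(info, `[[`, character(1), "kind")
    kept <- depths >= 0.5 * spacing & areas >= minArea
    all_tab <- data.frame(component = seq_len(ncomp), kind = kinds,
                          area = areas, depth = depths, kept = kept)

    sel <- which(kept)
    sel <- sel[order(-areas[sel])]
    out <- vector("list", length(sel))
    for (k in seq_along(sel)) {
        cc <- sel[k]
        sub <- .subMesh(mesh, info[[cc]]$tri)
        cav <- new("Cavity", cavityId = k, mesh = sub,
                   surfaceArea = meshArea(sub), atomIds = integer(),
                   residueKeys = character(), kind = kinds[cc])
        out[[k]] <- assignCavityResidues(cav, structure)
    }
    attr(out, "allCavities") <- all_tab
    out
}

.subMesh <- function(mesh, triIdx) {
    tr <- mesh@triangles[triIdx, , drop = FALSE]
    used <- sort(unique(as.vector(tr)))
    remap <- match(as.vector(tr), used)
    new("SurfaceMesh",
        vertices = mesh@vertices[used, , drop = FALSE],
        triangles = matrix(as.integer(remap), ncol = 3),
        triCell = mesh@triCell[triIdx])
}

#' Assign lining atoms and residues to a cavity
#'
#' For every surface triangle the atom nearest its centroid is a lining
#' atom; the cavity's residues are the lining atoms' residues,
#' de-duplicated and ordered by sequence.
#'
#' @param cavity a \code{\linkS4class{Cavity}} with a non-empty mesh.
#' @param structure the parent \code{\linkS4class{ChainStructure}}.
#' @return the cavity with \code{atomIds} and \code{residueKeys} filled.
#' @export
assignCavityResidues <- function(cavity, structure) {
    stopifnot(is(cavity, "Cavity"))
    if (nrow(cavity@mesh@triangles) == 0)
        stop("cavity mesh is empty")
    a <- structure@atoms
    cen <- triangleCentroids(cavity@mesh)
    nearest <- cpp_nearest_point(cen, as.matrix(a[, c("x", "y", "z")]))
    ids <- sort(unique(a$atom_id[nearest]))
    keys <- unique(resKey(a$resno, a$icode)[match(ids, a$atom_id)])
    cavity@atomIds <- as.integer(ids)
    cavity@residueKeys <- orderResKeys(keys)
    cavity
}

#' Write a cavity mesh as SURF text (and optionally OBJ)
#'
#' Plain-text mesh format: a header line \code{SURF <n_vertices>
#' <n_triangles>}, one \code{x y z} line per vertex, then one zero-based
#' \code{i j k} line per triangle.
#'
#' @param cavity a \code{\linkS4class{Cavity}} (or bare
#'   \code{\linkS4class{SurfaceMesh}}).
#' @param path SURF output file.
#' @param objPath optional Wavefront OBJ export for visualisation.
#' @export
writeSurf <- function(cavity, path, objPath = NULL) {
    mesh <- if (is(cavity, "Cavity")) cavity@mesh else cavity
    if (nrow(mesh@triangles) == 0) stop("empty mesh: nothing to write")
    v <- mesh@vertices
    tr <- mesh@triangles
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(sprintf("SURF %d %d", nrow(v), nrow(tr)),
                 sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
                 sprintf("%d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                         tr[, 3] - 1L)), con)
    if (!is.null(objPath)) {
        oc <- file(objPath, "wb")
        writeLines(c(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]),
                     sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3])), oc)
        close(oc)
    }
    invisible(path)
}

#' Read a SURF text mesh
#'
#' @param path file written by \code{\link{writeSurf}}.
#' @return a \code{\linkS4class{SurfaceMesh}}.
#' @export
readSurf <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- strsplit(lines[1], " +")[[1]]
    if (hdr[1] != "SURF") stop("not a SURF file: ", path)
    nv <- as.integer(hdr[2]); nt <- as.integer(hdr[3])
    v <- matrix(as.numeric(unlist(strsplit(lines[2:(1 + nv)], " +"))),
                ncol = 3, byrow = TRUE)
    tr <- matrix(as.integer(unlist(strsplit(
        lines[(2 + nv):(1 + nv + nt)], " +"))), ncol = 3,
        byrow = TRUE) + 1L
    new("SurfaceMesh", vertices = v, triangles = tr,
        triCell = rep(0L, nt))
}
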