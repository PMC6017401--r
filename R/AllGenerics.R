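#' @rdname ChainStructure-class
#' @param object,x a package object.
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname ChainStructure-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ChainStructure-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname ChainStructure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname MechanicalModel-class
#' @param x a \code{MechanicalModel}.
#' @export
setGeneric("bodies", function(x) standardGeneric("bodies"))

#' @rdname MechanicalModel-class
#' @export
setGeneric("constraints", function(x) standardGeneric("constraints"))

#' @rdname RigidClusterDecomposition-class
#' @param x a \code{RigidClusterDecomposition}.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname RigidClusterDecomposition-class
#' @export
setGeneric("totalFreeDof", function(x) standardGeneric("totalFreeDof"))

#' @rdname Cavity-class
#' @param x a \code{Cavity}.
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' @rdname Cavity-class
#' @export
setGeneric("cavityAtoms", function(x) standardGeneric("cavityAtoms"))

#' @rdname Cavity-class
#' @export
setGeneric("cavityResidues", function(x) standardGeneric("cavityResidues"))

#' @rdname EtScoreTable-class
#' @param x an \code{EtScoreTable}.
#' @export
setGeneric("etScores", function(x) standardGeneric("etScores"))

#' @rdname EtScoreTable-class
#' @export
setGeneric("etCoverage", function(x) standardGeneric("etCoverage"))

#' @describeIn ChainStructure-class chain identifier.
#' @export
setMethod("chainId", "ChainStructure", function(x) x@chainId)

#' @describeIn ChainStructure-class the atom table.
#' @export
setMethod("atomTable", "ChainStructure", function(x) x@atoms)

#' @describeIn ChainStructure-class one row per residue, key-ordered, with
#'   its atom ids as a list column.
#' @export
setMethod("residueTable", "ChainStructure", function(x) {
    a <- x@atoms
    key <- resKey(a$resno, a$icode)
    split_ids <- split(a$atom_id, key)
    ord <- orderResKeys(names(split_ids))
    first <- a[!duplicated(key), , drop = FALSE]
    rownames(first) <- resKey(first$resno, first$icode)
    data.frame(residue_key = ord,
               resno = first[ord, "resno"],
               icode = first[ord, "icode"],
               resid = first[ord, "resid"],
               atom_ids = I(unname(split_ids[ord])),
               row.names = NULL, stringsAsFactors = FALSE)
})

#' @describeIn ChainStructure-class number of atoms.
#' @export
setMethod("nAtoms", "ChainStructure", function(x) nrow(x@atoms))

setMethod("show", "ChainStructure", function(object) {
    rt <- residueTable(object)
    cat("ChainStructure", object@sourceLabel, "chain", object@chainId, "\n")
    cat(" ", nrow(object@atoms), "atoms,", nrow(rt), "residues\n")
})

#' @describeIn MechanicalModel-class list of body atom sets.
#' @export
setMethod("bodies", "MechanicalModel", function(x) x@bodies)

#' @describeIn MechanicalModel-class the constraint multiset.
#' @export
setMethod("constraints", "MechanicalModel", function(x) x@constraints)

setMethod("show", "MechanicalModel", function(object) {
    cs <- object@constraints
    cat("MechanicalModel:", length(object@bodies), "bodies,",
        nrow(cs), "constraints (", sum(cs$bars), "bars )\n")
    if (nrow(cs)) print(table(cs$kind))
})

setMethod("show", "BodyBarGraph", function(object) {
    cat("BodyBarGraph:", object@nNodes, "nodes,", nrow(object@edges),
        "bars\n")
})

#' @describeIn RigidClusterDecomposition-class a data.frame with one row
#'   per cluster: \code{cluster_id}, \code{n_bodies}, \code{n_atoms}, plus
#'   list columns \code{body_ids} and \code{atom_ids}.
#' @export
setMethod("clusters", "RigidClusterDecomposition", function(x) {
    data.frame(cluster_id = x@clusterIds,
               n_bodies = vapply(x@clusterBodies, length, 1L),
               n_atoms = if (length(x@clusterAtoms))
                   vapply(x@clusterAtoms, length, 1L) else NA_integer_,
               body_ids = I(x@clusterBodies),
               atom_ids = I(if (length(x@clusterAtoms)) x@clusterAtoms
                            else vector("list", length(x@clusterIds))),
               row.names = NULL)
})

#' @describeIn RigidClusterDecomposition-class total free degrees of
#'   freedom (6 per body minus independent bars).
#' @export
setMethod("totalFreeDof", "RigidClusterDecomposition",
          function(x) x@totalFreeDof)

setMethod("show", "RigidClusterDecomposition", function(object) {
    cat("RigidClusterDecomposition:", length(object@clusterIds),
        "rigid clusters over", object@nBodies, "bodies; total free DOF",
        object@totalFreeDof, "\n")
})

setMethod("show", "VolumetricGrid", function(object) {
    cat("VolumetricGrid:", paste(object@dims, collapse = " x "),
        "voxels at", object@spacing, "A; probe", object@probe, "A\n")
})

setMethod("show", "SurfaceMesh", function(object) {
    cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
        nrow(object@triangles), "triangles; area",
        format(meshArea(object), digits = 6), "A^2\n")
})

#' @describeIn Cavity-class surface area in square angstrom.
#' @export
setMethod("surfaceArea", "Cavity", function(x) x@surfaceArea)

#' @describeIn Cavity-class ids of the atoms lining the cavity.
#' @export
setMethod("cavityAtoms", "Cavity", function(x) x@atomIds)

#' @describeIn Cavity-class residue keys of the lining atoms.
#' @export
setMethod("cavityResidues", "Cavity", function(x) x@residueKeys)

setMethod("show", "Cavity", function(object) {
    cat("Cavity", object@cavityId, "(", object@kind, "): area",
        format(object@surfaceArea, digits = 6), "A^2,",
        length(object@atomIds), "lining atoms,",
        length(object@residueKeys), "residues\n")
})

#' @describeIn EtScoreTable-class named score vector.
#' @export
setMethod("etScores", "EtScoreTable", function(x) x@scores)

#' @describeIn EtScoreTable-class fraction of chain residues scored.
#' @export
setMethod("etCoverage", "EtScoreTable", function(x) x@coverage)

setMethod("show", "EtScoreTable", function(object) {
    cat("EtScoreTable: chain", object@chainId, "-",
        length(object@scores), "scored residues; coverage",
        format(object@coverage, digits = 4), "\n")
})
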