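#' @useDynLib CavityRigidity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor median nls coef fitted predict quantile rnorm runif
#'   rnbinom sd setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Protein chain structure
#'
#' One protein chain held as an atom table with validated identifiers.
#' Residue keys combine the residue sequence number and insertion code
#' (\code{"<resno>:<icode>"}), so chains with insertion codes keep their
#' ordering \code{(resno, icode)}.
#'
#' @slot chainId single-character chain identifier.
#' @slot sourceLabel free-text provenance label, e.g. \code{"3e3xA"}.
#' @slot atoms \code{data.frame} with columns \code{atom_id} (PDB serial,
#'   unique), \code{name}, \code{element}, \code{resno}, \code{icode},
#'   \code{resid} (3-letter residue name), \code{x}, \code{y}, \code{z}
#'   (angstrom), \code{occupancy}, \code{alt}.
#' @export
setClass("ChainStructure",
    representation(chainId = "character", sourceLabel = "character",
                   atoms = "data.frame"))

setValidity("ChainStructure", function(object) {
    a <- object@atoms
    need <- c("atom_id", "name", "element", "resno", "icode", "resid",
              "x", "y", "z", "occupancy", "alt")
    if (!all(need %in% names(a)))
        return(paste("atoms table missing columns:",
                     paste(setdiff(need, names(a)), collapse = ", ")))
    if (nrow(a) == 0) return("empty structure")
    if (anyDuplicated(a$atom_id)) return("duplicate atom ids")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        return("non-finite atom coordinates")
    if (any(a$occupancy < 0 | a$occupancy > 1, na.rm = TRUE))
        return("occupancy outside [0,1]")
    TRUE
})

#' Body-bar mechanical model
#'
#' Rigid bodies (atom sets, merged over locked covalent bonds) joined by
#' counted bar constraints.  A hinge (rotatable covalent bond) is 5 bars
#' and shares its two endpoint atoms between both bodies.
#'
#' @slot bodies list of integer atom-id vectors; body ids are list
#'   positions (1-based).
#' @slot constraints \code{data.frame} with columns \code{body_u},
#'   \code{body_v}, \code{bars}, \code{kind}, \code{atom_a}, \code{atom_b},
#'   \code{distance}; one row per bond-derived constraint (multiset).
#' @export
setClass("MechanicalModel",
    representation(bodies = "list", constraints = "data.frame"))

setValidity("MechanicalModel", function(object) {
    if (length(object@bodies) == 0) return("no bodies")
    if (any(vapply(object@bodies, length, 1L) == 0))
        return("empty body atom set")
    cs <- object@constraints
    if (nrow(cs)) {
        if (any(cs$body_u == cs$body_v)) return("self-constraint")
        nb <- length(object@bodies)
        if (any(cs$body_u < 1 | cs$body_u > nb |
                cs$body_v < 1 | cs$body_v > nb))
            return("constraint endpoint is not a body id")
        if (any(cs$bars < 1 | cs$bars > 6))
            return("invalid bar count")
        if (any(cs$bars[cs$kind == "covalent_rotatable"] != 5))
            return("hinge constraint without exactly 5 bars")
    }
    TRUE
})

#' Body-bar multigraph
#'
#' The graph handed to the pebble game: one node per rigid body, one edge
#' per bar.
#'
#' @slot nNodes number of nodes.
#' @slot edges integer matrix with columns \code{u}, \code{v} (1-based
#'   node ids), one row per bar; no self-loops.
#' @export
setClass("BodyBarGraph",
    representation(nNodes = "integer", edges = "matrix"))

setValidity("BodyBarGraph", function(object) {
    if (object@nNodes < 1) return("need at least one node")
    e <- object@edges
    if (nrow(e)) {
        if (ncol(e) != 2) return("edges must have two columns")
        if (any(e < 1 | e > object@nNodes)) return("edge endpoint out of range")
        if (any(e[, 1] == e[, 2])) return("invalid graph: self-loop")
    }
    TRUE
})

#' Rigid-cluster decomposition
#'
#' Output of the (6,6) pebble game: a partition of the bodies into maximal
#' rigid components, with degree-of-freedom bookkeeping.  Cluster ids are
#' 0-based to match the XML interchange format.
#'
#' @slot clusterIds integer cluster ids (0-based).
#' @slot clusterBodies list (parallel to \code{clusterIds}) of member body
#'   ids.
#' @slot clusterAtoms list of member atom-id vectors; empty until
#'   \code{\link{clustersToAtoms}} is applied.
#' @slot nBodies number of bodies in the analysed graph.
#' @slot totalFreeDof total unconstrained degrees of freedom,
#'   \eqn{6 n - }(independent bars).
#' @export
setClass("RigidClusterDecomposition",
    representation(clusterIds = "integer", clusterBodies = "list",
                   clusterAtoms = "list", nBodies = "integer",
                   totalFreeDof = "integer"))

setValidity("RigidClusterDecomposition", function(object) {
    if (length(object@clusterIds) != length(object@clusterBodies))
        return("cluster ids and body lists differ in length")
    bodies <- unlist(object@clusterBodies)
    if (length(bodies) &&
        !setequal(bodies, seq_len(object@nBodies)))
        return("clusters must cover every body exactly once")
    if (length(bodies) && anyDuplicated(bodies))
        return("body assigned to two clusters")
    TRUE
})

#' Volumetric surface grid
#'
#' Regular grid holding the signed solvent-excluded-surface field
#' (\code{field > 0} inside the protein) and the raw distance-to-van-der-
#' Waals field used to derive probe closures at other radii.
#'
#' @slot origin coordinates of voxel (1,1,1), angstrom.
#' @slot spacing voxel edge length, angstrom.
#' @slot dims integer grid dimensions.
#' @slot field numeric array: signed SES field at the construction probe.
#' @slot atomField numeric array: min over atoms of
#'   (distance - vdW radius), capped at \code{cap}.
#' @slot probe probe radius used for \code{field}, angstrom.
#' @slot cap cap applied to \code{atomField}, angstrom.
#' @export
setClass("VolumetricGrid",
    representation(origin = "numeric", spacing = "numeric",
                   dims = "integer", field = "array", atomField = "array",
                   probe = "numeric", cap = "numeric"))

setValidity("VolumetricGrid", function(object) {
    if (object@spacing <= 0) return("spacing must be positive")
    if (length(object@dims) != 3) return("dims must have length 3")
    TRUE
})

#' Triangulated surface mesh
#'
#' @slot vertices numeric matrix (n x 3), angstrom.
#' @slot triangles integer matrix (m x 3) of 1-based vertex indices.
#' @slot triCell integer vector: linear index of the grid cube each
#'   triangle came from (0 when not grid-derived).
#' @export
setClass("SurfaceMesh",
    representation(vertices = "matrix", triangles = "matrix",
                   triCell = "integer"))

setValidity("SurfaceMesh", function(object) {
    tr <- object@triangles
    if (nrow(tr) && (any(tr < 1) || any(tr > nrow(object@vertices))))
        return("triangle vertex index out of range")
    TRUE
})

#' Surface cavity or interior void
#'
#' A connected empty region indented into (pocket) or enclosed by (void)
#' the molecular surface, carried with its protein-facing triangulated
#' surface patch.
#'
#' @slot cavityId integer id (1-based, assigned in descending area order).
#' @slot mesh \code{\linkS4class{SurfaceMesh}} of the protein-facing
#'   boundary.
#' @slot surfaceArea sum of triangle areas, square angstrom.
#' @slot atomIds atoms lining the cavity (nearest atom of some triangle).
#' @slot residueKeys residue keys of the lining atoms, sequence-ordered.
#' @slot kind \code{"pocket"} or \code{"void"}.
#' @export
setClass("Cavity",
    representation(cavityId = "integer", mesh = "SurfaceMesh",
                   surfaceArea = "numeric", atomIds = "integer",
                   residueKeys = "character", kind = "character"))

setValidity("Cavity", function(object) {
    if (object@surfaceArea < 0) return("negative surface area")
    if (nrow(object@mesh@triangles)) {
        a <- meshArea(object@mesh)
        if (a > 0 && abs(a - object@surfaceArea) > 1e-6 * max(a, 1))
            return("surfaceArea does not equal the sum of triangle areas")
    }
    TRUE
})

#' Evolutionary-trace score table
#'
#' Per-residue real-value evolutionary-trace (rvet) conservation scores
#' for one chain, keyed by residue key.
#'
#' @slot chainId chain the scores belong to.
#' @slot scores named numeric vector; names are residue keys
#'   (\code{"<resno>:<icode>"}).
#' @slot coverage fraction of chain residues scored (\code{NA} when the
#'   chain residue count is unknown).
#' @export
setClass("EtScoreTable",
    representation(chainId = "character", scores = "numeric",
                   coverage = "numeric"))

setValidity("EtScoreTable", function(object) {
    if (length(object@scores) && !all(is.finite(object@scores)))
        return("non-finite rvet score")
    if (!is.na(object@coverage) &&
        (object@coverage < 0 || object@coverage > 1))
        return("coverage outside [0,1]")
    TRUE
})
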