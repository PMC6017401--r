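# Rigid-cluster decomposition of the body-bar multigraph via the (6,6)
# pebble game, and the XML interchange format for cluster/atom membership
# (body elements holding point elements whose ids are PDB atom serials).

#' Build the body-bar multigraph of a mechanical model
#'
#' One node per rigid body; each constraint contributes \code{bars}
#' parallel edges.  Edges are stored sorted by (u, v) with u < v so the
#' pebble game sees a canonical insertion order.
#'
#' @param model a \code{\linkS4class{MechanicalModel}}, or a data.frame
#'   with columns \code{body_u}, \code{body_v}, \code{bars}.
#' @param nNodes node count (inferred from the model when missing).
#' @return a \code{\linkS4class{BodyBarGraph}}.
#' @export
bodyBarGraph <- function(model, nNodes = NULL) {
    if (is(model, "MechanicalModel")) {
        cs <- model@constraints
        if (is.null(nNodes)) nNodes <- length(model@bodies)
    } else {
        cs <- model
        if (is.null(nNodes)) nNodes <- max(cs$body_u, cs$body_v, 1L)
    }
    if (nrow(cs)) {
        u <- pmin(cs$body_u, cs$body_v)
        v <- pmax(cs$body_u, cs$body_v)
        e <- cbind(u = rep(u, cs$bars), v = rep(v, cs$bars))
        e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    } else {
        e <- cbind(u = integer(), v = integer())
    }
    new("BodyBarGraph", nNodes = as.integer(nNodes),
        edges = matrix(as.integer(e), ncol = 2,
                       dimnames = list(NULL, c("u", "v"))))
}

#' Decompose a body-bar graph into rigid clusters
#'
#' Runs the (6,6) pebble game: every node (a 3D rigid body) starts with 6
#' pebbles; a bar is independent iff 7 pebbles can be gathered on its
#' endpoints before it is covered.  Rigid clusters are the maximal body
#' sets with zero internal degrees of freedom; for body-bar frameworks
#' they partition the bodies.  Deterministic: edges are inserted in
#' sorted (u, v) order and searches use sorted neighbour order.
#'
#' @param graph a \code{\linkS4class{BodyBarGraph}}.
#' @return a \code{\linkS4class{RigidClusterDecomposition}} with 0-based
#'   cluster ids ordered by smallest member body.
#' @export
pebbleGameDecompose <- function(graph) {
    stopifnot(is(graph, "BodyBarGraph"))
    validObject(graph)
    n <- graph@nNodes
    res <- cpp_pebble_game(n, graph@edges)
    labs <- res$clusterLabels
    mem <- split(seq_len(n), labs)
    mem <- mem[order(as.integer(names(mem)))]
    new("RigidClusterDecomposition",
        clusterIds = seq_along(mem) - 1L,
        clusterBodies = unname(mem),
        clusterAtoms = list(),
        nBodies = as.integer(n),
        totalFreeDof = as.integer(res$totalFreeDof))
}

#' Remaining degrees of freedom between two bodies
#'
#' The relative DOF left between nodes u and v after all constraints:
#' the number of pebbles collectible on the pair beyond the 6 trivial
#' ones, in [0, 6].  Disconnected bodies have 6; hinge-joined bodies 1;
#' bodies of one rigid cluster 0.
#'
#' @param graph a \code{\linkS4class{BodyBarGraph}}.
#' @param u,v node ids.
#' @return integer in [0, 6].
#' @export
dofBetween <- function(graph, u, v) {
    stopifnot(is(graph, "BodyBarGraph"))
    if (u < 1 || u > graph@nNodes || v < 1 || v > graph@nNodes)
        stop("unknown node")
    cpp_pebble_dof(graph@nNodes, graph@edges, as.integer(u),
                   as.integer(v))
}

#' Expand rigid clusters from bodies to atoms
#'
#' Each cluster's atom set is the union of its member bodies' atom sets;
#' hinge endpoint atoms (members of two bodies) may appear in two
#' clusters.
#'
#' @param decomp a \code{\linkS4class{RigidClusterDecomposition}} from the
#'   graph of \code{model}.
#' @param model the \code{\linkS4class{MechanicalModel}} that produced it.
#' @return the decomposition with \code{clusterAtoms} filled.
#' @export
clustersToAtoms <- function(decomp, model) {
    stopifnot(is(decomp, "RigidClusterDecomposition"),
              is(model, "MechanicalModel"))
    if (decomp@nBodies != length(model@bodies))
        stop("id mismatch: decomposition and model disagree on body count")
    decomp@clusterAtoms <- lapply(decomp@clusterBodies, function(bs)
        sort(unique(unlist(model@bodies[bs]))))
    decomp
}

#' Write a rigid-cluster decomposition as XML
#'
#' One \code{body} element per rigid cluster (attribute \code{id}), each
#' holding \code{point} elements whose \code{id} attributes are the PDB
#' atom serials of the cluster members.  Output ordering is stable:
#' clusters by id, points by atom id.
#'
#' @param decomp a \code{\linkS4class{RigidClusterDecomposition}} with
#'   atoms filled (see \code{\link{clustersToAtoms}}), or a list of
#'   \code{list(body_id, atom_ids)}.
#' @param path output file.
#' @export
writeClusterXml <- function(decomp, path) {
    if (is(decomp, "RigidClusterDecomposition")) {
        if (!length(decomp@clusterAtoms) && length(decomp@clusterIds))
            stop("decomposition has no atom sets; run clustersToAtoms first")
        items <- Map(function(id, at) list(body_id = id, atom_ids = at),
                     decomp@clusterIds, decomp@clusterAtoms)
    } else items <- decomp
    doc <- xml2::xml_new_root("rigidClusters")
    for (it in items) {
        body <- xml2::xml_add_child(doc, "body", id = as.character(it$body_id))
        for (aid in sort(it$atom_ids))
            xml2::xml_add_child(body, "point", id = as.character(aid))
    }
    xml2::write_xml(doc, path)
    invisible(path)
}

#' Read a rigid-cluster XML file
#'
#' @param path XML file written by \code{\link{writeClusterXml}} (or any
#'   file following the body/point schema).
#' @return list of \code{list(body_id, atom_ids)}, ordered as in the file.
#' @export
readClusterXml <- function(path) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        stop("XML parse error in ", path, ": ", conditionMessage(e),
             call. = FALSE))
    bodies <- xml2::xml_find_all(doc, ".//body")
    lapply(bodies, function(b) {
        pts <- xml2::xml_find_all(b, "./point")
        list(body_id = as.integer(xml2::xml_attr(b, "id")),
             atom_ids = as.integer(xml2::xml_attr(pts, "id")))
    })
}
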