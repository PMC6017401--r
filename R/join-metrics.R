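# Association of cavities with rigid clusters by shared atom ids, and the
# per-cavity / per-cluster survey records behind the correlation analyses.

# normalise cavity input to list(cavity_id, atom_ids, residue_keys, area)
.cavList <- function(cavities) {
    lapply(cavities, function(cv) {
        if (is(cv, "Cavity"))
            list(cavity_id = cv@cavityId, atom_ids = cv@atomIds,
                 residue_keys = cv@residueKeys, area = cv@surfaceArea)
        else
            list(cavity_id = cv$cavity_id, atom_ids = cv$atom_ids,
                 residue_keys = if (is.null(cv$residue_keys)) character()
                                else cv$residue_keys,
                 area = if (is.null(cv$area)) cv$surface_area else cv$area)
    })
}

# normalise cluster input to list(cluster_id, atom_ids)
.cluList <- function(clusters) {
    if (is(clusters, "RigidClusterDecomposition")) {
        if (!length(clusters@clusterAtoms))
            stop("decomposition has no atom sets; run clustersToAtoms first")
        return(Map(function(id, at) list(cluster_id = id, atom_ids = at),
                   clusters@clusterIds, clusters@clusterAtoms))
    }
    lapply(clusters, function(cl)
        list(cluster_id = cl$cluster_id, atom_ids = cl$atom_ids))
}

#' Associate cavities with rigid clusters through shared atoms
#'
#' A cavity participates with a rigid cluster iff their atom sets share
#' at least \code{minSharedAtoms} atoms (atom ids are PDB serials of one
#' chain).
#'
#' @param cavities list of \code{\linkS4class{Cavity}} objects (or plain
#'   lists with \code{cavity_id}, \code{atom_ids}).
#' @param clusters a \code{\linkS4class{RigidClusterDecomposition}} with
#'   atoms, or a list of \code{list(cluster_id, atom_ids)}.
#' @param minSharedAtoms participation threshold (default 1).
#' @return data.frame with columns \code{cavity_id}, \code{cluster_id},
#'   \code{shared} (intersection size); one row per participating pair.
#' @export
associateCavities <- function(cavities, clusters, minSharedAtoms = 1) {
    cavs <- .cavList(cavities)
    clus <- .cluList(clusters)
    rows <- list()
    for (cv in cavs)
        for (cl in clus) {
            s <- length(intersect(cv$atom_ids, cl$atom_ids))
            if (s >= minSharedAtoms)
                rows[[length(rows) + 1L]] <- data.frame(
                    cavity_id = cv$cavity_id, cluster_id = cl$cluster_id,
                    shared = s)
        }
    if (!length(rows))
        return(data.frame(cavity_id = integer(), cluster_id = integer(),
                          shared = integer()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-cavity survey records
#'
#' For every cavity: the number of participating rigid clusters, the
#' number of its lining atoms that belong to a participating cluster
#' (\code{n_rigid_atoms}), and the pooled percentage
#' \code{pct_rigid_atoms_in_cavity} = 100 * n_rigid_atoms / (all atoms of
#' all participating clusters, inside the cavity or not).  ET aggregates
#' are computed over the cavity's residues and stay missing when no score
#' is available.  A cavity with no participating cluster gets pct 0 and
#' \code{no_clusters = TRUE}.
#'
#' @param assoc participation map from \code{\link{associateCavities}}.
#' @param cavities,clusters the inputs given to
#'   \code{\link{associateCavities}}.
#' @param et optional \code{\linkS4class{EtScoreTable}}.
#' @param chain chain label for the records.
#' @return data.frame, one row per cavity.
#' @export
computeCavityRecords <- function(assoc, cavities, clusters, et = NULL,
                                 chain = "") {
    cavs <- .cavList(cavities)
    clus <- .cluList(clusters)
    cluById <- setNames(clus, vapply(clus, function(x)
        as.character(x$cluster_id), ""))
    rows <- lapply(cavs, function(cv) {
        part <- assoc$cluster_id[assoc$cavity_id == cv$cavity_id]
        partAtoms <- unique(unlist(lapply(as.character(part), function(k)
            cluById[[k]]$atom_ids)))
        nRigid <- length(intersect(cv$atom_ids, partAtoms))
        pct <- if (length(partAtoms)) 100 * nRigid / length(partAtoms)
               else 0
        agg <- if (length(cv$residue_keys))
            aggregateRvet(et, cv$residue_keys)
        else list(mean = NA_real_, median = NA_real_, n_scored = 0L)
        data.frame(chain = chain, cavity_id = cv$cavity_id,
                   surface_area = cv$area,
                   n_residues = length(cv$residue_keys),
                   n_rigid_clusters = length(part),
                   n_rigid_atoms = nRigid,
                   pct_rigid_atoms_in_cavity = pct,
                   mean_rvet = agg$mean, median_rvet = agg$median,
                   n_scored_residues = agg$n_scored,
                   no_clusters = length(part) == 0,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(chain = character(), cavity_id = integer(),
                          surface_area = numeric(), n_residues = integer(),
                          n_rigid_clusters = integer(),
                          n_rigid_atoms = integer(),
                          pct_rigid_atoms_in_cavity = numeric(),
                          mean_rvet = numeric(), median_rvet = numeric(),
                          n_scored_residues = integer(),
                          no_clusters = logical())
    rownames(out) <- NULL
    out
}

#' Per-rigid-cluster survey records
#'
#' For every rigid cluster: its atom and residue counts, its cavity
#' participation (number of cavities sharing at least one atom), and the
#' mean and maximum surface area of the cavities it participates in
#' (missing when participation is zero).  ET aggregates run over the
#' cluster's residues.
#'
#' @param assoc participation map from \code{\link{associateCavities}}.
#' @param cavities,clusters the inputs given to
#'   \code{\link{associateCavities}}.
#' @param structure optional \code{\linkS4class{ChainStructure}} used to
#'   resolve cluster atoms to residues (residue fields are NA without it).
#' @param et optional \code{\linkS4class{EtScoreTable}}.
#' @param chain chain label for the records.
#' @return data.frame, one row per cluster.
#' @export
computeClusterRecords <- function(assoc, cavities, clusters,
                                  structure = NULL, et = NULL,
                                  chain = "") {
    cavs <- .cavList(cavities)
    clus <- .cluList(clusters)
    areaById <- setNames(vapply(cavs, function(x) x$area, 1),
                         vapply(cavs, function(x)
                             as.character(x$cavity_id), ""))
    atomKeys <- NULL
    if (!is.null(structure)) {
        a <- structure@atoms
        atomKeys <- setNames(resKey(a$resno, a$icode),
                             as.character(a$atom_id))
    }
    rows <- lapply(clus, function(cl) {
        part <- assoc$cavity_id[assoc$cluster_id == cl$cluster_id]
        areas <- unname(areaById[as.character(part)])
        keys <- if (!is.null(atomKeys))
            unique(unname(atomKeys[as.character(cl$atom_ids)]))
        else character()
        keys <- keys[!is.na(keys)]
        agg <- if (length(keys)) aggregateRvet(et, keys)
               else list(mean = NA_real_, median = NA_real_,
                         n_scored = 0L)
        data.frame(chain = chain, cluster_id = cl$cluster_id,
                   n_atoms = length(cl$atom_ids),
                   n_residues = if (is.null(atomKeys)) NA_integer_
                                else length(keys),
                   cavity_participation = length(part),
                   mean_cavity_area = if (length(areas)) mean(areas)
                                      else NA_real_,
                   max_cavity_area = if (length(areas)) max(areas)
                                     else NA_real_,
                   mean_rvet = agg$mean, median_rvet = agg$median,
                   n_scored_residues = agg$n_scored,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(chain = character(), cluster_id = integer(),
                          n_atoms = integer(), n_residues = integer(),
                          cavity_participation = integer(),
                          mean_cavity_area = numeric(),
                          max_cavity_area = numeric(),
                          mean_rvet = numeric(), median_rvet = numeric(),
                          n_scored_residues = integer())
    rownames(out) <- NULL
    out
}

#' Write survey records as TSV and JSON
#'
#' One TSV and one JSON file per record table, with the documented fixed
#' column order, floats at 6 significant digits, and missing values as
#' empty fields (TSV) / null (JSON).
#'
#' @param records data.frame of cavity or cluster records (may be empty).
#' @param pathPrefix output prefix; files are
#'   \code{<prefix>.tsv} and \code{<prefix>.json}.
#' @return the two paths, invisibly.
#' @export
writeAggregates <- function(records, pathPrefix) {
    tsv <- paste0(pathPrefix, ".tsv")
    json <- paste0(pathPrefix, ".json")
    num <- vapply(records, is.numeric, logical(1))
    fmt <- records
    for (cn in names(fmt)[num])
        fmt[[cn]] <- ifelse(is.na(records[[cn]]), NA,
                            signif(records[[cn]], 6))
    con <- file(tsv, "wb")
    write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    close(con)
    jsonlite::write_json(fmt, json, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = FALSE)
    invisible(c(tsv = tsv, json = json))
}
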