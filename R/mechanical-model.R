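# Construction of the body-bar mechanical model: covalent bond detection
# with rotatable/locked classification, geometric hydrogen-bond and
# hydrophobic-contact detection, and conversion to rigid bodies joined by
# counted bars (a rotatable covalent bond is a hinge: exactly 5 bars).

# Intra-residue bonds with partial double-bond character (sp2, resonance)
# per standard amino-acid topology; these are locked (merged into one
# rigid body).  Backbone C-O and the inter-residue peptide C-N bond are
# locked for every residue.
.LOCKED_SIDECHAIN <- list(
    PHE = c("CG-CD1", "CD1-CE1", "CE1-CZ", "CZ-CE2", "CE2-CD2", "CD2-CG"),
    TYR = c("CG-CD1", "CD1-CE1", "CE1-CZ", "CZ-CE2", "CE2-CD2", "CD2-CG"),
    HIS = c("CG-ND1", "ND1-CE1", "CE1-NE2", "NE2-CD2", "CD2-CG"),
    TRP = c("CG-CD1", "CD1-NE1", "NE1-CE2", "CE2-CD2", "CD2-CG",
            "CE2-CZ2", "CZ2-CH2", "CH2-CZ3", "CZ3-CE3", "CE3-CD2"),
    ARG = c("NE-CZ", "CZ-NH1", "CZ-NH2"),
    ASP = c("CG-OD1", "CG-OD2"),
    GLU = c("CD-OE1", "CD-OE2"),
    ASN = c("CG-OD1", "CG-ND2"),
    GLN = c("CD-OE1", "CD-NE2"))

.AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

.bondKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Detect covalent bonds by covalent-radius distance criterion
#'
#' Two atoms are bonded iff their distance is at most the sum of their
#' covalent radii plus \code{tolerance}.  Bonds are classified as
#' \code{covalent_locked} (merged bodies: peptide C-N, backbone C=O,
#' sp2/aromatic template bonds, and bonds to hydrogen) or
#' \code{covalent_rotatable} (hinges) from a per-residue template of the
#' 20 amino acids; unknown residues default to all-rotatable with a
#' warning.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param tolerance distance slack in angstrom (default 0.4).
#' @return data.frame with columns \code{atom_a}, \code{atom_b} (ids,
#'   \code{atom_a < atom_b}), \code{kind}, \code{distance}, \code{angle}
#'   (NA for covalent bonds).
#' @export
detectCovalentBonds <- function(structure, tolerance = 0.4) {
    a <- structure@atoms
    if (nrow(a) < 2)
        return(data.frame(atom_a = integer(), atom_b = integer(),
                          kind = character(), distance = numeric(),
                          angle = numeric()))
    xyz <- as.matrix(a[, c("x", "y", "z")])
    rc <- covRadius(a$element)
    d <- as.matrix(stats::dist(xyz))
    cut <- outer(rc, rc, `+`) + tolerance
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) == 0)
        return(data.frame(atom_a = integer(), atom_b = integer(),
                          kind = character(), distance = numeric(),
                          angle = numeric()))
    i <- hit[, 1]; j <- hit[, 2]
    key <- resKey(a$resno, a$icode)
    sameRes <- key[i] == key[j]
    kind <- rep("covalent_rotatable", length(i))

    # bonds to hydrogen: terminal, no rotational freedom to model
    isH <- a$element[i] == "H" | a$element[j] == "H"
    kind[isH] <- "covalent_locked"

    known <- a$resid %in% .AA20
    unk <- unique(a$resid[!known])
    if (length(unk))
        warning("unknown residue(s) ", paste(unk, collapse = ", "),
                "; covalent bonds treated as rotatable")

    # intra-residue template bonds
    bkey <- .bondKey(a$name[i], a$name[j])
    lockedTpl <- vapply(seq_along(i), function(k) {
        if (!sameRes[k] || !known[i[k]]) return(FALSE)
        if (bkey[k] == "C-O" || bkey[k] == "C-OXT") return(TRUE)
        tpl <- .LOCKED_SIDECHAIN[[a$resid[i[k]]]]
        !is.null(tpl) && bkey[k] %in% .bondKey(
            sub("-.*", "", tpl), sub(".*-", "", tpl))
    }, logical(1))
    kind[lockedTpl] <- "covalent_locked"

    # peptide bond (omega): C of one residue to N of the next
    pep <- !sameRes &
        ((a$name[i] == "C" & a$name[j] == "N") |
         (a$name[i] == "N" & a$name[j] == "C")) &
        known[i] & known[j]
    kind[pep] <- "covalent_locked"

    data.frame(atom_a = a$atom_id[i], atom_b = a$atom_id[j],
               kind = kind, distance = d[hit], angle = NA_real_,
               stringsAsFactors = FALSE)
}

# adjacency list (atom id -> bonded atom ids) from a bond table
.bondAdjacency <- function(atomIds, bonds) {
    adj <- vector("list", length(atomIds))
    names(adj) <- as.character(atomIds)
    if (nrow(bonds)) {
        for (k in seq_len(nrow(bonds))) {
            ka <- as.character(bonds$atom_a[k])
            kb <- as.character(bonds$atom_b[k])
            adj[[ka]] <- c(adj[[ka]], bonds$atom_b[k])
            adj[[kb]] <- c(adj[[kb]], bonds$atom_a[k])
        }
    }
    adj
}

# atom ids within `depth` covalent bonds of `id`
.withinBonds <- function(adj, id, depth) {
    seen <- id
    frontier <- id
    for (d in seq_len(depth)) {
        frontier <- unique(unlist(adj[as.character(frontier)]))
        frontier <- setdiff(frontier, seen)
        if (!length(frontier)) break
        seen <- c(seen, frontier)
    }
    seen
}

#' Detect hydrogen bonds by geometric criterion
#'
#' Donor (N or O with a covalently attached hydrogen) to acceptor (N or O)
#' with donor-acceptor distance at most \code{maxDaDist} and, when the
#' hydrogen is present, a D-H-A angle of at least \code{minDhaAngle}.  In
#' structures without hydrogens every N/O is a potential donor and only
#' the distance criterion applies.  Pairs closer than three covalent bonds
#' are excluded.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param maxDaDist donor-acceptor distance cutoff, angstrom (default 3.5).
#' @param minDhaAngle minimum donor-hydrogen-acceptor angle, degrees
#'   (default 120).
#' @param bonds covalent bond table (recomputed when NULL).
#' @return data.frame of \code{hydrogen_bond} records (\code{atom_a} =
#'   donor heavy atom, \code{atom_b} = acceptor).
#' @export
detectHydrogenBonds <- function(structure, maxDaDist = 3.5,
                                minDhaAngle = 120, bonds = NULL) {
    a <- structure@atoms
    if (is.null(bonds)) bonds <- detectCovalentBonds(structure)
    adj <- .bondAdjacency(a$atom_id, bonds)
    empty <- data.frame(atom_a = integer(), atom_b = integer(),
                        kind = character(), distance = numeric(),
                        angle = numeric())
    hasH <- any(a$element == "H")
    polar <- a$atom_id[a$element %in% c("N", "O")]
    if (length(polar) < 2) return(empty)
    idx <- match(polar, a$atom_id)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    hOf <- function(id) {
        nb <- adj[[as.character(id)]]
        nb[a$element[match(nb, a$atom_id)] == "H"]
    }
    donors <- if (hasH) polar[vapply(polar, function(p) length(hOf(p)) > 0,
                                     logical(1))] else polar
    out <- list()
    for (don in donors) {
        di <- match(don, a$atom_id)
        cand <- polar[polar != don]
        dd <- sqrt(colSums((t(xyz[match(cand, a$atom_id), , drop = FALSE]) -
                            xyz[di, ])^2))
        cand <- cand[dd <= maxDaDist]
        dd <- dd[dd <= maxDaDist]
        if (!length(cand)) next
        near <- .withinBonds(adj, don, 2L)
        keep <- !(cand %in% near)
        cand <- cand[keep]; dd <- dd[keep]
        for (k in seq_along(cand)) {
            acc <- cand[k]
            ang <- NA_real_
            if (hasH) {
                hs <- hOf(don)
                angs <- vapply(hs, function(h) {
                    hi <- match(h, a$atom_id)
                    v1 <- xyz[di, ] - xyz[hi, ]
                    v2 <- xyz[match(acc, a$atom_id), ] - xyz[hi, ]
                    cosang <- sum(v1 * v2) /
                        (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
                    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
                }, numeric(1))
                ang <- max(angs)
                if (ang < minDhaAngle) next
            }
            out[[length(out) + 1L]] <-
                data.frame(atom_a = don, atom_b = acc,
                           kind = "hydrogen_bond", distance = dd[k],
                           angle = ang, stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    # one record per unordered atom pair
    pk <- paste(pmin(res$atom_a, res$atom_b), pmax(res$atom_a, res$atom_b))
    res <- res[!duplicated(pk), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Detect hydrophobic contacts
#'
#' Carbon/sulfur atoms of different residues whose van der Waals
#' surface-to-surface distance is at most \code{cutoff}, excluding pairs
#' within three covalent bonds, deduplicated to the single closest contact
#' per residue pair.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param cutoff surface-to-surface cutoff beyond the vdW sum, angstrom
#'   (default 0.25).
#' @param bonds covalent bond table (recomputed when NULL).
#' @return data.frame of \code{hydrophobic} records.
#' @export
detectHydrophobicContacts <- function(structure, cutoff = 0.25,
                                      bonds = NULL) {
    a <- structure@atoms
    if (is.null(bonds)) bonds <- detectCovalentBonds(structure)
    empty <- data.frame(atom_a = integer(), atom_b = integer(),
                        kind = character(), distance = numeric(),
                        angle = numeric())
    sel <- a$element %in% c("C", "S")
    if (sum(sel) < 2) return(empty)
    sub <- a[sel, , drop = FALSE]
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    rv <- vdwRadius(sub$element)
    d <- as.matrix(stats::dist(xyz))
    surf <- d - outer(rv, rv, `+`)
    key <- resKey(sub$resno, sub$icode)
    hit <- which(surf <= cutoff & upper.tri(surf), arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    i <- hit[, 1]; j <- hit[, 2]
    keep <- key[i] != key[j]
    i <- i[keep]; j <- j[keep]
    if (!length(i)) return(empty)
    adj <- .bondAdjacency(a$atom_id, bonds)
    sep <- vapply(seq_along(i), function(k) {
        sub$atom_id[j[k]] %in% .withinBonds(adj, sub$atom_id[i[k]], 3L)
    }, logical(1))
    i <- i[!sep]; j <- j[!sep]
    if (!length(i)) return(empty)
    res <- data.frame(atom_a = sub$atom_id[i], atom_b = sub$atom_id[j],
                      kind = "hydrophobic",
                      distance = d[cbind(i, j)],
                      angle = NA_real_, stringsAsFactors = FALSE)
    rp <- paste(pmin(key[i], key[j]), pmax(key[i], key[j]))
    ord <- order(rp, surf[cbind(i, j)])
    res <- res[ord, , drop = FALSE]
    res <- res[!duplicated(rp[ord]), , drop = FALSE]
    res <- res[order(res$atom_a, res$atom_b), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Build the body-bar mechanical model
#'
#' Atoms joined by locked covalent bonds are merged transitively into
#' rigid bodies.  Each rotatable covalent bond becomes a hinge: exactly 5
#' bars between the bodies holding its endpoints, with both endpoint
#' atoms members of both bodies.  Hydrogen bonds and hydrophobic contacts
#' contribute \code{barPolicy} bars (defaults 5 and 2).  Isolated atoms
#' become singleton bodies.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param bonds bond table (rows from the three detectors combined).
#' @param barPolicy named vector mapping \code{hydrogen_bond} and
#'   \code{hydrophobic} to bar counts in 1..6.
#' @return a \code{\linkS4class{MechanicalModel}}.
#' @export
buildMechanicalModel <- function(structure, bonds,
                                 barPolicy = c(hydrogen_bond = 5,
                                               hydrophobic = 2)) {
    if (any(barPolicy < 1 | barPolicy > 6))
        stop("invalid bar count: bar policy values must lie in [1,6]")
    a <- structure@atoms
    n <- nrow(a)
    idx <- function(id) match(id, a$atom_id)
    bad <- c(bonds$atom_a, bonds$atom_b)
    if (any(is.na(idx(bad))))
        stop("bond references unknown atom id")

    uf <- unionFind(n)
    locked <- bonds[bonds$kind == "covalent_locked", , drop = FALSE]
    for (k in seq_len(nrow(locked)))
        uf$unite(idx(locked$atom_a[k]), idx(locked$atom_b[k]))
    lab <- uf$labels()
    bodyOf <- match(lab, sort(unique(lab)))
    bodiesCore <- split(a$atom_id, bodyOf)
    names(bodiesCore) <- NULL
    bodies <- bodiesCore

    rows <- list()
    addConstraint <- function(bu, bv, bars, kind, aa, ab, dist) {
        rows[[length(rows) + 1L]] <<- data.frame(
            body_u = bu, body_v = bv, bars = bars, kind = kind,
            atom_a = aa, atom_b = ab, distance = dist,
            stringsAsFactors = FALSE)
    }
    other <- bonds[bonds$kind != "covalent_locked", , drop = FALSE]
    for (k in seq_len(nrow(other))) {
        aa <- other$atom_a[k]; ab <- other$atom_b[k]
        bu <- bodyOf[idx(aa)]; bv <- bodyOf[idx(ab)]
        if (bu == bv) next
        kind <- other$kind[k]
        if (kind == "covalent_rotatable") {
            # hinge: 5 bars; endpoint atoms shared between both bodies
            bodies[[bu]] <- sort(unique(c(bodies[[bu]], ab)))
            bodies[[bv]] <- sort(unique(c(bodies[[bv]], aa)))
            addConstraint(bu, bv, 5L, kind, aa, ab, other$distance[k])
        } else {
            bars <- unname(barPolicy[kind])
            if (is.na(bars)) stop("no bar policy for bond kind ", kind)
            addConstraint(bu, bv, as.integer(bars), kind, aa, ab,
                          other$distance[k])
        }
    }
    cs <- if (length(rows)) do.call(rbind, rows) else
        data.frame(body_u = integer(), body_v = integer(),
                   bars = integer(), kind = character(),
                   atom_a = integer(), atom_b = integer(),
                   distance = numeric())
    new("MechanicalModel", bodies = bodies, constraints = cs)
}

#' Map atoms to the bodies containing them
#'
#' @param model a \code{\linkS4class{MechanicalModel}}.
#' @return named list: atom id -> integer vector of body ids (hinge
#'   endpoint atoms belong to two bodies).
#' @export
atomToBodies <- function(model) {
    m <- list()
    for (b in seq_along(model@bodies))
        for (id in model@bodies[[b]]) {
            k <- as.character(id)
            m[[k]] <- c(m[[k]], b)
        }
    m
}

#' Export a bond table as TSV
#'
#' @param bonds bond table from the detectors.
#' @param path output file.
#' @export
writeBondsTsv <- function(bonds, path) {
    write.table(bonds[, c("atom_a", "atom_b", "kind", "distance")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
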