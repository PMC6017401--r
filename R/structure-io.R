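# Reading and writing single protein chains (wwPDB v3.3 ATOM records).
# Parsing and record formatting are delegated to bio3d; this layer applies
# the chain filter, alternate-location resolution and validation.

#' Construct a ChainStructure from an atom table
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{name},
#'   \code{element}, \code{resno}, \code{icode}, \code{resid}, \code{x},
#'   \code{y}, \code{z}, and optionally \code{occupancy}, \code{alt}.
#' @param chainId single-character chain id.
#' @param sourceLabel provenance label.
#' @return a validated \code{\linkS4class{ChainStructure}}.
#' @export
chainStructure <- function(atoms, chainId = "A", sourceLabel = "") {
    if (is.null(atoms$occupancy)) atoms$occupancy <- 1
    if (is.null(atoms$alt)) atoms$alt <- ""
    if (is.null(atoms$icode)) atoms$icode <- ""
    atoms <- atoms[order(atoms$resno, atoms$icode, atoms$atom_id), ,
                   drop = FALSE]
    rownames(atoms) <- NULL
    atoms$atom_id <- as.integer(atoms$atom_id)
    atoms$resno <- as.integer(atoms$resno)
    new("ChainStructure", chainId = chainId, sourceLabel = sourceLabel,
        atoms = atoms)
}

#' Read one chain from a PDB file
#'
#' Reads the ATOM records of a single chain.  HETATM records (waters,
#' ligands) are excluded by default; hydrogens are retained when present.
#' Alternate locations are resolved per atom by keeping the
#' highest-occupancy record (ties: first in file).  A missing element
#' column is inferred from the first non-digit character of the atom name.
#'
#' @param path PDB file.
#' @param chainId chain identifier to extract.
#' @param includeHetatm also keep HETATM records of that chain.
#' @return a \code{\linkS4class{ChainStructure}}.
#' @export
readPdbChain <- function(path, chainId, includeHetatm = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                        stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
    at <- pdb$atom
    if (!any(at$chain == chainId, na.rm = TRUE))
        stop("chain not found: ", chainId)
    at <- at[at$chain == chainId, , drop = FALSE]
    if (!includeHetatm) at <- at[at$type == "ATOM", , drop = FALSE]
    if (nrow(at) == 0) stop("empty structure: no ATOM records for chain ",
                            chainId)
    bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
    if (any(bad)) {
        lines <- readLines(path, warn = FALSE)
        serial <- at$eleno[which(bad)[1]]
        hit <- grep(sprintf("^(ATOM  |HETATM)%5s", serial), lines)
        stop("parse error: malformed coordinates at line ",
             if (length(hit)) hit[1] else "?", " (atom serial ", serial, ")")
    }
    # alternate locations: per (residue, atom name) keep max occupancy,
    # ties resolved by file order
    at$alt[is.na(at$alt)] <- ""
    at$insert[is.na(at$insert)] <- ""
    grp <- paste(at$resno, at$insert, at$elety, sep = "\r")
    occ <- at$o
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), grp),
                          function(i) i[which.max(occ[i])]),
                   use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
    el <- at$elesy
    el[is.na(el) | el == ""] <- inferElement(at$elety[is.na(el) | el == ""])
    atoms <- data.frame(atom_id = as.integer(at$eleno),
                        name = at$elety,
                        element = toupper(el),
                        resno = as.integer(at$resno),
                        icode = at$insert,
                        resid = at$resid,
                        x = at$x, y = at$y, z = at$z,
                        occupancy = pmin(1, pmax(0, ifelse(is.na(at$o),
                                                           1, at$o))),
                        alt = at$alt,
                        stringsAsFactors = FALSE)
    label <- paste0(sub("\\.pdb$", "", basename(path)), chainId)
    chainStructure(atoms, chainId = chainId, sourceLabel = label)
}

#' Write a chain to a PDB file
#'
#' Emits standards-conformant ATOM records; a round trip through
#' \code{\link{readPdbChain}} reproduces ids, names, residue keys and
#' coordinates to the PDB's 3-decimal precision.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param path output file.
#' @export
writePdbChain <- function(structure, path) {
    stopifnot(is(structure, "ChainStructure"))
    validObject(structure)
    a <- structure@atoms
    if (nrow(a) == 0) stop("empty structure: nothing to write")
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = rep("ATOM", nrow(a)),
                     eleno = a$atom_id, elety = a$name,
                     resid = a$resid, chain = structure@chainId,
                     resno = a$resno, insert = a$icode,
                     o = a$occupancy, b = rep(0, nrow(a)),
                     elesy = a$element)
    invisible(path)
}
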