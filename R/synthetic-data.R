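# Synthetic fixtures with machine-checkable ground truth: ideal-geometry
# polymer chains (known rigid-cluster structure), hollow-shell and open-
# pocket atom arrangements (known cavity count/area/lining), random
# body-bar multigraphs, correlated metric corpora, and ET score files.
# Every generator is bit-stable under a fixed seed.

# internal-coordinate atom placement: position D bonded to C with bond
# length r, angle B-C-D theta (deg) and dihedral A-B-C-D phi (deg).
.nerf <- function(A, B, C, r, theta, phi) {
    th <- theta * pi / 180
    ph <- phi * pi / 180
    bc <- C - B
    bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
    C + d[1] * bc + d[2] * m + d[3] * n
}

# ideal backbone geometry (angstrom / degrees)
.GEO <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             n_h = 1.01, ca_cb = 1.521,
             ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
             ang_ca_c_o = 120.8, ang_c_n_h = 119.0, ang_c_ca_cb = 110.1,
             dih_n_c_ca_cb = 122.6)

#' Generate an ideal-geometry polymer chain with known rigidity
#'
#' Builds a poly-alanine-like backbone (N, H, CA, CB, C, O per residue)
#' with fixed ideal bond lengths and angles, in an extended
#' (phi = psi = 180) or alpha-helical (phi = -57, psi = -47)
#' conformation.  A chosen fraction of the rotatable covalent bonds is
#' relabelled locked (seeded, uniform), so the expected rigid-body
#' partition is derivable by union-find over locked bonds; with
#' \code{lockedFraction = 1} the whole chain is one rigid cluster.
#'
#' @param nResidues chain length (at least 2).
#' @param lockedFraction fraction of rotatable bonds relabelled locked,
#'   in [0, 1].
#' @param seed RNG seed for the relabelling draw.
#' @param conformation \code{"extended"} or \code{"helix"}.
#' @param chainId chain identifier.
#' @return list with \code{structure}
#'   (\code{\linkS4class{ChainStructure}}), \code{bonds} (covalent bond
#'   table after relabelling), and \code{expectedBodies} (list of atom-id
#'   sets: the locked-bond-connected components).
#' @export
makePolymerChain <- function(nResidues, lockedFraction = 0, seed = 1,
                             conformation = c("extended", "helix"),
                             chainId = "A") {
    if (nResidues < 2) stop("need at least 2 residues")
    if (lockedFraction < 0 || lockedFraction > 1)
        stop("invalid fraction")
    conformation <- match.arg(conformation)
    phi <- if (conformation == "extended") 180 else -57
    psi <- if (conformation == "extended") 180 else -47
    g <- .GEO
    N <- CA <- C <- O <- H <- CB <- matrix(NA_real_, nResidues, 3)
    N[1, ] <- c(0, 0, 0)
    CA[1, ] <- c(g$n_ca, 0, 0)
    C[1, ] <- .nerf(c(0, -1, 0), N[1, ], CA[1, ], g$ca_c, g$ang_n_ca_c, 0)
    for (i in seq_len(nResidues)) {
        if (i < nResidues) {
            N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$c_n,
                                g$ang_ca_c_n, psi)
            CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], g$n_ca,
                                 g$ang_c_n_ca, 180)
            C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                                g$ang_n_ca_c, phi)
            O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                            psi + 180)
            H[i + 1, ] <- .nerf(O[i, ], C[i, ], N[i + 1, ], g$n_h,
                                g$ang_c_n_h, 180)
        } else {
            O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                            0)
        }
        CB[i, ] <- .nerf(N[i, ], C[i, ], CA[i, ], g$ca_cb, g$ang_c_ca_cb,
                         g$dih_n_c_ca_cb)
    }
    rows <- list()
    aid <- 0L
    addAtom <- function(name, element, resno, xyz) {
        aid <<- aid + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
            atom_id = aid, name = name, element = element, resno = resno,
            icode = "", resid = "ALA", x = xyz[1], y = xyz[2], z = xyz[3],
            occupancy = 1, alt = "", stringsAsFactors = FALSE)
    }
    for (i in seq_len(nResidues)) {
        addAtom("N", "N", i, N[i, ])
        if (i > 1) addAtom("H", "H", i, H[i, ])
        addAtom("CA", "C", i, CA[i, ])
        addAtom("CB", "C", i, CB[i, ])
        addAtom("C", "C", i, C[i, ])
        addAtom("O", "O", i, O[i, ])
    }
    structure <- chainStructure(do.call(rbind, rows), chainId = chainId,
                                sourceLabel = sprintf("poly%d", nResidues))
    bonds <- detectCovalentBonds(structure)
    rot <- which(bonds$kind == "covalent_rotatable")
    nLock <- round(lockedFraction * length(rot))
    if (nLock > 0) {
        pick <- withSeed(seed, sample(rot, nLock))
        bonds$kind[pick] <- "covalent_locked"
    }
    # ground truth: locked-bond-connected components of the atom set
    uf <- unionFind(nAtoms(structure))
    lk <- bonds[bonds$kind == "covalent_locked", , drop = FALSE]
    ids <- structure@atoms$atom_id
    for (k in seq_len(nrow(lk)))
        uf$unite(match(lk$atom_a[k], ids), match(lk$atom_b[k], ids))
    expected <- unname(lapply(split(ids, uf$labels()), sort))
    list(structure = structure, bonds = bonds,
         expectedBodies = expected)
}

# quasi-uniform points on a sphere (Fibonacci lattice)
.fibSphere <- function(n, radius, center = c(0, 0, 0)) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    th <- pi * (1 + sqrt(5)) * i
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(center[1] + radius * r * cos(th),
          center[2] + radius * r * sin(th),
          center[3] + radius * z)
}

.shellAtomCount <- function(radius, spacing) {
    max(12L, as.integer(ceiling(1.1 * (3.81 * radius / spacing)^2)))
}

# voxel leak test: TRUE when the probe-centre region at the shell centre
# is connected to the bulk solvent (i.e. the shell is not closed)
.shellLeaks <- function(coords, radii, probe, center) {
    spacing <- 0.5
    lo <- apply(coords, 2, min) - max(radii) - probe - 3
    hi <- apply(coords, 2, max) + max(radii) + probe + 3
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    af <- cpp_atom_field(dims, lo, spacing, coords, radii, probe + 2)
    open <- af >= probe
    reached <- cpp_flood_boundary(open, dims, 6L)
    ci <- as.integer(round((center - lo) / spacing))
    cidx <- 1L + ci[1] + dims[1] * (ci[2] + dims[2] * ci[3])
    isTRUE(reached[cidx])
}

#' Generate a hollow atom shell with a known interior cavity
#'
#' Atoms (carbon, vdW 1.7 A) tile one or more concentric spheres on a
#' Fibonacci lattice at the requested spacing.  Closure is verified at
#' generation time by a voxel flood-fill leak test, so the cavity-count
#' ground truth is guaranteed rather than assumed.  The expected interior
#' cavity surface is the contact surface of a probe rolling inside the
#' innermost shell: a sphere of radius \code{shellRadius - vdW}, with
#' analytic area \code{4 pi (shellRadius - vdW)^2}.
#'
#' @param shellRadius radius (angstrom, at least 6) of the shell's atom
#'   centres; a vector builds nested shells (one cavity per enclosed
#'   region).
#' @param atomSpacing target distance between neighbouring shell atoms;
#'   must not exceed twice the vdW radius.
#' @param probe probe radius the ground truth refers to (default 1.4).
#' @param chainId chain identifier.
#' @return list with \code{structure}, \code{expectedCavities} (count),
#'   \code{voidRadius} and \code{expectedArea} (innermost cavity, single
#'   shell only).
#' @export
makeHollowShell <- function(shellRadius = 8, atomSpacing = 1.5,
                            probe = 1.4, chainId = "A") {
    rv <- 1.7
    if (any(shellRadius < 6)) stop("shellRadius must be at least 6 A")
    if (atomSpacing > 2 * rv)
        stop("shell not closed: atom spacing exceeds twice the vdW radius")
    shellRadius <- sort(shellRadius)
    if (length(shellRadius) > 1 &&
        any(diff(shellRadius) <= 2 * (rv + probe)))
        stop("nested shells too close: the probe cannot enter the gap")
    pts <- do.call(rbind, lapply(shellRadius, function(R)
        .fibSphere(.shellAtomCount(R, atomSpacing), R)))
    if (.shellLeaks(pts, rep(rv, nrow(pts)), probe, c(0, 0, 0)))
        stop("shell not closed: probe leaks through the atom lattice")
    atoms <- data.frame(atom_id = seq_len(nrow(pts)), name = "CA",
                        element = "C", resno = seq_len(nrow(pts)),
                        icode = "", resid = "GLY",
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        occupancy = 1, alt = "", stringsAsFactors = FALSE)
    rInner <- shellRadius[1] - rv
    list(structure = chainStructure(atoms, chainId = chainId,
                                    sourceLabel = "hollowshell"),
         expectedCavities = length(shellRadius),
         voidRadius = rInner,
         expectedArea = 4 * pi * rInner^2)
}

#' Generate an open hemispherical pocket fixture
#'
#' A spherical atom shell with a circular opening (polar cap removed)
#' small enough that the default 8 A envelope probe cannot enter: the
#' interior is detected as a surface pocket whose lining ground truth is
#' the full atom set.
#'
#' @param radius shell radius, angstrom.
#' @param atomSpacing lattice spacing, angstrom.
#' @param openingHalfAngle half-angle of the removed polar cap, degrees;
#'   the opening radius \code{radius * sin(openingHalfAngle)} must stay
#'   below the envelope probe radius.
#' @param chainId chain identifier.
#' @return list with \code{structure}, \code{expectedCavities} (1) and
#'   \code{liningAtoms} (all atom ids).
#' @export
makeOpenPocket <- function(radius = 8, atomSpacing = 1.5,
                           openingHalfAngle = 25, chainId = "A") {
    pts <- .fibSphere(.shellAtomCount(radius, atomSpacing), radius)
    polar <- acos(pmin(1, pmax(-1, pts[, 3] / radius))) * 180 / pi
    pts <- pts[polar >= openingHalfAngle, , drop = FALSE]
    atoms <- data.frame(atom_id = seq_len(nrow(pts)), name = "CA",
                        element = "C", resno = seq_len(nrow(pts)),
                        icode = "", resid = "GLY",
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        occupancy = 1, alt = "", stringsAsFactors = FALSE)
    list(structure = chainStructure(atoms, chainId = chainId,
                                    sourceLabel = "openpocket"),
         expectedCavities = 1L,
         liningAtoms = atoms$atom_id)
}

#' Generate a random body-bar multigraph
#'
#' Uniform random multigraph without self-loops (edges drawn with
#' replacement from the distinct node pairs), seed-stable.
#'
#' @param nNodes number of bodies (at least 1).
#' @param nEdges number of bars.
#' @param seed RNG seed.
#' @return a \code{\linkS4class{BodyBarGraph}}.
#' @export
makeRandomBodyBarGraph <- function(nNodes, nEdges, seed = 1) {
    if (nNodes < 1) stop("need at least one node")
    if (nEdges > 0 && nNodes < 2)
        stop("cannot place edges on a single node")
    if (nEdges == 0)
        return(new("BodyBarGraph", nNodes = as.integer(nNodes),
                   edges = matrix(integer(), ncol = 2,
                                  dimnames = list(NULL, c("u", "v")))))
    pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
    pick <- withSeed(seed, sample.int(nrow(pairs), nEdges,
                                      replace = TRUE))
    e <- pairs[pick, , drop = FALSE]
    e <- cbind(u = pmin(e[, 1], e[, 2]), v = pmax(e[, 1], e[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    new("BodyBarGraph", nNodes = as.integer(nNodes),
        edges = matrix(as.integer(e), ncol = 2,
                       dimnames = list(NULL, c("u", "v"))))
}

#' Generate a synthetic survey corpus with a set metric correlation
#'
#' Emits per-chain cavity and cluster record tables whose key metric
#' pairs (residues vs rigid clusters per cavity; cluster size vs cavity
#' participation) are drawn bivariate-normal with true correlation
#' \code{rhoStar} and then mapped to each metric's support (counts by
#' rounding with a floor of 1, areas by exponentiation).  Support
#' locations and scales are chosen so rounding and truncation leave the
#' latent correlation essentially intact (attenuation well below 0.001).
#' Record counts per chain are negative-binomial (size 5, mean 10, plus
#' one).
#'
#' @param nChains number of synthetic chains.
#' @param rhoStar true latent correlation, in (-1, 1).
#' @param seed RNG seed.
#' @return list with data.frames \code{cavities} and \code{clusters};
#'   attribute \code{"rhoStar"} stores the ground truth.
#' @export
makeMetricCorpus <- function(nChains, rhoStar, seed = 1) {
    if (rhoStar <= -1 || rhoStar >= 1) stop("invalid rhoStar")
    sig <- matrix(c(1, rhoStar, rhoStar, 1), 2)
    withSeed(seed, {
        nCav <- rnbinom(nChains, size = 5, mu = 10) + 1L
        nClu <- rnbinom(nChains, size = 5, mu = 10) + 1L
        chain <- sprintf("synth%05d", seq_len(nChains))
        zc <- MASS::mvrnorm(sum(nCav), mu = c(0, 0), Sigma = sig)
        zk <- MASS::mvrnorm(sum(nClu), mu = c(0, 0), Sigma = sig)
        cav <- data.frame(
            chain = rep(chain, nCav),
            cavity_id = unlist(lapply(nCav, seq_len)),
            surface_area = exp(4.5 + 0.8 * rnorm(sum(nCav))),
            n_residues = pmax(1, round(45 + 12 * zc[, 1])),
            n_rigid_clusters = pmax(1, round(40 + 10 * zc[, 2])),
            stringsAsFactors = FALSE)
        cav$n_rigid_atoms <- pmax(0L, as.integer(round(
            4 * cav$n_residues + 10 * rnorm(nrow(cav)))))
        cav$pct_rigid_atoms_in_cavity <- pmin(100, pmax(0,
            rnorm(nrow(cav), 50, 15)))
        cav$mean_rvet <- runif(nrow(cav), 1, 100)
        cav$median_rvet <- cav$mean_rvet +
            rnorm(nrow(cav), 0, 3)
        clu <- data.frame(
            chain = rep(chain, nClu),
            cluster_id = unlist(lapply(nClu, function(k) seq_len(k) - 1L)),
            n_atoms = pmax(1, round(120 + 30 * zk[, 1])),
            cavity_participation = pmax(0, round(30 + 8 * zk[, 2])),
            stringsAsFactors = FALSE)
        clu$n_residues <- pmax(1L, as.integer(round(clu$n_atoms / 4)))
        clu$mean_cavity_area <- exp(4.5 + 0.8 * rnorm(nrow(clu)))
        clu$max_cavity_area <- clu$mean_cavity_area *
            runif(nrow(clu), 1, 2.5)
        clu$mean_rvet <- runif(nrow(clu), 1, 100)
        clu$median_rvet <- clu$mean_rvet + rnorm(nrow(clu), 0, 3)
        out <- list(cavities = cav, clusters = clu)
        attr(out, "rhoStar") <- rhoStar
        out
    })
}

#' Write a synthetic evolutionary-trace ranks file
#'
#' One rvet score per residue, drawn uniform on \code{range}; an optional
#' fraction of residues is left unscored.  The output parses with
#' \code{\link{readEtFile}}.
#'
#' @param structure a \code{\linkS4class{ChainStructure}}.
#' @param path output file.
#' @param range rvet range (default [1, 100]).
#' @param missingFraction fraction of residues to omit (default 0).
#' @param seed RNG seed.
#' @return \code{path}, with the written score table attached as
#'   attribute \code{"scores"}.
#' @export
makeEtTable <- function(structure, path, range = c(1, 100),
                        missingFraction = 0, seed = 1) {
    rt <- residueTable(structure)
    tab <- withSeed(seed, {
        sc <- runif(nrow(rt), range[1], range[2])
        keep <- rep(TRUE, nrow(rt))
        nDrop <- round(missingFraction * nrow(rt))
        if (nDrop > 0) keep[sample.int(nrow(rt), nDrop)] <- FALSE
        data.frame(resno = rt$resno[keep], restype = rt$resid[keep],
                   rvet = sc[keep], stringsAsFactors = FALSE)
    })
    con <- file(path, "wb")
    writeLines(c("% synthetic evolutionary trace ranks",
                 "% resno restype rvet",
                 sprintf("%d\t%s\t%.10g", tab$resno, tab$restype,
                         tab$rvet)), con)
    close(con)
    attr(path, "scores") <- tab
    invisible(path)
}
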