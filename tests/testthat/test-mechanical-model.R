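test_that("covalent bonds follow the covalent-radius distance rule", {
    two <- function(d) chainStructure(simpleAtoms(cbind(c(0, d), 0, 0)))
    b1 <- detectCovalentBonds(two(1.5))
    expect_equal(nrow(b1), 1)           # 1.5 <= 0.77 + 0.77 + 0.4
    expect_equal(b1$distance, 1.5, tolerance = 1e-9)
    expect_equal(nrow(detectCovalentBonds(two(3.0))), 0)
})

test_that("backbone bonds are classified against the residue template", {
    g <- makePolymerChain(3)
    b <- g$bonds
    a <- atomTable(g$structure)
    lab <- function(id) a$name[match(id, a$atom_id)]
    res <- function(id) a$resno[match(id, a$atom_id)]
    for (k in seq_len(nrow(b))) {
        nm <- sort(c(lab(b$atom_a[k]), lab(b$atom_b[k])))
        inter <- res(b$atom_a[k]) != res(b$atom_b[k])
        expected <- if (inter && identical(nm, c("C", "N")))
            "covalent_locked"                     # peptide omega
        else if (identical(nm, c("C", "O")))
            "covalent_locked"                     # carbonyl double bond
        else if ("H" %in% nm) "covalent_locked"   # terminal hydrogen
        else "covalent_rotatable"                 # phi/psi/side chain
        expect_identical(b$kind[k], expected)
    }
    expect_gt(sum(b$kind == "covalent_rotatable"), 0)
})

test_that("hydrogen bonds need geometry: distance and D-H-A angle", {
    # donor N with collinear H pointing at acceptor O, 2.9 A away
    at <- rbind(
        simpleAtoms(cbind(0, 0, 0), element = "N", name = "N", resno = 1),
        simpleAtoms(cbind(1.0, 0, 0), element = "H", name = "H",
                    resno = 1),
        simpleAtoms(cbind(2.9, 0, 0), element = "O", name = "O",
                    resno = 5))
    at$atom_id <- 1:3
    s <- chainStructure(at)
    hb <- detectHydrogenBonds(s)
    expect_equal(nrow(hb), 1)
    expect_equal(hb$atom_a, 1)
    expect_equal(hb$angle, 180, tolerance = 1e-6)
    # same geometry but 4.5 A: none
    at2 <- at
    at2$x[3] <- 4.5
    expect_equal(nrow(detectHydrogenBonds(chainStructure(at2))), 0)
    # bent H (angle < 120): rejected
    at3 <- at
    at3$x[2] <- 0
    at3$y[2] <- 1.0
    expect_equal(nrow(detectHydrogenBonds(chainStructure(at3))), 0)
})

test_that("ideal helix hydrogen bonds equal a brute-force geometric scan", {
    g <- makePolymerChain(10, conformation = "helix")
    s <- g$structure
    a <- atomTable(s)
    hb <- detectHydrogenBonds(s, bonds = g$bonds)
    # brute force: every N/O donor with H, every N/O acceptor, criterion
    # applied directly, excluding pairs within 2 covalent bonds
    adj <- CavityRigidity:::.bondAdjacency(a$atom_id, g$bonds)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    polar <- a$atom_id[a$element %in% c("N", "O")]
    found <- 0
    for (don in polar) {
        hs <- intersect(adj[[as.character(don)]],
                        a$atom_id[a$element == "H"])
        if (!length(hs)) next
        for (acc in setdiff(polar, don)) {
            if (acc %in% CavityRigidity:::.withinBonds(adj, don, 2L)) next
            di <- match(don, a$atom_id); ai <- match(acc, a$atom_id)
            dda <- sqrt(sum((xyz[di, ] - xyz[ai, ])^2))
            if (dda > 3.5) next
            best <- max(vapply(hs, function(h) {
                hi <- match(h, a$atom_id)
                v1 <- xyz[di, ] - xyz[hi, ]
                v2 <- xyz[ai, ] - xyz[hi, ]
                acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
            }, 1))
            if (best >= 120) found <- found + 1
        }
    }
    expect_equal(nrow(hb), found)
    expect_equal(nrow(hb), 10 - 4)      # i -> i+4 backbone ladder
})

test_that("hydrophobic contacts obey the vdW surface-distance rule", {
    pairAt <- function(d) chainStructure(
        simpleAtoms(cbind(c(0, d), 0, 0), resno = c(1, 5), name = "CB",
                    resid = "LEU"))
    # surface distance d - 3.4: inside the 0.25 A default cutoff at 3.6
    expect_equal(nrow(detectHydrophobicContacts(pairAt(3.6))), 1)
    expect_equal(nrow(detectHydrophobicContacts(pairAt(3.9))), 0)
    expect_equal(nrow(detectHydrophobicContacts(pairAt(3.9),
                                                cutoff = 0.5)), 1)
    # same-residue carbons never contact
    same <- chainStructure(simpleAtoms(cbind(c(0, 3.6), 0, 0),
                                       resno = c(1, 1)))
    expect_equal(nrow(detectHydrophobicContacts(same)), 0)
    # fully extended chain: all side chains point apart
    g <- makePolymerChain(5)
    expect_equal(nrow(detectHydrophobicContacts(g$structure,
                                                bonds = g$bonds)), 0)
})

test_that("hydrophobic contacts deduplicate to the closest pair per residue pair", {
    at <- simpleAtoms(rbind(c(0, 0, 0), c(0, 1.5, 0),
                            c(3.5, 0, 0), c(3.6, 1.5, 0)),
                      resno = c(1, 1, 5, 5))
    s <- chainStructure(at)
    hc <- detectHydrophobicContacts(s)
    expect_equal(nrow(hc), 1)
    expect_equal(sort(c(hc$atom_a, hc$atom_b)), c(1, 3))
})

test_that("the converter builds hinges with 5 bars and shared endpoint atoms", {
    two <- chainStructure(simpleAtoms(cbind(c(0, 1.5), 0, 0)))
    bonds <- data.frame(atom_a = 1L, atom_b = 2L,
                        kind = "covalent_rotatable", distance = 1.5,
                        angle = NA_real_)
    m <- buildMechanicalModel(two, bonds)
    expect_length(bodies(m), 2)
    expect_equal(nrow(constraints(m)), 1)
    expect_equal(constraints(m)$bars, 5L)
    expect_equal(bodies(m)[[1]], c(1L, 2L))
    expect_equal(bodies(m)[[2]], c(1L, 2L))
})

test_that("locked triangles merge transitively into one body", {
    tri <- chainStructure(simpleAtoms(rbind(c(0, 0, 0), c(1.5, 0, 0),
                                            c(0.75, 1.3, 0))))
    bonds <- data.frame(atom_a = c(1L, 2L, 1L), atom_b = c(2L, 3L, 3L),
                        kind = "covalent_locked", distance = 1.5,
                        angle = NA_real_)
    m <- buildMechanicalModel(tri, bonds)
    expect_length(bodies(m), 1)
    expect_equal(nrow(constraints(m)), 0)
})

test_that("body count equals the union-find components of locked bonds", {
    for (lf in c(0, 0.3, 0.7)) {
        g <- makePolymerChain(8, lockedFraction = lf, seed = 42)
        m <- buildMechanicalModel(g$structure, g$bonds)
        # independent union-find oracle over locked bonds
        a <- atomTable(g$structure)
        parent <- seq_len(nrow(a))
        find <- function(x) {
            while (parent[x] != x) x <- parent[x]
            x
        }
        lk <- g$bonds[g$bonds$kind == "covalent_locked", ]
        for (k in seq_len(nrow(lk))) {
            ra <- find(match(lk$atom_a[k], a$atom_id))
            rb <- find(match(lk$atom_b[k], a$atom_id))
            if (ra != rb) parent[ra] <- rb
        }
        expect_length(bodies(m),
                      length(unique(vapply(seq_len(nrow(a)), find, 1L))))
    }
})

test_that("model construction is invariant to bond input order", {
    g <- makePolymerChain(6, lockedFraction = 0.4, seed = 7)
    m1 <- buildMechanicalModel(g$structure, g$bonds)
    canon <- function(m) {
        cs <- constraints(m)
        cs <- cs[order(cs$body_u, cs$body_v, cs$kind, cs$atom_a), ]
        rownames(cs) <- NULL
        list(b = bodies(m), cs = cs)
    }
    for (seed in 1:5) {
        set.seed(seed)
        perm <- g$bonds[sample.int(nrow(g$bonds)), ]
        m2 <- buildMechanicalModel(g$structure, perm)
        expect_identical(canon(m2), canon(m1))
    }
})

test_that("invalid bar policies are rejected", {
    two <- chainStructure(simpleAtoms(cbind(c(0, 1.5), 0, 0)))
    bonds <- data.frame(atom_a = 1L, atom_b = 2L,
                        kind = "hydrogen_bond", distance = 1.5,
                        angle = NA_real_)
    expect_error(buildMechanicalModel(two, bonds,
                                      barPolicy = c(hydrogen_bond = 0,
                                                    hydrophobic = 2)),
                 "invalid bar count")
    expect_error(buildMechanicalModel(two, bonds,
                                      barPolicy = c(hydrogen_bond = 7,
                                                    hydrophobic = 2)),
                 "invalid bar count")
})

test_that("body atom sets cover all atoms; only hinge endpoints are shared", {
    g <- makePolymerChain(6, lockedFraction = 0.3, seed = 3)
    m <- buildMechanicalModel(g$structure, g$bonds)
    all_ids <- atomTable(g$structure)$atom_id
    expect_setequal(unique(unlist(bodies(m))), all_ids)
    counts <- table(unlist(bodies(m)))
    shared <- as.integer(names(counts)[counts > 1])
    hingeAtoms <- with(constraints(m),
                       unique(c(atom_a[kind == "covalent_rotatable"],
                                atom_b[kind == "covalent_rotatable"])))
    expect_true(all(shared %in% hingeAtoms))
})
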