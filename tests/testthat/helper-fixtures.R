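# Shared fixture builders (all generated in code; no binary data).

# minimal atom-table builder: one row per atom, residue = ceiling(id/2)
# unless given
simpleAtoms <- function(coords, element = "C", name = "CA",
                        resno = NULL, resid = "GLY") {
    n <- nrow(coords)
    data.frame(atom_id = seq_len(n), name = name, element = element,
               resno = if (is.null(resno)) seq_len(n) else resno,
               icode = "", resid = resid,
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               occupancy = 1, alt = "", stringsAsFactors = FALSE)
}

# the hand-computed association fixture: 4 rigid clusters, 3 cavities,
# 34 atoms (atom i belongs to residue ceiling(i/2)), ET score of residue
# r is 10*r.  Expected record tables live in inst/extdata.
joinFixture <- function() {
    coords <- cbind(seq_len(34) * 2, 0, 0)
    structure <- chainStructure(
        simpleAtoms(coords, resno = ceiling(seq_len(34) / 2),
                    resid = "ALA"),
        chainId = "A", sourceLabel = "fixA")
    clusters <- list(list(cluster_id = 0L, atom_ids = 1:10),
                     list(cluster_id = 1L, atom_ids = 11:20),
                     list(cluster_id = 2L, atom_ids = 21:30),
                     list(cluster_id = 3L, atom_ids = 31:34))
    cavities <- list(
        list(cavity_id = 1L, atom_ids = 1:8, area = 250,
             residue_keys = resKeyVec(1:4)),
        list(cavity_id = 2L, atom_ids = c(3:6, 11:13), area = 120,
             residue_keys = resKeyVec(c(2, 3, 6, 7))),
        list(cavity_id = 3L, atom_ids = c(31L, 32L), area = 80,
             residue_keys = resKeyVec(16)))
    scores <- setNames(10 * (1:17), resKeyVec(1:17))
    et <- new("EtScoreTable", chainId = "A", scores = scores,
              coverage = 1)
    list(structure = structure, clusters = clusters,
         cavities = cavities, et = et)
}

resKeyVec <- function(resno) paste0(resno, ":")

# random cavity/cluster atom-set fixtures for association properties
randomAssociationFixture <- function(seed) {
    set.seed(seed)
    nC <- sample(1:6, 1)
    nK <- sample(1:6, 1)
    pool <- 1:60
    cavities <- lapply(seq_len(nC), function(i)
        list(cavity_id = i, area = runif(1, 10, 500),
             atom_ids = sort(sample(pool, sample(3:20, 1))),
             residue_keys = character()))
    clusters <- lapply(seq_len(nK), function(i)
        list(cluster_id = i - 1L,
             atom_ids = sort(sample(pool, sample(3:20, 1)))))
    list(cavities = cavities, clusters = clusters)
}

expectedTsv <- function(name) {
    path <- system.file("extdata", name, package = "CavityRigidity")
    read.table(path, sep = "\t", header = TRUE,
               stringsAsFactors = FALSE)
}
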