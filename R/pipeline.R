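# End-to-end orchestration over one chain or a batch: structure ->
# mechanical model -> rigid clusters -> cavities -> ET -> join metrics,
# with per-chain failure isolation (a chain that fails at any stage is
# recorded and skipped; the batch continues).

#' Survey configuration
#'
#' Single key-value configuration governing every cutoff of the pipeline;
#' the effective configuration is snapshotted into the run manifest.
#'
#' @param covalent_tolerance covalent-bond distance slack, angstrom.
#' @param hbond_max_da_dist hydrogen-bond donor-acceptor cutoff, angstrom.
#' @param hbond_min_dha_angle minimum donor-H-acceptor angle, degrees.
#' @param hydrophobic_cutoff hydrophobic surface-to-surface cutoff,
#'   angstrom.
#' @param bar_policy named vector: bars per hydrogen bond / hydrophobic
#'   contact.
#' @param probe molecular-surface probe radius, angstrom.
#' @param envelope_probe cavity envelope probe radius, angstrom.
#' @param spacing voxel spacing, angstrom.
#' @param min_area minimum cavity surface area, square angstrom.
#' @param margin grid margin, angstrom.
#' @return named list of settings.
#' @export
surveyConfig <- function(covalent_tolerance = 0.4,
                         hbond_max_da_dist = 3.5,
                         hbond_min_dha_angle = 120,
                         hydrophobic_cutoff = 0.25,
                         bar_policy = c(hydrogen_bond = 5,
                                        hydrophobic = 2),
                         probe = 1.4, envelope_probe = 8,
                         spacing = 0.5, min_area = 50, margin = 10) {
    list(covalent_tolerance = covalent_tolerance,
         hbond_max_da_dist = hbond_max_da_dist,
         hbond_min_dha_angle = hbond_min_dha_angle,
         hydrophobic_cutoff = hydrophobic_cutoff,
         bar_policy = bar_policy, probe = probe,
         envelope_probe = envelope_probe, spacing = spacing,
         min_area = min_area, margin = margin)
}

.stage <- function(name, expr) {
    tryCatch(list(ok = TRUE, value = expr),
             error = function(e)
                 list(ok = FALSE, stage = name,
                      message = conditionMessage(e)))
}

#' Run the full survey pipeline on one chain
#'
#' Executes structure reading, bond detection, mechanical-model
#' construction, pebble-game rigid-cluster decomposition, cavity
#' detection, optional ET parsing and the join metrics.  Artifacts
#' (clusters XML, SURF meshes, aggregate TSV/JSON) are written under
#' \code{outDir} when given; on failure, partial artifacts go to
#' \code{outDir/failed/}.
#'
#' @param pdbPath PDB file (or a \code{\linkS4class{ChainStructure}},
#'   bypassing the reader).
#' @param chainId chain identifier.
#' @param config from \code{\link{surveyConfig}}.
#' @param etPath optional ET ranks file; when absent the chain completes
#'   with ET fields missing.
#' @param outDir optional artifact directory.
#' @return list with \code{status} (\code{"ok"} or
#'   \code{"failed:<stage>"}), \code{cavityRecords},
#'   \code{clusterRecords}, \code{label}, and intermediate objects
#'   (\code{structure}, \code{model}, \code{decomp}, \code{cavities},
#'   \code{et}).
#' @export
runChain <- function(pdbPath, chainId = "A", config = surveyConfig(),
                     etPath = NULL, outDir = NULL) {
    t0 <- proc.time()[["elapsed"]]
    res <- list(status = "ok", cavityRecords = NULL,
                clusterRecords = NULL, label = NA_character_)
    fail <- function(st) {
        res$status <<- paste0("failed:", st$stage)
        res$error <<- st$message
        if (!is.null(outDir)) {
            dir.create(file.path(outDir, "failed"), recursive = TRUE,
                       showWarnings = FALSE)
        }
        res
    }

    st <- .stage("structure_io", {
        if (is(pdbPath, "ChainStructure")) pdbPath
        else readPdbChain(pdbPath, chainId)
    })
    if (!st$ok) return(fail(st))
    struct <- st$value
    res$structure <- struct
    res$label <- struct@sourceLabel

    st <- .stage("mechanical_model", {
        bonds <- detectCovalentBonds(struct,
                                     tolerance = config$covalent_tolerance)
        hb <- detectHydrogenBonds(struct,
                                  maxDaDist = config$hbond_max_da_dist,
                                  minDhaAngle = config$hbond_min_dha_angle,
                                  bonds = bonds)
        ph <- detectHydrophobicContacts(struct,
                                        cutoff = config$hydrophobic_cutoff,
                                        bonds = bonds)
        buildMechanicalModel(struct, rbind(bonds, hb, ph),
                             barPolicy = config$bar_policy)
    })
    if (!st$ok) return(fail(st))
    model <- st$value
    res$model <- model

    st <- .stage("rigidity_engine", {
        decomp <- pebbleGameDecompose(bodyBarGraph(model))
        clustersToAtoms(decomp, model)
    })
    if (!st$ok) return(fail(st))
    decomp <- st$value
    res$decomp <- decomp

    st <- .stage("cavity_finder", {
        surf <- computeMolecularSurface(struct, probe = config$probe,
                                        spacing = config$spacing,
                                        margin = config$margin)
        detectCavities(surf$grid, struct,
                       envelopeProbe = config$envelope_probe,
                       minArea = config$min_area, mesh = surf$mesh)
    })
    if (!st$ok) return(fail(st))
    cavities <- st$value
    res$cavities <- cavities

    et <- NULL
    if (!is.null(etPath) && !is.na(etPath) && nzchar(etPath)) {
        st <- .stage("et_scores",
                     readEtFile(etPath, chainId = chainId,
                                structure = struct))
        if (!st$ok) return(fail(st))
        et <- st$value
    }
    res$et <- et

    st <- .stage("join_metrics", {
        assoc <- associateCavities(cavities, decomp)
        list(assoc = assoc,
             cav = computeCavityRecords(assoc, cavities, decomp, et = et,
                                        chain = res$label),
             clu = computeClusterRecords(assoc, cavities, decomp,
                                         structure = struct, et = et,
                                         chain = res$label))
    })
    if (!st$ok) return(fail(st))
    res$cavityRecords <- st$value$cav
    res$clusterRecords <- st$value$clu

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeClusterXml(decomp, file.path(outDir,
                                          paste0(res$label,
                                                 "_clusters.xml")))
        for (cv in cavities)
            writeSurf(cv, file.path(outDir,
                                    sprintf("%s_cavity%03d.surf",
                                            res$label, cv@cavityId)))
        writeAggregates(res$cavityRecords,
                        file.path(outDir, paste0(res$label, "_cavities")))
        writeAggregates(res$clusterRecords,
                        file.path(outDir, paste0(res$label, "_clusters")))
    }
    res$elapsed <- proc.time()[["elapsed"]] - t0
    res
}

#' Run the survey over a batch of chains
#'
#' Independent per-chain runs with continue-on-error semantics; results
#' are identical whether executed serially or in parallel (forked
#' workers).  Produces a run manifest (one row per input chain with
#' status and timing), corpus-level concatenated records, and summary
#' counts.
#'
#' @param manifest data.frame with columns \code{pdb_path},
#'   \code{chain_id} and optionally \code{et_path}.
#' @param config from \code{\link{surveyConfig}}.
#' @param outDir optional artifact directory (one subdirectory per
#'   chain).
#' @param parallel fork-parallel execution via
#'   \code{parallel::mclapply}.
#' @param cores worker count when \code{parallel}.
#' @return list with \code{manifest} (statuses), \code{cavityRecords},
#'   \code{clusterRecords}, \code{summary}, \code{config}.
#' @export
runBatch <- function(manifest, config = surveyConfig(), outDir = NULL,
                     parallel = FALSE, cores = 2) {
    if (nrow(manifest) == 0) stop("empty manifest")
    if (is.null(manifest$et_path)) manifest$et_path <- NA_character_
    runOne <- function(i) {
        runChain(manifest$pdb_path[i], manifest$chain_id[i],
                 config = config, etPath = manifest$et_path[i],
                 outDir = if (is.null(outDir)) NULL else
                     file.path(outDir, sprintf("chain%04d", i)))
    }
    idx <- seq_len(nrow(manifest))
    results <- if (parallel)
        parallel::mclapply(idx, runOne, mc.cores = cores)
    else lapply(idx, runOne)
    status <- vapply(results, function(r)
        if (inherits(r, "try-error")) "failed:internal" else r$status, "")
    mf <- data.frame(pdb_path = as.character(manifest$pdb_path),
                     chain_id = manifest$chain_id,
                     et_path = manifest$et_path,
                     status = status,
                     message = vapply(results, function(r)
                         if (is.null(r$error)) "" else r$error, ""),
                     elapsed = vapply(results, function(r)
                         if (is.null(r$elapsed)) NA_real_ else r$elapsed,
                         1),
                     stringsAsFactors = FALSE)
    okRes <- results[status == "ok"]
    cav <- do.call(rbind, lapply(okRes, `[[`, "cavityRecords"))
    clu <- do.call(rbind, lapply(okRes, `[[`, "clusterRecords"))
    summary <- list(n_chains = nrow(manifest),
                    n_ok = sum(status == "ok"),
                    n_failed = sum(status != "ok"),
                    n_cavities = if (is.null(cav)) 0L else nrow(cav),
                    n_clusters = if (is.null(clu)) 0L else nrow(clu))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!is.null(cav))
            writeAggregates(cav, file.path(outDir, "corpus_cavities"))
        if (!is.null(clu))
            writeAggregates(clu, file.path(outDir, "corpus_clusters"))
        jsonlite::write_json(summary,
                             file.path(outDir, "corpus_summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(manifest = mf, cavityRecords = cav, clusterRecords = clu,
         summary = summary, config = config)
}
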