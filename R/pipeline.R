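# End-to-end orchestration: screen -> profile -> context -> tree ->
# metaprofile over a validated run configuration, writing one provenance-
# stamped table per stage.

.stageError <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full discovery-and-profiling pipeline
#'
#' Executes the stages in order (screen, profile, context, tree,
#' metaprofile) on either simulated inputs (when the configuration carries a
#' `simulate` section) or files referenced under `inputs`. Each stage writes
#' one TSV table (plus auxiliary artifacts such as the Newick tree) into the
#' output directory; every table starts with a provenance line carrying the
#' configuration fingerprint and seed. Any stage failure aborts the run
#' naming the stage and cause.
#'
#' @param config path to a YAML configuration or a configuration list
#'   (validated via [readRunConfig()]).
#' @param outDir output directory (overrides `output_dir` in the config).
#' @param stages which stages to run (default: all, in order).
#' @return invisibly, a named list of the stage table paths.
#' @export
runPipeline <- function(config, outDir = NULL,
                        stages = c("screen", "profile", "context", "tree",
                                   "metaprofile")) {
    cfg <- readRunConfig(config)
    outDir <- outDir %||% cfg$output_dir %||% stop("no output directory set")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    seed <- cfg$seed
    set.seed(seed)
    paths <- list()
    stamp <- function(df, file) {
        p <- file.path(outDir, file)
        writeStageTable(df, p, config = cfg, seed = seed)
        p
    }

    # ---- inputs (simulated or from disk) ----------------------------------
    if (!is.null(cfg$simulate)) {
        sp <- cfg$simulate$pangenome %||% list()
        des <- pangenomeDesign(
            nPositive = sp$n_positive %||% 3L,
            nNegative = sp$n_negative %||% 3L,
            nDecoys = sp$n_decoys %||% 10L,
            familyLength = sp$family_length %||% 240L,
            divergence = sp$divergence %||% 0.2,
            nMarkerProximal = sp$n_marker_proximal %||% 2L,
            nFusion = sp$n_fusion %||% 0L)
        sim <- .stageError("simulate",
            simulatePangenome(des, seed = childSeed(seed, 1),
                              dir = file.path(outDir, "inputs")))
        proteomes <- sim$proteomes
        phen <- sim$phenotype
        labels <- sim$labels
        genomes <- sim$genomes
        markerIds <- sim$members$gene_id[sim$members$family == "marker"]
    } else {
        inp <- cfg$inputs %||% stop("config needs either simulate or inputs")
        need <- c("proteome_dir", "phenotype")
        miss <- need[!vapply(inp[need], function(x)
            !is.null(x) && file.exists(x), TRUE)]
        if (length(miss))
            stop("missing input(s): ", paste(miss, collapse = ", "))
        phenDf <- readStageTable(inp$phenotype)
        phen <- stats::setNames(phenDf$phenotype, phenDf$genome)
        proteomes <- lapply(stats::setNames(nm = phenDf$genome), function(g)
            readProteinFasta(file.path(inp$proteome_dir,
                                       paste0(g, ".faa"))))
        labels <- if (!is.null(inp$labels)) readStageTable(inp$labels)
                  else data.frame(gene_id = character(), label = character())
        genomes <- NULL
        markerIds <- character()
        sim <- NULL
    }

    # ---- screen ------------------------------------------------------------
    candidates <- NULL; om <- NULL
    if ("screen" %in% stages) {
        res <- .stageError("screen", {
            om <- rbhOrthogroups(proteomes, phen,
                                 minBits = cfg$screen$min_bits,
                                 gapOpen = cfg$screen$gap_open,
                                 gapExtension = cfg$screen$gap_extend)
            cand <- phenotypeScreen(om)
            kept <- labelFilter(cand, om, labels,
                                targetLabel = cfg$screen$target_label)
            list(om = om, cand = cand, kept = kept)
        })
        om <- res$om; candidates <- res$kept
        tab <- data.frame(
            orthogroup = names(orthoMembers(om)),
            n_members = lengths(orthoMembers(om)),
            presence = apply(orthoPresence(om), 1L, paste, collapse = ""),
            concordant = names(orthoMembers(om)) %in% res$cand,
            selected = names(orthoMembers(om)) %in% res$kept,
            members = vapply(orthoMembers(om), paste, "", collapse = ","))
        paths$screen <- stamp(tab, "screen_candidates.tsv")
    }

    geneIdsOf <- function(og) sub("^.*\\|", "", orthoMembers(om)[[og]])
    allProts <- do.call(c, lapply(names(proteomes), function(g) {
        aa <- as.character(proteomes[[g]])
        stats::setNames(aa, names(proteomes[[g]]))
    }))

    # ---- profile -----------------------------------------------------------
    models <- list()
    if ("profile" %in% stages) {
        if (is.null(candidates) || !length(candidates))
            stop("stage 'profile' failed: no candidate orthogroups to model")
        hits <- .stageError("profile", {
            for (og in candidates) {
                fam <- allProts[geneIdsOf(og)]
                msa <- progressiveMSA(fam)
                tr <- trimMSA(msa, maxGapFrac = cfg$profile$max_gap_frac,
                              minLen = cfg$profile$min_len)
                hmm <- buildProfileHMM(tr$msa,
                                       alpha = cfg$profile$pseudocount,
                                       matchOccupancy = cfg$profile$match_occupancy,
                                       modelId = og)
                models[[og]] <- calibrateProfile(hmm,
                    nullN = cfg$profile$null_n,
                    seed = childSeed(seed, 2))
                writeProfileHMM(models[[og]],
                                file.path(outDir, paste0(og, ".hmm")))
            }
            searchProteins(models, allProts,
                           evalueCeiling = cfg$profile$evalue_ceiling)
        })
        paths$profile <- stamp(hits, "profile_hits.tsv")
        fus <- callFusions(hits)
        writeStageTable(fus, file.path(outDir, "fusions.tsv"),
                        config = cfg, seed = seed)
        if (nrow(fus))
            writeFasta(splitFusedDomains(allProts, fus),
                       file.path(outDir, "fusion_domains.faa"))
    }

    # ---- context -----------------------------------------------------------
    targetIds <- if (!is.null(candidates) && length(candidates))
        unlist(lapply(candidates, geneIdsOf)) else character()
    if ("context" %in% stages) {
        calls <- .stageError("context", {
            if (is.null(genomes))
                stop("context stage needs annotated genomes (simulate mode)")
            do.call(rbind, lapply(genomes, function(gn) {
                ids <- S4Vectors::mcols(genes(gn))$gene_id
                tg <- intersect(targetIds, ids)
                if (!length(tg)) return(NULL)
                classifyColocalization(gn, tg, intersect(markerIds, ids),
                                       windowGenes = cfg$context$window_genes,
                                       windowBp = cfg$context$window_bp)
            }))
        })
        paths$context <- stamp(calls, "context_calls.tsv")
        writeStageTable(copresenceSummary(calls),
                        file.path(outDir, "context_summary.tsv"),
                        config = cfg, seed = seed)
    }

    # ---- tree --------------------------------------------------------------
    if ("tree" %in% stages) {
        cl <- .stageError("tree", {
            fam <- allProts[targetIds]
            mk <- allProts[intersect(markerIds, names(allProts))]
            og <- if (!is.null(sim))
                allProts[sim$members$gene_id[sim$members$family == "core01"][1]]
            else fam[1]
            seqs <- c(fam, mk, og)
            msa <- progressiveMSA(seqs)
            d <- alignmentDistances(msa, maxDistance = cfg$tree$max_distance)
            tre <- njTree(d)
            ape::write.tree(tre, file.path(outDir, "family_tree.nwk"))
            anchors <- list(target = names(fam)[seq_len(min(2, length(fam)))])
            if (length(mk) >= 2)
                anchors$marker <- names(mk)[1:2]
            assignClades(tre, anchors, outgroup = names(og))
        })
        tab <- data.frame(leaf = names(cladeLabels(cl)),
                          clade = unname(cladeLabels(cl)))
        paths$tree <- stamp(tab, "tree_clades.tsv")
    }

    # ---- metaprofile -------------------------------------------------------
    if ("metaprofile" %in% stages) {
        tab <- .stageError("metaprofile", {
            smp <- cfg$simulate$metagenome %||% list()
            panelProt <- allProts[targetIds[seq_len(min(3, length(targetIds)))]]
            panel <- vapply(panelProt, reverseTranslate, "")
            names(panel) <- names(panelProt)
            groups <- smp$groups %||% c(female = 20L, male = 20L)
            groups <- stats::setNames(as.integer(groups), names(groups))
            carr <- matrix(c(rep(smp$carriage_a %||% 0.9, length(panel)),
                             rep(smp$carriage_b %||% 0.6, length(panel))),
                           ncol = 2,
                           dimnames = list(names(panel), names(groups)))
            des <- metagenomeDesign(groups = groups, carriage = carr,
                                    depth = smp$depth %||% 2e4,
                                    readLength = smp$read_length %||% 150L,
                                    errorProb = smp$error_prob %||% 0.005)
            simm <- simulateMetagenome(des, panel,
                                       seed = childSeed(seed, 3),
                                       output = "counts",
                                       k = cfg$metaprofile$k,
                                       theta = cfg$metaprofile$theta)
            sps <- profileSamples(simm$counts, simm$totals, simm$metadata,
                                  cpmThreshold = cfg$metaprofile$cpm_threshold,
                                  qcMinReads = cfg$metaprofile$qc_min_reads)
            genePrevalenceTests(sps, names(groups)[1], names(groups)[2],
                                correct = cfg$metaprofile$correct,
                                dropZeroCpm = cfg$metaprofile$drop_zero_cpm)
        })
        paths$metaprofile <- stamp(tab, "metaprofile_tests.tsv")
    }
    invisible(paths)
}
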