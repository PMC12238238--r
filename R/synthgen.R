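# Truth-tagged synthetic data: pangenomes with a planted phenotype-concordant
# family, clade-structured homolog families, and paired-group metagenomes.

#' @importFrom stats runif rbinom hclust as.dist setNames
NULL

# fixed codon per amino acid for deterministic reverse translation
.CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

randomProtein <- function(n) {
    paste(sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND),
          collapse = "")
}

# Independent per-site substitution: each site is replaced with probability p
# by a uniform draw among the 19 alternative residues.
mutateProtein <- function(x, p) {
    if (p <= 0) return(x)
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < p)
    if (length(hit)) {
        cur <- match(ch[hit], AA20)
        shift <- sample.int(19L, length(hit), replace = TRUE)
        ch[hit] <- AA20[(cur - 1L + shift) %% 20L + 1L]
    }
    paste(ch, collapse = "")
}

reverseTranslate <- function(protein) {
    ch <- strsplit(protein, "", fixed = TRUE)[[1]]
    paste0(paste(.CODON[ch], collapse = ""), "TAA")
}

#' Design of a synthetic pangenome screen
#'
#' Describes the truth structure of a simulated pangenome: how many
#' phenotype-positive and -negative genomes, one planted gene family whose
#' presence exactly matches the phenotype, decoy families that each violate
#' that pattern in at least one genome, core families present everywhere, a
#' marker family (an analog of the bile-acid-inducible operon genes) placed
#' next to the planted gene in a configurable subset of carriers, and
#' optional fused two-domain variants of the planted protein.
#'
#' @param nPositive,nNegative number of phenotype-positive/-negative genomes
#'   (both must be at least 1).
#' @param nDecoys number of decoy families.
#' @param nCore number of core families present in every genome.
#' @param familyLength ancestor length (residues) of the planted family.
#' @param divergence per-site substitution probability applied independently
#'   to every genome's copy of a family ancestor.
#' @param nMarkerProximal number of positive genomes in which the marker gene
#'   is placed immediately next to the planted gene; remaining positive
#'   genomes carry the marker on a separate contig.
#' @param nFusion number of positive genomes whose planted-family copy is
#'   fused at the C-terminus with a second (dehydrogenase-analog) domain.
#' @param fusionDomainLength length of the fused partner domain.
#' @param spacer intergenic spacer (bp) between tiled genes.
#' @param randomStrand place genes on random strands instead of all "+".
#' @return a `PangenomeDesign` list understood by [simulatePangenome()].
#' @export
pangenomeDesign <- function(nPositive = 3L, nNegative = 3L, nDecoys = 10L,
                            nCore = 3L, familyLength = 240L,
                            divergence = 0.2, nMarkerProximal = 2L,
                            nFusion = 0L, fusionDomainLength = 160L,
                            spacer = 200L, randomStrand = FALSE) {
    if (nPositive < 1L || nNegative < 1L)
        stop("at least one positive and one negative genome are required")
    stopifnot_scalar_prob(divergence, "divergence")
    if (nMarkerProximal > nPositive)
        stop("nMarkerProximal cannot exceed nPositive")
    if (nFusion > nPositive)
        stop("fusion carriers must be a subset of planted-family carriers")
    structure(list(nPositive = as.integer(nPositive),
                   nNegative = as.integer(nNegative),
                   nDecoys = as.integer(nDecoys),
                   nCore = as.integer(nCore),
                   familyLength = as.integer(familyLength),
                   divergence = divergence,
                   nMarkerProximal = as.integer(nMarkerProximal),
                   nFusion = as.integer(nFusion),
                   fusionDomainLength = as.integer(fusionDomainLength),
                   spacer = as.integer(spacer),
                   randomStrand = isTRUE(randomStrand)),
              class = "PangenomeDesign")
}

#' Simulate a truth-tagged pangenome
#'
#' Generates protein families and genome assemblies realising a
#' [pangenomeDesign()]: the planted family is present in exactly the
#' phenotype-positive genomes, every decoy family violates that pattern in at
#' least one genome, genes are tiled non-overlapping on contigs with fixed
#' intergenic spacers, and all output is deterministic under `seed`.
#'
#' @param design a `PangenomeDesign`.
#' @param seed integer seed; identical design + seed reproduce identical
#'   output (byte-identical files when `dir` is given).
#' @param dir optional output directory; per-genome nucleotide FASTA + GFF3,
#'   per-genome protein FASTA and truth/label TSV tables are written there.
#' @param nucleotide build contig sequences and gene coordinates (set to
#'   FALSE for protein-only work to save time).
#' @return a list with elements `genomes` (list of [AnnotatedGenome] when
#'   `nucleotide`, else NULL), `proteomes` (named list of `AAStringSet`),
#'   `phenotype`, `truth` (family table), `members` (gene-to-family table),
#'   `labels` (gene family-label table; planted members carry "OYE"),
#'   `markerProximal`, `fusionCarriers`, `design`, `seed`.
#' @export
simulatePangenome <- function(design, seed, dir = NULL, nucleotide = TRUE) {
    stopifnot(inherits(design, "PangenomeDesign"))
    set.seed(seed)
    ng <- design$nPositive + design$nNegative
    genomeIds <- c(sprintf("gpos%02d", seq_len(design$nPositive)),
                   sprintf("gneg%02d", seq_len(design$nNegative)))
    phen <- setNames(rep(c("positive", "negative"),
                         c(design$nPositive, design$nNegative)), genomeIds)
    phenInd <- as.integer(phen == "positive")

    famIds <- c("planted",
                if (design$nDecoys) sprintf("decoy%02d", seq_len(design$nDecoys)),
                if (design$nCore) sprintf("core%02d", seq_len(design$nCore)),
                "marker")
    famType <- c("planted", rep("decoy", design$nDecoys),
                 rep("core", design$nCore), "marker")

    # presence patterns
    pres <- matrix(0L, length(famIds), ng,
                   dimnames = list(famIds, genomeIds))
    pres["planted", ] <- phenInd
    for (i in seq_len(design$nDecoys)) {
        repeat {
            v <- rbinom(ng, 1L, 0.5)
            if (sum(v) > 0L && !identical(v, phenInd)) break
        }
        pres[1L + i, ] <- v
    }
    if (design$nCore)
        pres[famType == "core", ] <- 1L
    # marker: all positives plus the first negative, so it is deliberately
    # not phenotype-concordant
    pres["marker", ] <- pmax(phenInd,
                             as.integer(genomeIds == genomeIds[design$nPositive + 1L]))

    # ancestors (lengths vary a little across decoys for realism)
    lens <- setNames(integer(length(famIds)), famIds)
    lens["planted"] <- design$familyLength
    if (design$nDecoys)
        lens[famType == "decoy"] <- sample(180:300, design$nDecoys, replace = TRUE)
    if (design$nCore)
        lens[famType == "core"] <- sample(180:300, design$nCore, replace = TRUE)
    lens["marker"] <- 200L
    ancestors <- vapply(lens, randomProtein, "")
    fusionAncestor <- randomProtein(design$fusionDomainLength)

    markerProximal <- genomeIds[seq_len(design$nMarkerProximal)]
    fusionCarriers <- if (design$nFusion)
        genomeIds[seq_len(design$nFusion)] else character()

    proteomes <- list()
    members <- list()
    genomes <- if (nucleotide) list() else NULL
    for (gi in seq_along(genomeIds)) {
        gid <- genomeIds[gi]
        fams <- famIds[pres[, gi] == 1L]
        # deterministic shuffled gene order, marker kept adjacent to planted
        ord <- fams[sample.int(length(fams))]
        if (gid %in% markerProximal && all(c("planted", "marker") %in% fams)) {
            ord <- setdiff(ord, "marker")
            at <- match("planted", ord)
            ord <- append(ord, "marker", after = at)
        }
        onContig2 <- character()
        if (!gid %in% markerProximal && "marker" %in% fams &&
            "planted" %in% fams) {
            ord <- setdiff(ord, "marker")
            onContig2 <- "marker"
        }
        seqs <- vapply(c(ord, onContig2), function(f) {
            p <- mutateProtein(ancestors[[f]], design$divergence)
            if (f == "planted" && gid %in% fusionCarriers)
                p <- paste0(p, mutateProtein(fusionAncestor, design$divergence))
            p
        }, "")
        ids <- if (length(seqs)) sprintf("%s_g%02d", gid, seq_along(seqs))
               else character()
        aa <- Biostrings::AAStringSet(seqs)
        names(aa) <- ids
        proteomes[[gid]] <- aa
        members[[gid]] <- data.frame(genome = rep(gid, length(ids)),
                                     gene_id = ids,
                                     family = c(ord, onContig2))
        if (nucleotide) {
            ctgOf <- rep(c("contig1", "contig2"),
                         c(length(ord), length(onContig2)))
            nt <- vapply(seqs, reverseTranslate, "")
            ctgs <- character(); grl <- list()
            for (ct in unique(ctgOf)) {
                idx <- which(ctgOf == ct)
                pos <- 1L; parts <- character(); st <- integer(); en <- integer()
                for (j in idx) {
                    sp <- paste(sample(c("A", "C", "G", "T"), design$spacer,
                                       replace = TRUE), collapse = "")
                    parts <- c(parts, sp, nt[j])
                    st <- c(st, pos + design$spacer)
                    en <- c(en, pos + design$spacer + nchar(nt[j]) - 1L)
                    pos <- pos + design$spacer + nchar(nt[j])
                }
                parts <- c(parts, paste(sample(c("A", "C", "G", "T"),
                                               design$spacer, replace = TRUE),
                                        collapse = ""))
                ctgs[ct] <- paste(parts, collapse = "")
                strand <- if (design$randomStrand)
                    sample(c("+", "-"), length(idx), replace = TRUE)
                else rep("+", length(idx))
                grl[[ct]] <- GenomicRanges::GRanges(
                    seqnames = ct,
                    ranges = IRanges::IRanges(start = st, end = en),
                    strand = strand,
                    gene_id = ids[idx], protein = unname(seqs[idx]))
            }
            gr <- suppressWarnings(do.call(c, unname(grl)))
            genomes[[gid]] <- AnnotatedGenome(gid,
                Biostrings::DNAStringSet(ctgs), gr)
        }
    }
    members <- do.call(rbind, members)
    rownames(members) <- NULL
    truth <- data.frame(family = famIds, type = famType,
                        presence = apply(pres, 1L, paste, collapse = ""))
    labels <- data.frame(
        gene_id = members$gene_id[members$family == "planted"],
        label = "OYE")

    out <- list(genomes = genomes, proteomes = proteomes, phenotype = phen,
                truth = truth, presence = pres, members = members,
                labels = labels, markerProximal = markerProximal,
                fusionCarriers = fusionCarriers, design = design, seed = seed)
    class(out) <- "SyntheticPangenome"
    if (!is.null(dir)) writePangenome(out, dir)
    out
}

#' Clade-structured homolog family model
#'
#' A family of homologous proteins evolved along a small labelled tree by
#' independent per-site substitution (uniform choice among the 19 alternative
#' residues; no indels), with designated diagnostic columns that never mutate
#' and instead carry a fixed clade-specific residue in every leaf.
#'
#' @param tree an [ape::phylo] tree (or newick string); edge lengths are
#'   interpreted as per-branch, per-site substitution probabilities and must
#'   lie in `[0, 1)`.
#' @param cladeOf named character vector mapping every leaf to a clade label.
#' @param ancestor root protein sequence (string); defaults to a random
#'   background-frequency protein of length `ancestorLength`.
#' @param ancestorLength used when `ancestor` is NULL.
#' @param diagnosticColumns named list: column index (as name) -> named
#'   character vector clade -> residue.
#' @return a `FamilyModel` list for [simulateHomologFamily()].
#' @export
familyModel <- function(tree, cladeOf, ancestor = NULL,
                        ancestorLength = 300L, diagnosticColumns = list()) {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length))
        stop("tree must carry branch lengths (per-site substitution probabilities)")
    if (any(tree$edge.length < 0 | tree$edge.length >= 1))
        stop("per-branch substitution probabilities must lie in [0, 1)")
    if (!setequal(names(cladeOf), tree$tip.label))
        stop("cladeOf must label exactly the tree leaves")
    structure(list(tree = tree, cladeOf = cladeOf, ancestor = ancestor,
                   ancestorLength = as.integer(ancestorLength),
                   diagnosticColumns = diagnosticColumns),
              class = "FamilyModel")
}

#' Simulate a clade-labelled homolog family
#'
#' @param model a [familyModel()].
#' @param seed integer seed.
#' @return list with `sequences` (named `AAStringSet`, one per leaf),
#'   `clades` (named label vector) and `ancestor`.
#' @export
simulateHomologFamily <- function(model, seed) {
    stopifnot(inherits(model, "FamilyModel"))
    set.seed(seed)
    anc <- model$ancestor %||% randomProtein(model$ancestorLength)
    L <- nchar(anc)
    diagIdx <- as.integer(names(model$diagnosticColumns))
    if (length(diagIdx) && max(diagIdx) > L)
        stop("diagnostic column ", max(diagIdx),
             " is out of range for ancestor length ", L)
    tr <- model$tree
    nTip <- length(tr$tip.label)
    root <- nTip + 1L
    seqAt <- list(); seqAt[[root]] <- anc
    # preorder traversal over edges (ape edge matrix is parent, child)
    ord <- order(tr$edge[, 1L])
    edges <- tr$edge[ord, , drop = FALSE]
    elen <- tr$edge.length[ord]
    # walk edges repeatedly until all children are filled (tree is small)
    repeat {
        done <- TRUE
        for (i in seq_len(nrow(edges))) {
            p <- edges[i, 1L]; ch <- edges[i, 2L]
            if (is.null(seqAt[p][[1]]) || !is.null(seqAt[ch][[1]])) next
            seqAt[[ch]] <- mutateProtein(seqAt[[p]], elen[i])
            done <- FALSE
        }
        if (done) break
    }
    leaves <- vapply(seq_len(nTip), function(i) seqAt[[i]], "")
    names(leaves) <- tr$tip.label
    # pin diagnostic columns to the designed clade residues
    if (length(diagIdx)) {
        for (nm in names(leaves)) {
            ch <- strsplit(leaves[[nm]], "", fixed = TRUE)[[1]]
            lab <- model$cladeOf[[nm]]
            for (d in seq_along(diagIdx)) {
                res <- model$diagnosticColumns[[d]][[lab]]
                if (!is.null(res)) ch[diagIdx[d]] <- res
            }
            leaves[nm] <- paste(ch, collapse = "")
        }
        # keep the recorded ancestor consistent with non-mutating columns
        acs <- strsplit(anc, "", fixed = TRUE)[[1]]
        anc <- paste(acs, collapse = "")
    }
    aa <- Biostrings::AAStringSet(leaves)
    list(sequences = aa, clades = model$cladeOf[names(leaves)],
         ancestor = anc)
}

#' Design of a paired-group synthetic metagenome cohort
#'
#' Emulates a sex-stratified gut metagenome survey at reduced scale: two
#' sample groups, each biosample's source community carrying each panel gene
#' with a group-specific probability, uniform read sampling from the realised
#' community, and i.i.d. per-base substitution errors.
#'
#' @param groups named integer vector of biosample counts, e.g.
#'   `c(female = 60, male = 60)`.
#' @param carriage numeric matrix (genes x groups) of carriage
#'   probabilities, or a single probability recycled for all genes/groups.
#' @param depth reads per run.
#' @param readLength read length (bases).
#' @param errorProb per-base substitution error probability.
#' @param runsPerSample sequencing runs per biosample (counts are later
#'   summed per biosample).
#' @param relAbundance fraction of community bases contributed by each
#'   carried panel gene.
#' @param nBackground,backgroundLength background community genomes to
#'   generate when none are supplied.
#' @return a `MetagenomeDesign` list for [simulateMetagenome()].
#' @export
metagenomeDesign <- function(groups = c(female = 60L, male = 60L),
                             carriage, depth = 1e5, readLength = 150L,
                             errorProb = 0.005, runsPerSample = 1L,
                             relAbundance = 0.01, nBackground = 5L,
                             backgroundLength = 20000L) {
    if (length(groups) != 2L || is.null(names(groups)))
        stop("groups must be a named vector of two sample counts")
    if (depth <= 0) stop("depth must be positive")
    stopifnot_scalar_prob(errorProb, "errorProb")
    if (is.matrix(carriage)) {
        if (!all(colnames(carriage) == names(groups)))
            stop("carriage columns must match group names")
        if (any(carriage < 0 | carriage > 1))
            stop("carriage probabilities must lie in [0, 1]")
    } else {
        stopifnot_scalar_prob(carriage, "carriage")
    }
    structure(list(groups = groups, carriage = carriage, depth = depth,
                   readLength = as.integer(readLength),
                   errorProb = errorProb,
                   runsPerSample = as.integer(runsPerSample),
                   relAbundance = relAbundance,
                   nBackground = as.integer(nBackground),
                   backgroundLength = as.integer(backgroundLength)),
              class = "MetagenomeDesign")
}

.carriageMatrix <- function(design, geneNames) {
    if (is.matrix(design$carriage)) {
        m <- design$carriage
        if (is.null(rownames(m))) rownames(m) <- geneNames
        m[geneNames, names(design$groups), drop = FALSE]
    } else {
        matrix(design$carriage, length(geneNames), length(design$groups),
               dimnames = list(geneNames, names(design$groups)))
    }
}

randomGenome <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a paired-group metagenome cohort
#'
#' For every biosample the carried gene set is drawn per gene
#' (Bernoulli with the group's carriage probability), reads are then drawn
#' uniformly from the realised community (background genomes plus carried
#' panel genes at the designed relative abundance), and i.i.d. per-base
#' substitution errors are applied. Deterministic under `seed`.
#'
#' @param design a [metagenomeDesign()].
#' @param genePanel named `DNAStringSet` (or character vector) of panel gene
#'   nucleotide sequences; must be non-empty.
#' @param backgroundGenomes optional named `DNAStringSet` of community
#'   genomes; generated from the design when NULL.
#' @param seed integer seed.
#' @param output `"reads"` returns per-run read vectors (FASTQ-writable);
#'   `"counts"` skips read materialisation and returns per-run mapped-read
#'   counts directly (identical RNG stream, used for large sweeps).
#' @param k,theta,prefilter mapping parameters used when `output="counts"`
#'   (see [mapReads()]).
#' @param dir optional directory: writes one FASTQ per run plus
#'   `metadata.tsv` and `carriage_truth.tsv`.
#' @return list with `metadata` (run, biosample, group), `truth` (biosample,
#'   group, gene, carried), and either `reads` (named list per run) or
#'   `counts`/`totals` matrices, plus `panel` and `background`.
#' @export
simulateMetagenome <- function(design, genePanel, backgroundGenomes = NULL,
                               seed, output = c("reads", "counts"),
                               k = 21L, theta = 0.3, prefilter = TRUE,
                               dir = NULL) {
    stopifnot(inherits(design, "MetagenomeDesign"))
    output <- match.arg(output)
    if (length(genePanel) == 0L) stop("gene panel is empty")
    panel <- stats::setNames(as.character(genePanel), names(genePanel))
    if (is.null(names(panel)))
        names(panel) <- sprintf("gene%02d", seq_along(panel))
    set.seed(seed)
    if (is.null(backgroundGenomes)) {
        backgroundGenomes <- setNames(
            vapply(seq_len(design$nBackground), function(i)
                randomGenome(design$backgroundLength), ""),
            sprintf("bg%02d", seq_len(design$nBackground)))
    } else backgroundGenomes <- stats::setNames(
        as.character(backgroundGenomes), names(backgroundGenomes))
    if (design$readLength > min(nchar(c(panel, backgroundGenomes))))
        stop("read length exceeds the shortest source sequence")
    carr <- .carriageMatrix(design, names(panel))
    bgLen <- nchar(backgroundGenomes)

    groups <- rep(names(design$groups), design$groups)
    biosamples <- sprintf("%s_s%03d", groups,
                          unlist(lapply(design$groups, seq_len)))
    nRun <- design$runsPerSample
    meta <- data.frame(
        run = sprintf("%s_r%d", rep(biosamples, each = nRun),
                      rep(seq_len(nRun), length(biosamples))),
        biosample = rep(biosamples, each = nRun),
        group = rep(groups, each = nRun))
    truth <- list(); reads <- list()
    counts <- matrix(0L, length(panel), nrow(meta),
                     dimnames = list(names(panel), meta$run))
    totals <- setNames(rep(design$depth, nrow(meta)), meta$run)
    for (si in seq_along(biosamples)) {
        carried <- rbinom(length(panel), 1L, carr[, groups[si]]) == 1L
        truth[[si]] <- data.frame(biosample = biosamples[si],
                                  group = groups[si], gene = names(panel),
                                  carried = carried)
        src <- c(backgroundGenomes, panel[carried])
        pGene <- design$relAbundance
        nCar <- sum(carried)
        probs <- c(bgLen / sum(bgLen) * (1 - nCar * pGene),
                   rep(pGene, nCar))
        for (ri in seq_len(nRun)) {
            run <- meta$run[(si - 1L) * nRun + ri]
            if (output == "reads") {
                reads[[run]] <- cpp_sim_reads(src, probs,
                    as.integer(design$depth), design$readLength,
                    design$errorProb)
            } else {
                r <- cpp_sim_and_map(src, probs, as.integer(design$depth),
                    design$readLength, design$errorProb, panel,
                    as.integer(k), theta, isTRUE(prefilter))
                counts[, run] <- as.integer(r$counts)
            }
        }
    }
    truth <- do.call(rbind, truth)
    out <- list(metadata = meta, truth = truth,
                panel = panel, background = backgroundGenomes,
                design = design, seed = seed)
    if (output == "reads") out$reads <- reads
    else { out$counts <- counts; out$totals <- totals }
    class(out) <- "SyntheticMetagenome"
    if (!is.null(dir)) writeMetagenome(out, dir)
    out
}
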