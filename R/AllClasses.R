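#' @import methods
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet AAStringSet writeXStringSet
#'   readDNAStringSet readAAStringSet
NULL

#' Annotated bacterial genome
#'
#' Container for one genome assembly: its contig sequences plus an ordered
#' table of protein-coding genes. Coordinates are 1-based and inclusive (the
#' GFF3 convention); gene order on a contig is the order used for gene-rank
#' proximity distances.
#'
#' @slot genomeId single genome identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of contig sequences.
#' @slot genes a [GenomicRanges::GRanges] with one range per gene and
#'   metadata columns `gene_id` (unique within the genome) and `protein`
#'   (translated sequence, no stop symbol).
#'
#' @export
setClass("AnnotatedGenome",
    slots = c(genomeId = "character", contigs = "DNAStringSet",
              genes = "GRanges"))

setValidity("AnnotatedGenome", function(object) {
    g <- object@genes
    msg <- character()
    if (length(object@genomeId) != 1L)
        msg <- c(msg, "genomeId must be a single string")
    need <- c("gene_id", "protein")
    if (!all(need %in% colnames(mcols(g))))
        msg <- c(msg, "genes must carry gene_id and protein columns")
    else {
        if (anyDuplicated(mcols(g)$gene_id))
            msg <- c(msg, "gene_id values must be unique within a genome")
        sq <- as.character(seqnames(g))
        unknown <- setdiff(unique(sq), names(object@contigs))
        if (length(unknown))
            msg <- c(msg, paste0("genes placed on unknown contig(s): ",
                                 paste(unknown, collapse = ", ")))
        else if (length(g)) {
            lens <- width(object@contigs)[match(sq, names(object@contigs))]
            if (any(start(g) < 1L) || any(end(g) > lens) ||
                any(start(g) > end(g)))
                msg <- c(msg, "gene coordinates must satisfy 1 <= start <= end <= contig length")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn AnnotatedGenome constructor.
#' @param genomeId genome identifier.
#' @param contigs named `DNAStringSet` (or named character vector).
#' @param genes `GRanges` with `gene_id` and `protein` metadata columns.
#' @export
AnnotatedGenome <- function(genomeId, contigs, genes) {
    if (!is(contigs, "DNAStringSet")) contigs <- DNAStringSet(contigs)
    new("AnnotatedGenome", genomeId = genomeId, contigs = contigs,
        genes = genes)
}

#' @describeIn AnnotatedGenome the genome identifier.
#' @param x an `AnnotatedGenome`.
#' @export
genomeId <- function(x) x@genomeId

#' @describeIn AnnotatedGenome the gene table as a `GRanges`.
#' @export
genes <- function(x) x@genes

#' @describeIn AnnotatedGenome contig sequences.
#' @export
contigs <- function(x) x@contigs

#' @describeIn AnnotatedGenome proteins as a named `AAStringSet`.
#' @export
proteins <- function(x) {
    aa <- AAStringSet(mcols(x@genes)$protein)
    names(aa) <- mcols(x@genes)$gene_id
    aa
}

setMethod("show", "AnnotatedGenome", function(object) {
    cat("AnnotatedGenome", object@genomeId, "with",
        length(object@contigs), "contig(s) and",
        length(object@genes), "gene(s)\n")
})

#' Orthogroup presence/absence matrix
#'
#' Result of reciprocal-best-hit orthogroup clustering: which genes belong to
#' which orthogroup, the binary presence vector of each orthogroup across
#' genomes, and the phenotype label of each genome. The presence entry for a
#' genome is 1 exactly when at least one member gene comes from that genome
#' (same-genome paralogs count once).
#'
#' @slot presence integer matrix, orthogroups x genomes, values 0/1.
#' @slot members named list; per orthogroup a character vector of member
#'   genes encoded as `"genome|gene_id"`.
#' @slot phenotype named character vector over genomes, values
#'   `"positive"`/`"negative"`.
#'
#' @export
setClass("OrthoMatrix",
    slots = c(presence = "matrix", members = "list", phenotype = "character"))

setValidity("OrthoMatrix", function(object) {
    msg <- character()
    p <- object@presence
    if (!all(p %in% c(0L, 1L)))
        msg <- c(msg, "presence must be a 0/1 matrix")
    if (!identical(colnames(p), names(object@phenotype)))
        msg <- c(msg, "presence columns and phenotype names must agree in order")
    if (!all(object@phenotype %in% c("positive", "negative")))
        msg <- c(msg, "phenotype values must be 'positive' or 'negative'")
    if (!identical(rownames(p), names(object@members)))
        msg <- c(msg, "presence rows and members must agree in order")
    if (length(msg)) msg else TRUE
})

#' @describeIn OrthoMatrix presence/absence matrix (orthogroups x genomes).
#' @param x an `OrthoMatrix`.
#' @export
orthoPresence <- function(x) x@presence

#' @describeIn OrthoMatrix member genes per orthogroup
#'   (`"genome|gene_id"` encoding).
#' @export
orthoMembers <- function(x) x@members

#' @describeIn OrthoMatrix phenotype vector over genomes.
#' @export
phenotype <- function(x) x@phenotype

setMethod("show", "OrthoMatrix", function(object) {
    cat("OrthoMatrix:", nrow(object@presence), "orthogroup(s) x",
        ncol(object@presence), "genome(s) (",
        sum(object@phenotype == "positive"), "positive /",
        sum(object@phenotype == "negative"), "negative )\n")
})

#' Multiple protein sequence alignment
#'
#' A thin S4 wrapper around a character matrix (rows = sequences, columns =
#' alignment positions, gap symbol `"-"`).
#'
#' @slot aln character matrix with row names.
#' @slot fullLength named numeric: the unaligned residue count each row had
#'   when it entered the alignment (used by the trim length filter, so that
#'   trimming is idempotent).
#' @export
setClass("ProteinMSA", slots = c(aln = "matrix", fullLength = "numeric"))

setValidity("ProteinMSA", function(object) {
    a <- object@aln
    if (!is.character(a)) return("alignment must be a character matrix")
    if (is.null(rownames(a))) return("alignment rows must be named")
    ok <- a %in% AAGAP
    if (!all(ok)) return("alignment contains symbols outside the amino-acid alphabet")
    if (!setequal(names(object@fullLength), rownames(a)))
        return("fullLength must be named by the alignment rows")
    TRUE
})

#' @describeIn ProteinMSA constructor from a character matrix or a named
#'   character vector of equal-length aligned strings.
#' @param x matrix or named character vector of aligned sequences.
#' @param fullLength optional named original residue counts (defaults to the
#'   current ungapped row lengths).
#' @export
ProteinMSA <- function(x, fullLength = NULL) {
    if (is.character(x) && !is.matrix(x)) {
        if (length(unique(nchar(x))) != 1L)
            stop("aligned sequences must have equal length")
        x <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE)) |>
            `rownames<-`(names(x))
    }
    if (is.null(fullLength))
        fullLength <- stats::setNames(rowSums(x != "-"), rownames(x))
    new("ProteinMSA", aln = x, fullLength = fullLength[rownames(x)])
}

#' @describeIn ProteinMSA underlying character matrix.
#' @export
alnMatrix <- function(x) x@aln

#' @describeIn ProteinMSA aligned rows as strings.
#' @export
alnStrings <- function(x) apply(x@aln, 1L, paste, collapse = "")

#' @describeIn ProteinMSA per-column gap fraction.
#' @export
gapFraction <- function(x) colMeans(x@aln == "-")

setMethod("show", "ProteinMSA", function(object) {
    cat("ProteinMSA:", nrow(object@aln), "sequence(s) x",
        ncol(object@aln), "column(s)\n")
})

setMethod("nrow", "ProteinMSA", function(x) base::nrow(x@aln))
setMethod("ncol", "ProteinMSA", function(x) base::ncol(x@aln))

#' Profile hidden Markov model of a protein family
#'
#' Match/insert/delete parameterisation of a trimmed family alignment.
#' Emissions and transitions are probabilities (each distribution sums to 1);
#' scoring happens in log-odds space against the background. `columnMap`
#' records, for every match state, the corresponding residue position of the
#' chosen reference sequence (NA where the reference is gapped), so model
#' coordinates can be translated back to reference numbering. `calibration`
#' holds the location/scale of a Gumbel fitted to null scores (in bits), NA
#' before [calibrateProfile()] is run.
#'
#' @slot modelId model name.
#' @slot matchEmissions 20 x M matrix of match emission probabilities.
#' @slot insertEmissions background emission vector (length 20).
#' @slot transitions 7 x (M+1) matrix, rows MM, MI, MD, IM, II, DM, DD;
#'   column j holds the transitions leaving model column j (column 0 = begin,
#'   column M feeds the end state).
#' @slot background background residue frequencies (length 20).
#' @slot columnMap integer vector, match column -> reference residue position.
#' @slot calibration numeric, `c(mu, beta)` of the null Gumbel (bits), plus
#'   `nullLength` used.
#' @export
setClass("ProfileHMM",
    slots = c(modelId = "character", matchEmissions = "matrix",
              insertEmissions = "numeric", transitions = "matrix",
              background = "numeric", columnMap = "integer",
              calibration = "numeric"))

setValidity("ProfileHMM", function(object) {
    msg <- character()
    M <- ncol(object@matchEmissions)
    if (nrow(object@matchEmissions) != 20L)
        msg <- c(msg, "matchEmissions must have 20 rows")
    if (any(abs(colSums(object@matchEmissions) - 1) > 1e-9))
        msg <- c(msg, "match emission columns must sum to 1")
    if (abs(sum(object@insertEmissions) - 1) > 1e-9)
        msg <- c(msg, "insert emissions must sum to 1")
    tr <- object@transitions
    if (!identical(dim(tr), c(7L, M + 1L)))
        msg <- c(msg, "transitions must be 7 x (M+1)")
    else {
        for (j in seq_len(ncol(tr))) {
            sm <- sum(tr[c("MM", "MI", "MD"), j])
            si <- sum(tr[c("IM", "II"), j])
            sd <- sum(tr[c("DM", "DD"), j])
            if (abs(sm - 1) > 1e-9 || abs(si - 1) > 1e-9 ||
                (j > 1 && abs(sd - 1) > 1e-9)) {
                msg <- c(msg, "each outgoing transition set must sum to 1")
                break
            }
        }
    }
    cm <- object@columnMap[!is.na(object@columnMap)]
    if (length(cm) > 1L && any(diff(cm) <= 0))
        msg <- c(msg, "columnMap must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM number of match states.
#' @param x a `ProfileHMM`.
#' @export
modelLength <- function(x) ncol(x@matchEmissions)

#' @describeIn ProfileHMM match-column to reference-position map.
#' @export
columnMap <- function(x) x@columnMap

#' @describeIn ProfileHMM Gumbel calibration constants (bits), or NA.
#' @export
calibration <- function(x) x@calibration

setMethod("show", "ProfileHMM", function(object) {
    cal <- if (anyNA(object@calibration)) "uncalibrated"
           else sprintf("Gumbel mu=%.2f beta=%.2f bits",
                        object@calibration[["mu"]],
                        object@calibration[["beta"]])
    cat("ProfileHMM", object@modelId, "with", modelLength(object),
        "match states (", cal, ")\n")
})

#' Rooted clade-labelled phylogeny
#'
#' A rooted tree over family members together with the anchor-defined clade
#' label of every leaf. Labels are `"unassigned"` for leaves outside all
#' anchor clades (or inside overlapping claims) and `"outgroup"` for the
#' leaves used to root the tree.
#'
#' @slot tree an [ape::phylo] rooted tree with branch lengths.
#' @slot labels named character vector over all leaves.
#' @slot anchors named list, clade label -> anchor leaf ids.
#' @slot outgroup character vector of outgroup leaf ids.
#' @export
setClass("CladeTree",
    slots = c(tree = "ANY", labels = "character", anchors = "list",
              outgroup = "character"))

setValidity("CladeTree", function(object) {
    msg <- character()
    if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
    else {
        tips <- object@tree$tip.label
        if (!setequal(names(object@labels), tips))
            msg <- c(msg, "labels must cover exactly the tree leaves")
        if (!all(object@outgroup %in% tips))
            msg <- c(msg, "outgroup leaves must be in the tree")
        for (lab in names(object@anchors))
            if (!all(object@anchors[[lab]] %in% tips)) {
                msg <- c(msg, "anchor leaves must be in the tree"); break
            }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CladeTree the underlying rooted `phylo` tree.
#' @param x a `CladeTree`.
#' @export
cladeTreePhylo <- function(x) x@tree

#' @describeIn CladeTree named clade label per leaf.
#' @export
cladeLabels <- function(x) x@labels

setMethod("show", "CladeTree", function(object) {
    tab <- table(object@labels)
    cat("CladeTree with", length(object@tree$tip.label), "leaves:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Per-sample gene quantification profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with genes as rows and
#' biosamples as columns. Assays: `counts` (reads mapped per gene after
#' summing runs) and `cpm` (counts per million of the sample's total reads).
#' Column data: `biosample`, `group`, `total` (total reads across the
#' sample's runs) and `qc_pass` (total >= the QC minimum). A gene is called
#' present in a sample when its CPM is strictly greater than the presence
#' threshold recorded in the object metadata.
#'
#' @export
setClass("SampleProfileSet", contains = "SummarizedExperiment")

#' @describeIn SampleProfileSet counts-per-million assay.
#' @param x a `SampleProfileSet`.
#' @export
cpm <- function(x) SummarizedExperiment::assay(x, "cpm")

#' @describeIn SampleProfileSet logical presence matrix (CPM strictly above
#'   the presence threshold).
#' @export
presenceCalls <- function(x) {
    thr <- S4Vectors::metadata(x)$cpm_threshold
    cpm(x) > thr
}

#' @describeIn SampleProfileSet logical QC flag per sample.
#' @export
qcPass <- function(x) SummarizedExperiment::colData(x)$qc_pass

#' @describeIn SampleProfileSet group label per sample.
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group
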