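# Phenotype-concordant orthogroup screen: all-vs-all global protein
# alignment, reciprocal-best-hit orthogroups, presence/absence filtering and
# family-label filtering of the candidates.

#' Global protein alignment score
#'
#' Needleman-Wunsch alignment with affine gap penalties (a gap of length L
#' costs `gapOpen + gapExtension * L`, the Biostrings convention) over
#' BLOSUM62; `X` is scored 0 against everything. The score is symmetric in
#' its arguments. Bit scores use the ungapped BLOSUM62 Karlin-Altschul
#' parameters (lambda = 0.267, K = 0.041), which is the conventional
#' raw-to-bit mapping for this matrix.
#'
#' @param a,b protein sequences (strings; standard alphabet plus X).
#' @param gapOpen,gapExtension affine gap penalties.
#' @return list with `raw` and `bits`.
#' @export
#' @examples
#' alignScore("ACDEF", "ACDEF")$raw  # 30: sum of BLOSUM62 diagonal scores
alignScore <- function(a, b, gapOpen = 11, gapExtension = 1) {
    if (!nzchar(a) && !nzchar(b))
        stop("sequences must be non-empty")
    raw <- cpp_affine_global(encodeProtein(a, "sequence a"),
                             encodeProtein(b, "sequence b"),
                             blosumMatrix(), gapOpen, gapExtension)
    list(raw = raw, bits = rawToBits(raw))
}

rawToBits <- function(raw) {
    (BLOSUM62_LAMBDA * raw - log(BLOSUM62_K)) / log(2)
}

# score matrix between two proteomes (rows = A, cols = B)
.scoreMatrix <- function(aaA, aaB, gapOpen, gapExtension) {
    encA <- lapply(as.character(aaA), encodeProtein)
    encB <- lapply(as.character(aaB), encodeProtein)
    m <- cpp_align_score_matrix(encA, encB, blosumMatrix(),
                                gapOpen, gapExtension)
    dimnames(m) <- list(names(aaA), names(aaB))
    m
}

# best hit per row with deterministic tie-breaking: higher raw score, then
# lexicographically smaller target gene id
.bestHits <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
        row <- stats::setNames(m[i, ], colnames(m))
        best <- which(row == max(row))
        names(best)[order(names(best))][1]
    }, "")
}

#' Reciprocal-best-hit orthogroups
#'
#' All proteome pairs are compared by global affine-gap alignment; a pair of
#' genes from two genomes forms an edge when each is the other's best hit in
#' that genome pair and the alignment reaches `minBits`. Orthogroups are the
#' connected components of the resulting graph; genes without any edge
#' become singleton orthogroups. Same-genome paralogs inside a component
#' count once towards the genome's presence entry.
#'
#' @param proteomes named list (genome id -> named `AAStringSet`).
#' @param phenotype named character vector over the same genomes with values
#'   `"positive"`/`"negative"`.
#' @param minBits bit-score floor for an orthology edge.
#' @param gapOpen,gapExtension affine gap penalties.
#' @return an [OrthoMatrix].
#' @export
rbhOrthogroups <- function(proteomes, phenotype, minBits = 50,
                           gapOpen = 11, gapExtension = 1) {
    if (length(proteomes) < 2L)
        stop("at least two genomes are required")
    empty <- names(proteomes)[lengths(proteomes) == 0L]
    if (length(empty))
        stop("empty proteome(s): ", paste(empty, collapse = ", "))
    if (!setequal(names(proteomes), names(phenotype)))
        stop("phenotype must be named by the same genomes as proteomes")
    genomes <- names(proteomes)
    phenotype <- phenotype[genomes]
    minRaw <- (minBits * log(2) + log(BLOSUM62_K)) / BLOSUM62_LAMBDA

    node <- function(g, id) paste0(g, "|", id)
    allNodes <- unlist(lapply(genomes, function(g)
        node(g, names(proteomes[[g]]))), use.names = FALSE)
    edges <- list()
    for (i in seq_along(genomes)[-length(genomes)]) {
        for (j in seq.int(i + 1L, length(genomes))) {
            gA <- genomes[i]; gB <- genomes[j]
            m <- .scoreMatrix(proteomes[[gA]], proteomes[[gB]],
                              gapOpen, gapExtension)
            bestAB <- .bestHits(m)           # per gene of A
            bestBA <- .bestHits(t(m))        # per gene of B
            idxA <- seq_len(nrow(m))
            recip <- bestBA[match(bestAB, colnames(m))] == rownames(m)[idxA]
            keep <- recip & m[cbind(idxA, match(bestAB, colnames(m)))] >= minRaw
            if (any(keep))
                edges[[paste(gA, gB)]] <- data.frame(
                    from = node(gA, rownames(m)[idxA][keep]),
                    to = node(gB, bestAB[keep]))
        }
    }
    comp <- if (length(edges)) {
        ed <- do.call(rbind, edges)
        g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                           vertices = allNodes)
        igraph::components(g)$membership
    } else setNames(seq_along(allNodes), allNodes)
    comp <- comp[allNodes]
    membersList <- split(allNodes, comp)
    # deterministic orthogroup order: by sorted member ids
    membersList <- lapply(membersList, sort)
    membersList <- membersList[order(vapply(membersList, `[`, "", 1L))]
    names(membersList) <- sprintf("OG%04d", seq_along(membersList))
    pres <- t(vapply(membersList, function(mem) {
        gs <- sub("\\|.*$", "", mem)
        as.integer(genomes %in% gs)
    }, integer(length(genomes))))
    colnames(pres) <- genomes
    new("OrthoMatrix", presence = pres, members = membersList,
        phenotype = phenotype)
}

#' Phenotype-concordance screen
#'
#' Selects exactly the orthogroups present in every phenotype-positive
#' genome and absent from every phenotype-negative genome, in deterministic
#' (orthogroup id) order.
#'
#' @param om an [OrthoMatrix].
#' @return character vector of candidate orthogroup ids.
#' @export
phenotypeScreen <- function(om) {
    phen <- phenotype(om)
    if (!any(phen == "positive") || !any(phen == "negative"))
        stop("phenotype must contain at least one genome of each class")
    p <- orthoPresence(om)
    target <- as.integer(phen == "positive")
    hits <- apply(p, 1L, function(v) all(v == target))
    rownames(p)[hits]
}

#' Filter candidate orthogroups by family label
#'
#' Keeps the candidates with at least one member gene carrying the target
#' family label (e.g. the Old Yellow Enzyme annotation used to narrow the
#' reductase search space). Genes missing from the label table are treated
#' as unlabelled.
#'
#' @param candidates orthogroup ids (from [phenotypeScreen()]).
#' @param om the [OrthoMatrix] the candidates came from.
#' @param labels data.frame with columns `gene_id`, `label`.
#' @param targetLabel label to require.
#' @return filtered character vector of orthogroup ids.
#' @export
labelFilter <- function(candidates, om, labels, targetLabel = "OYE") {
    if (!all(c("gene_id", "label") %in% colnames(labels)))
        stop("labels must have gene_id and label columns")
    keep <- vapply(candidates, function(og) {
        ids <- sub("^.*\\|", "", orthoMembers(om)[[og]])
        any(labels$label[match(ids, labels$gene_id)] == targetLabel,
            na.rm = TRUE)
    }, TRUE)
    candidates[keep]
}
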