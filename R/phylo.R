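# Distance phylogenetics over family members: Poisson-corrected alignment
# distances, neighbor joining, anchor-defined clade assignment, per-clade
# residue frequencies at mapped reference positions, and Fitch parsimony
# ancestral states.

#' Poisson-corrected distances from an alignment
#'
#' The raw dissimilarity `p` of a sequence pair is the fraction of differing
#' residues over the columns where both are ungapped; the reported distance
#' is `-ln(1 - p)` (single-rate Poisson correction), capped at `maxDistance`
#' so saturated pairs stay finite.
#'
#' @param msa a [ProteinMSA].
#' @param maxDistance distance cap for saturated pairs.
#' @return symmetric distance matrix with zero diagonal.
#' @export
alignmentDistances <- function(msa, maxDistance = 5) {
    a <- alnMatrix(msa)
    n <- nrow(a)
    d <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
    for (i in seq_len(max(0L, n - 1L))) {
        for (j in seq.int(i + 1L, n)) {
            ok <- a[i, ] != "-" & a[j, ] != "-"
            p <- if (!any(ok)) 1 else mean(a[i, ok] != a[j, ok])
            dist <- if (p >= 1 - exp(-maxDistance)) maxDistance
                    else -log(1 - p)
            d[i, j] <- d[j, i] <- dist
        }
    }
    d
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration. Ties in the Q criterion are
#' broken by the lowest (row, column) index pair so the result is
#' deterministic; negative branch lengths are clamped to zero with the
#' deficit shifted to the sister edge. The returned tree is unrooted (a
#' trifurcation at the last three clusters).
#'
#' @param d symmetric numeric matrix with zero diagonal and row/col names
#'   (>= 3 taxa).
#' @return an [ape::phylo] tree with branch lengths.
#' @export
njTree <- function(d) {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("distance input must be a square matrix")
    if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance diagonal must be zero")
    n <- nrow(d)
    if (n < 3L) stop("at least three taxa are required")
    if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
        sprintf("t%d", seq_len(n))
    lab <- rownames(d)

    clamp2 <- function(li, lj) {
        if (li < 0) { lj <- lj + li; li <- 0 }
        if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
        c(li, lj)
    }
    nodes <- as.list(lab)   # newick fragment per active cluster
    D <- d
    while (length(nodes) > 3L) {
        m <- length(nodes)
        r <- rowSums(D)
        Q <- (m - 2) * D - outer(r, r, `+`)
        diag(Q) <- Inf
        # lowest (row, col) pair among the minima, scanning i<j
        best <- c(NA_integer_, NA_integer_); bq <- Inf
        for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m))
            if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
        i <- best[1]; j <- best[2]
        li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
        lj <- D[i, j] - li
        ll <- clamp2(li, lj)
        newNode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]], ll[1],
                           nodes[[j]], ll[2])
        dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(m), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                    c(dk[keep], 0))
        nodes <- c(nodes[keep], newNode)
        D <- D2
    }
    d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
    x <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
           (d13 + d23 - d12) / 2)
    x <- pmax(x, 0)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[[1]], x[1],
                   nodes[[2]], x[2], nodes[[3]], x[3])
    ape::read.tree(text = nwk)
}

#' Assign anchor-defined clades on a rooted tree
#'
#' The tree is rooted on the outgroup edge; each label's clade is the
#' smallest rooted clade containing all of that label's anchors. Leaves
#' falling inside exactly one labelled clade inherit its label; leaves in
#' nested or overlapping claims, or outside every clade, become
#' `"unassigned"` (anchors always retain their own label); outgroup leaves
#' are labelled `"outgroup"`.
#'
#' @param tree an unrooted or rooted [ape::phylo].
#' @param anchors named list: clade label -> anchor leaf ids.
#' @param outgroup non-empty leaf set used for rooting, disjoint from all
#'   anchors.
#' @return a [CladeTree].
#' @export
assignClades <- function(tree, anchors, outgroup) {
    stopifnot(inherits(tree, "phylo"))
    if (!length(outgroup)) stop("outgroup must be non-empty")
    tips <- tree$tip.label
    if (!all(outgroup %in% tips)) stop("outgroup leaves not in tree")
    if (any(outgroup %in% unlist(anchors)))
        stop("outgroup must be disjoint from anchors")
    for (lab in names(anchors))
        if (!all(anchors[[lab]] %in% tips))
            stop("anchor leaves of '", lab, "' not in tree")
    rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    ntip <- length(rooted$tip.label)
    rootNode <- ntip + 1L
    cladeTips <- list()
    for (lab in names(anchors)) {
        anc <- anchors[[lab]]
        if (length(anc) == 1L) {
            cladeTips[[lab]] <- anc
        } else {
            mrca <- ape::getMRCA(rooted, anc)
            if (mrca == rootNode)
                stop("anchors of '", lab,
                     "' are not monophyletic under this rooting")
            cladeTips[[lab]] <- ape::extract.clade(rooted, mrca)$tip.label
        }
    }
    claims <- vapply(rooted$tip.label, function(tp)
        sum(vapply(cladeTips, function(ct) tp %in% ct, TRUE)), 0L)
    labels <- rep("unassigned", ntip)
    names(labels) <- rooted$tip.label
    for (lab in names(cladeTips))
        labels[cladeTips[[lab]]][claims[cladeTips[[lab]]] == 1L] <- lab
    for (lab in names(anchors)) labels[anchors[[lab]]] <- lab
    labels[outgroup] <- "outgroup"
    new("CladeTree", tree = rooted, labels = labels,
        anchors = anchors, outgroup = outgroup)
}

#' Map reference residue positions to alignment columns
#'
#' Translates positions in the reference sequence's own residue numbering
#' (e.g. the catalytic positions 166, 167, 171, 253) into columns of the
#' alignment, skipping over reference gaps.
#'
#' @param msa a [ProteinMSA].
#' @param refId reference row id.
#' @param positions integer positions in reference coordinates (strictly
#'   increasing).
#' @return data.frame `position`, `column`.
#' @export
mapReferencePositions <- function(msa, refId, positions) {
    a <- alnMatrix(msa)
    if (!refId %in% rownames(a)) stop("reference '", refId, "' not in alignment")
    if (is.unsorted(positions, strictly = TRUE))
        stop("positions must be strictly increasing")
    refrow <- a[refId, ]
    respos <- cumsum(refrow != "-")
    cols <- vapply(positions, function(p) {
        w <- which(respos == p & refrow != "-")
        if (!length(w)) stop("reference position ", p,
                             " is beyond the reference length")
        w[1]
    }, 0L)
    data.frame(position = positions, column = cols)
}

#' Per-clade residue frequencies at mapped positions
#'
#' @param msa a [ProteinMSA] over the clade-labelled sequences.
#' @param residueMap data.frame from [mapReferencePositions()].
#' @param labels named clade label per sequence; `"unassigned"` and
#'   `"outgroup"` rows are excluded.
#' @return named list (clade) of matrices (symbols x positions) of
#'   frequencies over the 20 residues, X and the gap symbol, normalised per
#'   clade and position.
#' @export
columnFrequencies <- function(msa, residueMap, labels) {
    a <- alnMatrix(msa)
    labels <- labels[rownames(a)]
    use <- !labels %in% c("unassigned", "outgroup") & !is.na(labels)
    clades <- unique(labels[use])
    out <- list()
    for (cl in clades) {
        rows <- rownames(a)[use & labels == cl]
        if (!length(rows)) stop("clade '", cl, "' is empty")
        freq <- vapply(residueMap$column, function(cc) {
            tab <- tabulate(match(a[rows, cc], AAGAP), length(AAGAP))
            tab / sum(tab)
        }, numeric(length(AAGAP)))
        dimnames(freq) <- list(AAGAP, as.character(residueMap$position))
        out[[cl]] <- freq
    }
    out
}

#' Fitch parsimony ancestral states
#'
#' Two-pass Fitch parsimony on a rooted binary tree. The upward pass builds
#' preliminary state sets (score = number of union events, the parsimony
#' score); the downward pass refines them to the states each internal node
#' takes in at least one most-parsimonious reconstruction.
#'
#' @param tree rooted binary [ape::phylo] (e.g. from a [CladeTree]).
#' @param states named character vector (one column) or a matrix
#'   (leaves x columns) of leaf states; every leaf needs a state. Gaps are a
#'   legitimate 21st state.
#' @return list with `score` (per column) and `sets` (per column: list of
#'   state sets keyed by internal-node postorder index).
#' @export
fitchAncestral <- function(tree, states) {
    stopifnot(inherits(tree, "phylo"))
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
    if (!ape::is.binary(tree)) stop("tree must be binary")
    if (is.vector(states)) states <- matrix(states, ncol = 1,
                                            dimnames = list(names(states)))
    missing <- setdiff(tree$tip.label, rownames(states))
    if (length(missing))
        stop("missing leaf state(s): ", paste(missing, collapse = ", "))
    ntip <- length(tree$tip.label)
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    nnode <- ntip + tree$Nnode
    # postorder index of internal nodes (order of completion in the up pass)
    internalPost <- unique(edges[, 1L])
    scores <- integer(ncol(states))
    setsPerCol <- vector("list", ncol(states))
    for (col in seq_len(ncol(states))) {
        B <- vector("list", nnode)
        for (i in seq_len(ntip))
            B[[i]] <- states[tree$tip.label[i], col]
        sc <- 0L
        for (nd in internalPost) {
            ch <- edges[edges[, 1L] == nd, 2L]
            s <- B[[ch[1]]]
            for (c2 in ch[-1]) {
                inter <- intersect(s, B[[c2]])
                if (length(inter)) s <- inter
                else { s <- union(s, B[[c2]]); sc <- sc + 1L }
            }
            B[[nd]] <- s
        }
        # down pass (most-parsimonious reconstruction sets)
        Fset <- vector("list", nnode)
        root <- internalPost[length(internalPost)]
        Fset[[root]] <- B[[root]]
        for (nd in rev(internalPost)) {
            ch <- edges[edges[, 1L] == nd, 2L]
            for (v in ch) {
                if (v <= ntip) { Fset[[v]] <- B[[v]]; next }
                vch <- edges[edges[, 1L] == v, 2L]
                up <- B[[v]]
                fu <- Fset[[nd]]
                if (all(fu %in% up)) {
                    Fset[[v]] <- fu
                } else if (length(intersect(B[[vch[1]]], B[[vch[2]]]))) {
                    Fset[[v]] <- union(up, intersect(fu, union(B[[vch[1]]],
                                                               B[[vch[2]]])))
                } else {
                    Fset[[v]] <- union(up, fu)
                }
            }
        }
        names(Fset) <- NULL
        scores[col] <- sc
        res <- Fset[internalPost]
        names(res) <- as.character(seq_along(internalPost))
        setsPerCol[[col]] <- res
    }
    list(score = scores, sets = setsPerCol)
}
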