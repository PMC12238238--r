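# Progressive multiple alignment (k-mer guide tree + profile-profile affine
# DP) and alignment trimming.

.kmerCounts <- function(x, k = 3L) {
    n <- nchar(x)
    if (n < k) return(table(character()))
    table(substring(x, seq_len(n - k + 1L), seq.int(k, n)))
}

# fractional common k-mer distance between unaligned sequences
.kmerDistance <- function(seqs, k = 3L) {
    n <- length(seqs)
    counts <- lapply(seqs, .kmerCounts, k = k)
    lens <- nchar(seqs)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            common <- sum(pmin(
                counts[[i]][intersect(names(counts[[i]]), names(counts[[j]]))],
                counts[[j]][intersect(names(counts[[i]]), names(counts[[j]]))]))
            denom <- max(1L, min(lens[i], lens[j]) - k + 1L)
            d[i, j] <- d[j, i] <- 1 - common / denom
        }
    }
    d
}

.colCounts <- function(aln) {
    # 22 x L counts over AAGAP (X = row 21, gap = row 22)
    apply(aln, 2L, function(col) tabulate(match(col, AAGAP), 22L))
}

.mergeAlignments <- function(alnA, alnB, S22, gapOpen, gapExtension) {
    ca <- .colCounts(alnA); cb <- .colCounts(alnB)
    if (!is.matrix(ca)) ca <- matrix(ca, nrow = 22L)
    if (!is.matrix(cb)) cb <- matrix(cb, nrow = 22L)
    ops <- cpp_profile_align(ca, cb, S22, gapOpen, gapExtension,
                            nrow(alnA), nrow(alnB))
    nc <- length(ops)
    out <- matrix("-", nrow(alnA) + nrow(alnB), nc,
                  dimnames = list(c(rownames(alnA), rownames(alnB)), NULL))
    ia <- 0L; ib <- 0L
    for (p in seq_len(nc)) {
        if (ops[p] != 3L) { ia <- ia + 1L; out[seq_len(nrow(alnA)), p] <- alnA[, ia] }
        if (ops[p] != 2L) { ib <- ib + 1L
            out[nrow(alnA) + seq_len(nrow(alnB)), p] <- alnB[, ib] }
    }
    out
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by average-linkage clustering of fractional common
#' k-mer distances, then merges alignments along the tree with
#' profile-profile global alignment under affine gap penalties (column pair
#' score = average pairwise BLOSUM62 score; gaps score 0). With two
#' sequences this reduces exactly to pairwise global alignment. The result
#' is deterministic for a fixed input order.
#'
#' @param seqs named `AAStringSet` or named character vector (>= 1 sequence).
#' @param gapOpen,gapExtension affine gap penalties.
#' @param k k-mer size for the guide distances.
#' @return a [ProteinMSA].
#' @export
progressiveMSA <- function(seqs, gapOpen = 11, gapExtension = 1, k = 3L) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm %||% sprintf("seq%d", seq_along(seqs))
    if (length(seqs) == 0L) stop("no sequences to align")
    if (length(seqs) == 1L) {
        warning("single sequence: returning a one-row alignment")
        return(ProteinMSA(seqs))
    }
    rows <- lapply(seqs, function(s) {
        m <- matrix(strsplit(toupper(s), "", fixed = TRUE)[[1]], nrow = 1L)
        m
    })
    S22 <- blosumMatrixGapped()
    if (length(seqs) == 2L) {
        aln <- .mergeAlignments(
            `rownames<-`(rows[[1]], names(seqs)[1]),
            `rownames<-`(rows[[2]], names(seqs)[2]),
            S22, gapOpen, gapExtension)
        return(ProteinMSA(aln))
    }
    d <- .kmerDistance(seqs, k = k)
    hc <- hclust(as.dist(d), method = "average")
    partial <- list()
    for (m in seq_len(nrow(hc$merge))) {
        pick <- function(idx) {
            if (idx < 0) `rownames<-`(rows[[-idx]], names(seqs)[-idx])
            else partial[[idx]]
        }
        partial[[m]] <- .mergeAlignments(pick(hc$merge[m, 1L]),
                                         pick(hc$merge[m, 2L]),
                                         S22, gapOpen, gapExtension)
    }
    aln <- partial[[nrow(hc$merge)]]
    ProteinMSA(aln[names(seqs)[names(seqs) %in% rownames(aln)], ,
                   drop = FALSE])
}

#' Trim a family alignment
#'
#' Reproduces the alignment hygiene of the family-modelling stage: sequences
#' whose (original, unaligned) length is below `minLen` are excluded first;
#' columns outside the reference-coordinate `domainWindow` are dropped; and
#' columns whose gap fraction is strictly greater than `maxGapFrac` are
#' removed (a column at exactly the threshold is retained). Trimming is
#' idempotent because the length filter uses the lengths recorded when the
#' sequences entered the alignment.
#'
#' @param msa a [ProteinMSA].
#' @param domainWindow optional `c(start, end)` interval in reference
#'   residue coordinates delimiting the modelled domain.
#' @param maxGapFrac gap-fraction ceiling (strict inequality removes).
#' @param minLen minimum unaligned sequence length to keep a row.
#' @param refId reference row for `domainWindow` (default: first row).
#' @return list with `msa` (trimmed [ProteinMSA]) and `excluded` (ids of
#'   length-filtered sequences).
#' @export
trimMSA <- function(msa, domainWindow = NULL, maxGapFrac = 0.95,
                    minLen = 0L, refId = NULL) {
    stopifnot(is(msa, "ProteinMSA"))
    aln <- alnMatrix(msa)
    fl <- msa@fullLength
    excluded <- rownames(aln)[fl[rownames(aln)] < minLen]
    aln <- aln[setdiff(rownames(aln), excluded), , drop = FALSE]
    if (nrow(aln) == 0L) stop("no sequences left after the length filter")
    if (!is.null(domainWindow)) {
        refId <- refId %||% rownames(aln)[1]
        if (!refId %in% rownames(aln))
            stop("reference sequence '", refId, "' not in alignment")
        refpos <- cumsum(aln[refId, ] != "-")
        refpos[aln[refId, ] == "-"] <- NA
        if (domainWindow[2] > max(refpos, na.rm = TRUE))
            stop("domain window exceeds the reference length")
        keep <- !is.na(refpos) & refpos >= domainWindow[1] &
                refpos <= domainWindow[2]
        # retain interior columns where the reference is gapped
        rng <- range(which(keep))
        keep[seq.int(rng[1], rng[2])] <- TRUE
        aln <- aln[, keep, drop = FALSE]
    }
    gapfrac <- colMeans(aln == "-")
    aln <- aln[, gapfrac <= maxGapFrac + 1e-12, drop = FALSE]
    if (ncol(aln) == 0L) stop("alignment window is empty after trimming")
    list(msa = ProteinMSA(aln, fullLength = fl[rownames(aln)]),
         excluded = excluded)
}
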