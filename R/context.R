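# Genomic-context classification: is a target gene near a marker gene
# (operon-scale colocalization), merely in the same genome, or is the marker
# absent?

#' Classify target/marker colocalization in a genome
#'
#' A target is `proximal` when some marker lies on the same contig within
#' `windowGenes` intervening genes OR within `windowBp` base pairs (either
#' condition suffices; distances are measured between nearest feature edges
#' and ignore strand). Otherwise it is `same_genome` when the genome carries
#' a marker anywhere else, and `absent` when no marker was found at all.
#'
#' @param genome an [AnnotatedGenome].
#' @param targets gene ids of target-family hits in this genome.
#' @param markers gene ids of marker-family hits in this genome.
#' @param windowGenes gene-rank window (number of intervening genes allowed).
#' @param windowBp base-pair window between feature edges.
#' @return data.frame: `genome`, `target`, `class`, `marker`, `bp_distance`,
#'   `gene_rank_distance` (NA where `absent`).
#' @export
classifyColocalization <- function(genome, targets, markers,
                                   windowGenes = 8L, windowBp = 10000L) {
    g <- genes(genome)
    ids <- S4Vectors::mcols(g)$gene_id
    missing <- setdiff(targets, ids)
    if (length(missing))
        stop("target gene(s) not in genome annotation: ",
             paste(missing, collapse = ", "))
    markers <- intersect(markers, ids)
    rows <- lapply(targets, function(tg) {
        ti <- match(tg, ids)
        if (!length(markers))
            return(data.frame(genome = genomeId(genome), target = tg,
                              class = "absent", marker = NA_character_,
                              bp_distance = NA_integer_,
                              gene_rank_distance = NA_integer_))
        mi <- match(markers, ids)
        sameCtg <- as.character(GenomicRanges::seqnames(g))[mi] ==
                   as.character(GenomicRanges::seqnames(g))[ti]
        best <- NULL
        if (any(sameCtg)) {
            cand <- mi[sameCtg]
            # gene-rank distance: number of intervening genes on the contig
            ctg <- as.character(GenomicRanges::seqnames(g))[ti]
            onCtg <- which(as.character(GenomicRanges::seqnames(g)) == ctg)
            rankOf <- match(c(ti, cand), onCtg)
            rank_d <- abs(rankOf[-1] - rankOf[1]) - 1L
            # intergenic distance between nearest feature edges (0 when
            # adjacent or overlapping)
            bp_d <- vapply(cand, function(m) {
                d <- max(GenomicRanges::start(g)[m] -
                         GenomicRanges::end(g)[ti] - 1L,
                         GenomicRanges::start(g)[ti] -
                         GenomicRanges::end(g)[m] - 1L, 0L)
                as.integer(d)
            }, 0L)
            o <- order(rank_d, bp_d)
            best <- list(marker = ids[cand[o[1]]], rank = rank_d[o[1]],
                         bp = bp_d[o[1]])
        }
        if (!is.null(best) &&
            (best$rank <= windowGenes || best$bp <= windowBp)) {
            cls <- "proximal"
        } else cls <- "same_genome"
        data.frame(genome = genomeId(genome), target = tg, class = cls,
                   marker = if (is.null(best)) markers[1] else best$marker,
                   bp_distance = if (is.null(best)) NA_integer_
                                 else as.integer(best$bp),
                   gene_rank_distance = if (is.null(best)) NA_integer_
                                        else as.integer(best$rank))
    })
    do.call(rbind, rows)
}

#' Summarise colocalization calls over a genome collection
#'
#' @param calls row-bound output of [classifyColocalization()] across
#'   genomes (one row per genome/target pair).
#' @return one-row data.frame: `n_targets`, `n_copresent` (marker somewhere
#'   in the genome), `n_proximal`. Satisfies
#'   `n_proximal <= n_copresent <= n_targets`.
#' @export
copresenceSummary <- function(calls) {
    if (is.null(calls) || nrow(calls) == 0L)
        return(data.frame(n_targets = 0L, n_copresent = 0L, n_proximal = 0L))
    data.frame(n_targets = nrow(calls),
               n_copresent = sum(calls$class %in% c("proximal", "same_genome")),
               n_proximal = sum(calls$class == "proximal"))
}
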