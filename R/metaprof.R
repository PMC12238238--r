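# Metagenomic quantification: k-mer containment read mapping, per-biosample
# aggregation with CPM and presence calls, and the group comparisons
# (one-sided two-proportion z-test on prevalence, one-sided Wilcoxon
# rank-sum on CPM).

#' Map reads to a gene panel by k-mer containment
#'
#' Each read is assigned to the panel gene sharing the largest fraction of
#' its k-mers (both orientations, via indexing each panel k-mer in both
#' strands) provided that fraction reaches `theta`; ties and sub-threshold
#' reads stay unassigned. With `prefilter = TRUE` a stride-8 probe filter
#' skips reads with no panel k-mer at any probed window; the filter is exact
#' for reads whose matching windows form at most `ceil(theta*(L-k+1)/8)`
#' runs (for 150-bp reads at the defaults: any read with up to 4
#' substitution errors).
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param panel named `DNAStringSet`/character vector of gene sequences.
#' @param k k-mer size (reads shorter than k are an error).
#' @param theta minimum shared-k-mer fraction for assignment.
#' @param prefilter use the probe prefilter (see Details).
#' @return list: `counts` (named per-gene read counts), `assignment`
#'   (per-read gene or NA), `total` (number of reads), `unassigned`.
#' @export
mapReads <- function(reads, panel, k = 21L, theta = 0.3, prefilter = TRUE) {
    if (length(reads) == 1L && file.exists(reads) &&
        grepl("\\.(fastq|fq)$", reads))
        reads <- readFastq(reads)
    panel <- stats::setNames(as.character(panel), names(panel))
    if (length(panel) == 0L) stop("gene panel is empty")
    if (is.null(names(panel)))
        names(panel) <- sprintf("gene%02d", seq_along(panel))
    r <- cpp_map_reads(reads, panel, as.integer(k), theta, isTRUE(prefilter))
    counts <- stats::setNames(as.integer(r$counts), names(panel))
    assign <- names(panel)[ifelse(r$assignment == 0L, NA_integer_,
                                  r$assignment)]
    list(counts = counts, assignment = assign,
         total = length(reads), unassigned = sum(r$assignment == 0L))
}

#' Aggregate run-level counts into per-biosample profiles
#'
#' Counts are summed across all runs of a biosample before anything else;
#' samples whose summed total read count is below `qcMinReads` are flagged
#' `qc_pass = FALSE` (they are reported, but excluded from downstream
#' tests). CPM is `count / total * 1e6`; a gene is present when its CPM is
#' strictly greater than `cpmThreshold`.
#'
#' @param counts gene x run matrix of mapped-read counts.
#' @param totals named per-run total read counts.
#' @param metadata data.frame with columns `run`, `biosample`, `group`;
#'   every run must map to exactly one biosample.
#' @param cpmThreshold presence threshold on CPM (strict inequality).
#' @param qcMinReads minimum summed reads per biosample to pass QC.
#' @return a [SampleProfileSet].
#' @export
profileSamples <- function(counts, totals, metadata, cpmThreshold = 1,
                           qcMinReads = 1e6) {
    need <- c("run", "biosample", "group")
    if (!all(need %in% colnames(metadata)))
        stop("metadata needs columns: ", paste(need, collapse = ", "))
    orphan <- setdiff(colnames(counts), metadata$run)
    if (length(orphan))
        stop("run(s) without metadata: ", paste(orphan, collapse = ", "))
    if (anyDuplicated(metadata$run))
        stop("each run must map to exactly one biosample")
    metadata <- metadata[match(colnames(counts), metadata$run), ]
    samples <- unique(metadata$biosample)
    agg <- vapply(samples, function(s) {
        runs <- metadata$run[metadata$biosample == s]
        rowSums(counts[, runs, drop = FALSE])
    }, numeric(nrow(counts)))
    if (!is.matrix(agg)) agg <- matrix(agg, nrow = nrow(counts),
                                       dimnames = list(rownames(counts),
                                                       samples))
    tot <- vapply(samples, function(s)
        sum(totals[metadata$run[metadata$biosample == s]]), 0)
    grp <- metadata$group[match(samples, metadata$biosample)]
    cpmMat <- sweep(agg, 2L, tot, "/") * 1e6
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = agg, cpm = cpmMat),
        colData = S4Vectors::DataFrame(biosample = samples, group = grp,
                                       total = unname(tot),
                                       qc_pass = unname(tot) >= qcMinReads,
                                       row.names = samples))
    S4Vectors::metadata(se)$cpm_threshold <- cpmThreshold
    S4Vectors::metadata(se)$qc_min_reads <- qcMinReads
    new("SampleProfileSet", se)
}

#' Per-group gene prevalence
#'
#' Fraction of QC-passing samples per group in which each gene is present
#' (CPM strictly above the threshold).
#'
#' @param sps a [SampleProfileSet].
#' @return data.frame: `gene`, `group`, `n`, `n_present`, `prevalence`.
#' @export
prevalenceByGroup <- function(sps) {
    keep <- qcPass(sps)
    pres <- presenceCalls(sps)[, keep, drop = FALSE]
    grp <- sampleGroups(sps)[keep]
    rows <- list()
    for (g in unique(grp)) {
        sub <- pres[, grp == g, drop = FALSE]
        rows[[g]] <- data.frame(gene = rownames(sub), group = g,
                                n = ncol(sub), n_present = rowSums(sub),
                                prevalence = rowMeans(sub))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' One-sided two-proportion z-test on prevalence
#'
#' Pooled-proportion z statistic with optional Yates continuity correction
#' (on by default, matching the conventional implementation of this test);
#' the one-sided p-value is the upper normal tail in the direction
#' `groupA > groupB`. Degenerate pooled proportions (0 or 1) are flagged and
#' return the conventional p of 1 or 0.5.
#'
#' @param nA,presentA group A sample count and number of present samples.
#' @param nB,presentB group B likewise.
#' @param correct apply the continuity correction.
#' @return data.frame: group sizes, proportions, `z`, `p`, `degenerate`.
#' @export
prevalenceTest <- function(nA, presentA, nB, presentB, correct = TRUE) {
    if (nA < 1 || nB < 1) stop("each group needs at least one sample")
    pA <- presentA / nA; pB <- presentB / nB
    pool <- (presentA + presentB) / (nA + nB)
    degenerate <- pool %in% c(0, 1)
    if (degenerate) {
        p <- if (pool == 0) 1 else 0.5
        z <- 0
    } else {
        se <- sqrt(pool * (1 - pool) * (1 / nA + 1 / nB))
        d <- pA - pB
        if (correct) {
            cc <- 0.5 * (1 / nA + 1 / nB)
            d <- sign(d) * max(0, abs(d) - cc)
        }
        z <- d / se
        p <- stats::pnorm(z, lower.tail = FALSE)
    }
    data.frame(n_a = nA, present_a = presentA, prop_a = pA,
               n_b = nB, present_b = presentB, prop_b = pB,
               z = z, p = p, degenerate = degenerate)
}

#' One-sided Wilcoxon rank-sum test on abundance
#'
#' Rank-sum statistic with midranks for ties, normal approximation with
#' tie-corrected variance and continuity correction (the standard
#' `wilcox.test` normal path), testing `groupA > groupB`. When every value
#' in both groups is identical the test is flagged degenerate with p = 0.5.
#'
#' @param valuesA,valuesB numeric CPM vectors (>= 1 value each).
#' @return data.frame: `n_a`, `n_b`, `w` (rank-sum statistic of group A,
#'   Mann-Whitney form), `p`, `degenerate`.
#' @export
abundanceTest <- function(valuesA, valuesB) {
    if (!length(valuesA) || !length(valuesB))
        stop("each group needs at least one value")
    nA <- length(valuesA); nB <- length(valuesB)
    if (length(unique(c(valuesA, valuesB))) == 1L) {
        return(data.frame(n_a = nA, n_b = nB, w = nA * nB / 2, p = 0.5,
                          degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(
        valuesA, valuesB, alternative = "greater",
        exact = FALSE, correct = TRUE))
    data.frame(n_a = nA, n_b = nB, w = unname(wt$statistic),
               p = wt$p.value, degenerate = FALSE)
}

#' Group comparison for every panel gene
#'
#' Runs the prevalence z-test and the abundance Wilcoxon test for each gene,
#' testing whether `groupA` exceeds `groupB`, and reports
#' Benjamini-Hochberg adjusted p-values alongside the raw ones.
#'
#' @param sps a [SampleProfileSet].
#' @param groupA,groupB group labels (direction: A > B).
#' @param correct continuity correction for the z-test.
#' @param dropZeroCpm exclude zero-CPM samples from the Wilcoxon test
#'   (mirrors excluding them from a log-scale plot); default keeps them.
#' @return data.frame per gene: prevalence columns, `z`, `p_prev`,
#'   `p_prev_bh`, `w`, `p_abund`, `p_abund_bh`.
#' @export
genePrevalenceTests <- function(sps, groupA, groupB, correct = TRUE,
                                dropZeroCpm = FALSE) {
    keep <- qcPass(sps)
    grp <- sampleGroups(sps)[keep]
    pres <- presenceCalls(sps)[, keep, drop = FALSE]
    cpms <- cpm(sps)[, keep, drop = FALSE]
    rows <- lapply(rownames(pres), function(g) {
        inA <- grp == groupA; inB <- grp == groupB
        zt <- prevalenceTest(sum(inA), sum(pres[g, inA]),
                             sum(inB), sum(pres[g, inB]), correct = correct)
        va <- cpms[g, inA]; vb <- cpms[g, inB]
        if (dropZeroCpm) { va <- va[va > 0]; vb <- vb[vb > 0] }
        at <- if (length(va) && length(vb)) abundanceTest(va, vb)
              else data.frame(w = NA_real_, p = NA_real_)
        data.frame(gene = g, n_a = zt$n_a, prop_a = zt$prop_a,
                   n_b = zt$n_b, prop_b = zt$prop_b, z = zt$z,
                   p_prev = zt$p, w = at$w, p_abund = at$p)
    })
    out <- do.call(rbind, rows)
    out$p_prev_bh <- stats::p.adjust(out$p_prev, method = "BH")
    out$p_abund_bh <- stats::p.adjust(out$p_abund, method = "BH")
    out
}

#' Natural-log CPM table for plotting
#'
#' Long-format ln(CPM) values of QC-passing samples; zero-CPM samples are
#' excluded (they have no finite logarithm).
#'
#' @param sps a [SampleProfileSet].
#' @return data.frame: `gene`, `biosample`, `group`, `ln_cpm`.
#' @export
lnCpmTable <- function(sps) {
    keep <- qcPass(sps)
    cpms <- cpm(sps)[, keep, drop = FALSE]
    grp <- sampleGroups(sps)[keep]
    df <- expand.grid(gene = rownames(cpms), biosample = colnames(cpms),
                      stringsAsFactors = FALSE)
    df$group <- grp[match(df$biosample, colnames(cpms))]
    df$ln_cpm <- log(cpms[cbind(df$gene, df$biosample)])
    df[is.finite(df$ln_cpm), , drop = FALSE]
}
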