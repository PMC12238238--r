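# Profile hidden Markov models: construction from a trimmed alignment,
# log-odds scoring (Viterbi/forward, glocal or local), Gumbel E-value
# calibration against background-sampled nulls, database search, and fused
# two-domain decomposition.

#' Build a profile HMM from a trimmed alignment
#'
#' Columns with residue occupancy (non-gap fraction) at or above
#' `matchOccupancy` become match states; the remaining columns are treated
#' as insertions. Emissions and transitions are maximum-likelihood counts
#' with a Laplace-style pseudocount `alpha` (emissions: `(n + alpha) /
#' (N + 20 alpha)`). Insert states emit the background distribution.
#'
#' @param msa a [ProteinMSA] (already trimmed).
#' @param alpha pseudocount.
#' @param matchOccupancy occupancy threshold for match-state assignment.
#' @param refId reference row used for the match-column to
#'   reference-position map (default first row).
#' @param background residue background frequencies (length 20, AA20 order).
#' @param modelId model name.
#' @return a [ProfileHMM].
#' @export
buildProfileHMM <- function(msa, alpha = 1, matchOccupancy = 0.5,
                            refId = NULL, background = AA_BACKGROUND,
                            modelId = "model") {
    stopifnot(is(msa, "ProteinMSA"))
    aln <- alnMatrix(msa)
    if (ncol(aln) == 0L) stop("alignment has no columns")
    refId <- refId %||% rownames(aln)[1]
    occ <- colMeans(aln != "-")
    isMatch <- occ >= matchOccupancy
    M <- sum(isMatch)
    if (M == 0L) stop("no columns satisfy the match-occupancy rule")
    matchCols <- which(isMatch)

    em <- matrix(0, 20L, M, dimnames = list(AA20, NULL))
    for (m in seq_len(M)) {
        col <- aln[, matchCols[m]]
        cnt <- tabulate(match(col, AA20), 20L)   # X and gaps excluded
        em[, m] <- (cnt + alpha) / (sum(cnt) + 20 * alpha)
    }

    # transition counts: walk each row's state path through the columns
    trn <- matrix(0, 7L, M + 1L,
                  dimnames = list(c("MM", "MI", "MD", "IM", "II", "DM", "DD"),
                                  NULL))
    midx <- cumsum(isMatch)                      # match index per column
    for (r in seq_len(nrow(aln))) {
        row <- aln[r, ]
        # state path of this row: begin, column states, end (as match)
        types <- "M"; cols <- 0L; cur <- 0L
        for (cc in seq_len(ncol(aln))) {
            if (isMatch[cc]) {
                cur <- midx[cc]
                types <- c(types, if (row[cc] == "-") "D" else "M")
                cols <- c(cols, cur)
            } else if (row[cc] != "-") {
                types <- c(types, "I"); cols <- c(cols, cur)
            }
        }
        types <- c(types, "M"); cols <- c(cols, M)
        for (t in seq_len(length(types) - 1L)) {
            a <- types[t]; b <- types[t + 1L]
            # trace doctoring: route I<->D adjacencies through match, since
            # the reduced topology has no I-D transitions
            if ((a == "I" && b == "D") || (a == "D" && b == "I")) {
                types[t + 1L] <- "M"; b <- "M"
            }
            trn[paste0(a, b), cols[t] + 1L] <- trn[paste0(a, b), cols[t] + 1L] + 1
        }
    }
    # normalise with pseudocounts over the allowed moves of each column;
    # a set with neither counts nor pseudocounts falls back to uniform
    tr <- matrix(0, 7L, M + 1L, dimnames = dimnames(trn))
    normSet <- function(v) {
        denom <- sum(v) + length(v) * alpha
        if (denom == 0) rep(1 / length(v), length(v))
        else (v + alpha) / denom
    }
    for (j in seq_len(M + 1L)) {
        lastCol <- j == M + 1L
        mset <- if (lastCol) c("MM", "MI") else c("MM", "MI", "MD")
        iset <- c("IM", "II")
        dset <- if (lastCol) "DM" else c("DM", "DD")
        tr[mset, j] <- normSet(trn[mset, j])
        tr[iset, j] <- normSet(trn[iset, j])
        if (j > 1L) tr[dset, j] <- normSet(trn[dset, j])
        else tr["DM", j] <- 1    # begin column has no delete state
    }

    refpos <- cumsum(aln[refId, ] != "-")
    cmap <- ifelse(aln[refId, matchCols] == "-", NA_integer_,
                   as.integer(refpos[matchCols]))
    bg <- background / sum(background)
    new("ProfileHMM", modelId = modelId, matchEmissions = em,
        insertEmissions = bg, transitions = tr, background = bg,
        columnMap = cmap,
        calibration = c(mu = NA_real_, beta = NA_real_,
                        nullLength = NA_real_))
}

.hmmLogOdds <- function(hmm) {
    list(lme = log(hmm@matchEmissions / hmm@background),
         ltr = log(hmm@transitions))
}

#' Score a protein against a profile HMM
#'
#' Log-odds scoring against the background, computed in log space. Glocal
#' alignment traverses the whole model (deletions allowed) anywhere within
#' the sequence; local alignment may also enter and leave the model at any
#' match state. Forward sums over all state paths and is therefore never
#' smaller than the Viterbi score.
#'
#' @param hmm a [ProfileHMM].
#' @param seq protein string.
#' @param mode `"viterbi"` (default, also yields the alignment envelope) or
#'   `"forward"`.
#' @param alignment `"glocal"` or `"local"`.
#' @return list with `nats`, `bits`, and for Viterbi `envStart`/`envEnd`
#'   (1-based sequence positions covered by match states).
#' @export
scoreSequence <- function(hmm, seq, mode = c("viterbi", "forward"),
                          alignment = c("glocal", "local")) {
    mode <- match.arg(mode); alignment <- match.arg(alignment)
    if (!nzchar(seq)) stop("sequence must be non-empty")
    lo <- .hmmLogOdds(hmm)
    r <- cpp_hmm_score(lo$lme, lo$ltr, encodeProtein(seq),
                       alignment == "local", mode == "forward",
                       mode == "viterbi")
    list(nats = r$score, bits = r$score / log(2),
         envStart = r$env_start, envEnd = r$env_end)
}

sampleBackgroundProtein <- function(n, background = AA_BACKGROUND) {
    paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

#' Calibrate the E-value null of a profile HMM
#'
#' Scores `nullN` i.i.d. background-sampled sequences with local Viterbi and
#' fits a Gumbel by the method of moments (`beta = s * sqrt(6) / pi`,
#' `mu = mean - 0.5772 * beta`). E-values are then
#' `dbSize * P(S > s)` under the fitted null.
#'
#' @param hmm a [ProfileHMM].
#' @param nullN number of null sequences (>= 200).
#' @param nullLength their length (default: the model length).
#' @param seed optional seed for the null sample.
#' @return the model with its `calibration` slot filled.
#' @export
calibrateProfile <- function(hmm, nullN = 500L, nullLength = NULL,
                             seed = NULL) {
    if (nullN < 200L) stop("null_n must be at least 200")
    if (!is.null(seed)) set.seed(seed)
    nullLength <- nullLength %||% modelLength(hmm)
    lo <- .hmmLogOdds(hmm)
    scores <- vapply(seq_len(nullN), function(i) {
        s <- sampleBackgroundProtein(nullLength, hmm@background)
        cpp_hmm_score(lo$lme, lo$ltr, encodeProtein(s), TRUE, FALSE,
                      FALSE)$score / log(2)
    }, 0)
    sdv <- stats::sd(scores)
    if (!is.finite(sdv) || sdv == 0)
        stop("degenerate null fit: zero scale")
    beta <- sdv * sqrt(6) / pi
    mu <- mean(scores) - 0.57721566490153 * beta
    hmm@calibration <- c(mu = mu, beta = beta, nullLength = nullLength)
    hmm
}

#' E-value of a bit score under a calibrated model
#' @param hmm calibrated [ProfileHMM].
#' @param bits bit score(s).
#' @param dbSize number of sequences searched.
#' @return E-value(s) (`dbSize` times the Gumbel exceedance probability).
#' @export
profileEvalue <- function(hmm, bits, dbSize) {
    cal <- calibration(hmm)
    if (anyNA(cal[c("mu", "beta")]))
        stop("model is not calibrated; run calibrateProfile() first")
    z <- (bits - cal[["mu"]]) / cal[["beta"]]
    dbSize * (1 - exp(-exp(-z)))
}

#' Search proteins with one or more profile HMMs
#'
#' Every protein is scored with local Viterbi against every model; hits with
#' an E-value at or below the ceiling are reported with their alignment
#' envelopes.
#'
#' @param hmms a [ProfileHMM] or list of calibrated models.
#' @param prots named `AAStringSet` or character vector.
#' @param evalueCeiling report hits with E-value <= this ceiling.
#' @param dbSize effective database size (default: number of proteins).
#' @return data.frame: `protein`, `model`, `env_start`, `env_end`, `bits`,
#'   `evalue`.
#' @export
searchProteins <- function(hmms, prots, evalueCeiling = 1e-3,
                           dbSize = NULL) {
    if (is(hmms, "ProfileHMM")) hmms <- list(hmms)
    prots <- stats::setNames(as.character(prots), names(prots))
    if (is.null(names(prots)))
        names(prots) <- sprintf("prot%d", seq_along(prots))
    dbSize <- dbSize %||% length(prots)
    rows <- list()
    for (hmm in hmms) {
        lo <- .hmmLogOdds(hmm)
        for (p in names(prots)) {
            r <- cpp_hmm_score(lo$lme, lo$ltr, encodeProtein(prots[[p]]),
                               TRUE, FALSE, TRUE)
            bits <- r$score / log(2)
            ev <- profileEvalue(hmm, bits, dbSize)
            if (ev <= evalueCeiling && !is.na(r$env_start))
                rows[[length(rows) + 1L]] <- data.frame(
                    protein = p, model = hmm@modelId,
                    env_start = r$env_start, env_end = r$env_end,
                    bits = bits, evalue = ev)
        }
    }
    if (!length(rows))
        return(data.frame(protein = character(), model = character(),
                          env_start = integer(), env_end = integer(),
                          bits = numeric(), evalue = numeric()))
    out <- do.call(rbind, rows)
    out[order(out$protein, out$env_start), , drop = FALSE]
}

#' Call fused two-domain proteins
#'
#' Proteins carrying two or more non-overlapping hits from distinct models
#' are decomposed: each adjacent envelope pair gets a split coordinate at
#' the integer midpoint (floor) of the inter-envelope gap.
#'
#' @param hits data.frame from [searchProteins()].
#' @return data.frame: `protein`, `model_a`, `model_b`, `end_a`, `start_b`,
#'   `split` (last residue of the N-terminal part).
#' @export
callFusions <- function(hits) {
    out <- list()
    for (p in unique(hits$protein)) {
        h <- hits[hits$protein == p, , drop = FALSE]
        h <- h[order(h$env_start), , drop = FALSE]
        if (nrow(h) < 2L) next
        for (i in seq_len(nrow(h) - 1L)) {
            a <- h[i, ]; b <- h[i + 1L, ]
            if (a$model == b$model) next
            if (b$env_start <= a$env_end) next  # overlapping envelopes
            out[[length(out) + 1L]] <- data.frame(
                protein = p, model_a = a$model, model_b = b$model,
                end_a = a$env_end, start_b = b$env_start,
                split = (a$env_end + b$env_start) %/% 2L)
        }
    }
    if (!length(out))
        return(data.frame(protein = character(), model_a = character(),
                          model_b = character(), end_a = integer(),
                          start_b = integer(), split = integer()))
    do.call(rbind, out)
}

#' Split fused proteins into their domain parts
#'
#' @param prots named `AAStringSet`/character vector of proteins.
#' @param fusions data.frame from [callFusions()].
#' @return named character vector of domain subsequences
#'   (`<protein>_part1`, `<protein>_part2`).
#' @export
splitFusedDomains <- function(prots, fusions) {
    prots <- stats::setNames(as.character(prots), names(prots))
    out <- character()
    for (i in seq_len(nrow(fusions))) {
        p <- fusions$protein[i]; sp <- fusions$split[i]
        s <- prots[[p]]
        out[paste0(p, "_part1")] <- substr(s, 1L, sp)
        out[paste0(p, "_part2")] <- substr(s, sp + 1L, nchar(s))
    }
    out
}

# ---- plain-text model serialisation ---------------------------------------

#' Write a profile HMM to a plain-text file
#' @param hmm a [ProfileHMM].
#' @param path output path.
#' @export
writeProfileHMM <- function(hmm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    cal <- calibration(hmm)
    writeLines(c(
        paste0("MODEL\t", hmm@modelId),
        paste0("LENGTH\t", modelLength(hmm)),
        paste0("COLMAP\t", paste(columnMap(hmm), collapse = ",")),
        paste0("CALIB\t", paste(format(cal, digits = 17), collapse = ",")),
        paste0("BG\t", paste(format(hmm@background, digits = 17),
                             collapse = ","))), con)
    writeLines(paste0("TRANS\t", apply(format(hmm@transitions, digits = 17),
                                       2L, paste, collapse = ",")), con)
    writeLines(paste0("MATCH\t",
                      apply(format(hmm@matchEmissions, digits = 17), 2L,
                            paste, collapse = ",")), con)
    invisible(path)
}

#' Read a profile HMM written by [writeProfileHMM()]
#' @param path file path.
#' @return a [ProfileHMM].
#' @export
readProfileHMM <- function(path) {
    lines <- readLines(path)
    field <- function(tag) sub(paste0("^", tag, "\t"), "",
                               grep(paste0("^", tag, "\t"), lines,
                                    value = TRUE))
    nums <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
    M <- as.integer(field("LENGTH"))
    cmap <- suppressWarnings(as.integer(strsplit(field("COLMAP"), ",")[[1]]))
    cal <- nums(field("CALIB"))
    names(cal) <- c("mu", "beta", "nullLength")
    bg <- nums(field("BG")); names(bg) <- AA20
    tr <- vapply(field("TRANS"), nums, numeric(7))
    dimnames(tr) <- list(c("MM", "MI", "MD", "IM", "II", "DM", "DD"), NULL)
    em <- vapply(field("MATCH"), nums, numeric(20))
    dimnames(em) <- list(AA20, NULL)
    new("ProfileHMM", modelId = field("MODEL"), matchEmissions = em,
        insertEmissions = bg, transitions = tr, background = bg,
        columnMap = cmap, calibration = cal)
}
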