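# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive implementations, kept separate from the package's
# algorithms.

# exhaustive affine-gap global alignment: enumerate all alignments
# recursively, tracking the previous operation for affine gap costs
oracle_affine_global <- function(a, b, S, open, ext) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    rec <- function(i, j, prev) {
        if (i > length(av) && j > length(bv)) return(0)
        best <- -Inf
        if (i <= length(av) && j <= length(bv))
            best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
        if (i <= length(av)) {
            gp <- if (prev == "X") ext else open + ext
            best <- max(best, -gp + rec(i + 1, j, "X"))
        }
        if (j <= length(bv)) {
            gp <- if (prev == "Y") ext else open + ext
            best <- max(best, -gp + rec(i, j + 1, "Y"))
        }
        best
    }
    rec(1, 1, "M")
}

# enumerate every state path through a profile HMM (the same declared
# topology the package documents: free N/C flanks, M/I/D columns, glocal or
# local entry/exit) and return the exact Viterbi max and forward log-sum
oracle_hmm_enumerate <- function(hmm, seq, local = FALSE) {
    lme <- log(hmm@matchEmissions / hmm@background)
    ltr <- log(hmm@transitions)
    codes <- match(strsplit(seq, "")[[1]], SteroScreen:::AA20)
    L <- length(codes); M <- ncol(lme)
    emit <- function(j, i) lme[codes[i], j]
    coll <- new.env(); coll$s <- numeric(0)
    # walk(state, j, i, acc): i = symbols consumed so far
    walk <- function(state, j, i, acc) {
        if (state == "E") { coll$s <- c(coll$s, acc); return(invisible()) }
        if (state == "M") {
            if (local) walk("E", j, i, acc)
            if (j == M) {
                if (!local) walk("E", j, i, acc + ltr["MM", M + 1])
            } else {
                if (i < L) walk("M", j + 1, i + 1,
                                acc + ltr["MM", j + 1] + emit(j + 1, i + 1))
                walk("D", j + 1, i, acc + ltr["MD", j + 1])
            }
            if (i < L && !(local && j == M))
                walk("I", j, i + 1, acc + ltr["MI", j + 1])
        } else if (state == "I") {
            if (j == M) {
                if (!local) walk("E", j, i, acc + ltr["IM", M + 1])
            } else if (i < L)
                walk("M", j + 1, i + 1,
                     acc + ltr["IM", j + 1] + emit(j + 1, i + 1))
            if (i < L) walk("I", j, i + 1, acc + ltr["II", j + 1])
        } else if (state == "D") {
            if (j == M) {
                if (!local) walk("E", j, i, acc + ltr["DM", M + 1])
            } else {
                if (i < L) walk("M", j + 1, i + 1,
                                acc + ltr["DM", j + 1] + emit(j + 1, i + 1))
                walk("D", j + 1, i, acc + ltr["DD", j + 1])
            }
        }
    }
    for (i0 in 0:L) {      # entry point after a free N flank of length i0
        if (local) {
            for (j in seq_len(M)) if (i0 < L)
                walk("M", j, i0 + 1, -log(M) + emit(j, i0 + 1))
        } else {
            if (i0 < L) walk("M", 1, i0 + 1, ltr["MM", 1] + emit(1, i0 + 1))
            walk("D", 1, i0, ltr["MD", 1])
            if (i0 < L) walk("I", 0, i0 + 1, ltr["MI", 1])
        }
    }
    # exits at position i are completed by a free C flank; enumeration above
    # already allows E at any consumed count, so the collection covers all
    # paths exactly once
    s <- coll$s
    list(viterbi = if (length(s)) max(s) else -Inf,
         forward = if (length(s)) {
             m <- max(s); m + log(sum(exp(s - m)))
         } else -Inf)
}

# exhaustive Fitch: minimise changes over all internal-state assignments
oracle_fitch <- function(tree, states) {
    stopifnot(ape::is.rooted(tree), ape::is.binary(tree))
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    stateSpace <- unique(unname(states))
    internal <- (ntip + 1):nnode
    edges <- tree$edge
    best <- Inf
    bestAt <- vector("list", nnode)
    grid <- expand.grid(rep(list(stateSpace), length(internal)),
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
        assign_ <- character(nnode)
        assign_[seq_len(ntip)] <- states[tree$tip.label]
        assign_[internal] <- unlist(grid[r, ])
        changes <- sum(assign_[edges[, 1]] != assign_[edges[, 2]])
        if (changes < best) {
            best <- changes
            bestAt <- lapply(seq_len(nnode), function(i) assign_[i])
        } else if (changes == best) {
            for (i in internal)
                bestAt[[i]] <- union(bestAt[[i]], assign_[i])
        }
    }
    list(score = best, sets = bestAt)
}

# exact one-sided (A > B) Wilcoxon rank-sum p-value by enumerating all
# assignments of the pooled values to the two groups
oracle_wilcoxon_exact <- function(a, b) {
    pool <- c(a, b); n <- length(a); N <- length(pool)
    rk <- rank(pool)   # midranks
    wObs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(N, n)
    ws <- apply(combs, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
    mean(ws >= wObs - 1e-12)
}

# closed-form pooled-proportion one-sided z-test (independently coded)
oracle_ztest <- function(nA, xA, nB, xB, correct = TRUE) {
    pA <- xA / nA; pB <- xB / nB
    pp <- (xA + xB) / (nA + nB)
    se <- sqrt(pp * (1 - pp) * (1 / nA + 1 / nB))
    num <- pA - pB
    if (correct) num <- sign(num) * max(0, abs(num) - (1 / nA + 1 / nB) / 2)
    z <- num / se
    stats::pnorm(z, lower.tail = FALSE)
}

# closed-form expected pairwise identity between two leaves whose path has
# total per-site substitution probabilities along m branches: per-branch
# transition keeps a site with prob (1-p), else uniform over the other 19
oracle_identity_after_path <- function(ps) {
    # probability the chain returns to / stays at the start state after the
    # sequence of branch steps in ps (symmetric 20-state chain)
    a <- 1
    for (p in ps) a <- a * (1 - p - p / 19) + p / 19
    a
}

random_protein <- function(n) {
    paste(sample(SteroScreen:::AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
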