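# Profile HMM construction, scoring against brute-force path enumeration,
# calibration, search and fusion decomposition.

build_toy_hmm <- function(seqs, alpha = 1, occ = 0.5) {
    m <- suppressWarnings(progressiveMSA(seqs))
    buildProfileHMM(m, alpha = alpha, matchOccupancy = occ)
}

test_that("emission pseudocounts follow the Laplace rule", {
    # one-row alignment, alpha = 0: indicator emissions
    h0 <- buildProfileHMM(ProteinMSA(c(r1 = "ACD")), alpha = 0)
    expect_equal(h0@matchEmissions[, 1], setNames(as.numeric(SteroScreen:::AA20 == "A"),
                                                  SteroScreen:::AA20))
    # column counts {A:2}, alpha = 1 -> P(A) = 3/22
    h1 <- buildProfileHMM(ProteinMSA(c(r1 = "A", r2 = "A")), alpha = 1)
    expect_equal(unname(h1@matchEmissions["A", 1]), 3 / 22)
    expect_equal(unname(h1@matchEmissions["C", 1]), 1 / 22)
})

test_that("match/insert assignment follows the occupancy rule", {
    # second column has 60% gaps (2/5 residues) -> insert state
    aln <- ProteinMSA(c(a = "AC", b = "A-", c = "A-", d = "AC", e = "A-"))
    h <- buildProfileHMM(aln, matchOccupancy = 0.5)
    expect_equal(modelLength(h), 1L)
    # at exactly 50% occupancy the column is a match state
    aln2 <- ProteinMSA(c(a = "AC", b = "A-", c = "AC", d = "A-"))
    expect_equal(modelLength(buildProfileHMM(aln2, matchOccupancy = 0.5)), 2L)
})

test_that("profile distributions stay normalised after every build", {
    set.seed(33)
    for (i in 1:5) {
        seqs <- setNames(vapply(1:4, function(j)
            random_protein(sample(10:25, 1)), ""), sprintf("s%d", 1:4))
        h <- build_toy_hmm(seqs)
        expect_true(validObject(h))
    }
})

test_that("forward and Viterbi match brute-force path enumeration", {
    set.seed(17)
    for (i in 1:12) {
        M <- sample(2:5, 1)
        seqs <- setNames(vapply(1:3, function(j) random_protein(M), ""),
                         sprintf("s%d", 1:3))
        h <- build_toy_hmm(seqs)
        if (modelLength(h) > 5) next
        for (local in c(FALSE, TRUE)) {
            seq <- random_protein(sample(1:8, 1))
            ora <- oracle_hmm_enumerate(h, seq, local = local)
            al <- if (local) "local" else "glocal"
            vit <- scoreSequence(h, seq, "viterbi", al)$nats
            fwd <- scoreSequence(h, seq, "forward", al)$nats
            expect_equal(vit, ora$viterbi, tolerance = 1e-9,
                         info = paste("viterbi", al, seq))
            expect_equal(fwd, ora$forward, tolerance = 1e-9,
                         info = paste("forward", al, seq))
            expect_lte(vit, fwd + 1e-12)
        }
    }
})

test_that("consensus scores above residue-shuffled permutations", {
    set.seed(23)
    fam <- setNames(vapply(1:5, function(i) random_protein(40), ""),
                    sprintf("s%d", 1:5))
    h <- build_toy_hmm(fam)
    consensus <- paste(SteroScreen:::AA20[apply(h@matchEmissions, 2,
                                                which.max)], collapse = "")
    base <- scoreSequence(h, consensus, "viterbi", "glocal")$bits
    wins <- 0L
    for (i in 1:100) {
        shuf <- paste(sample(strsplit(consensus, "")[[1]]), collapse = "")
        if (base > scoreSequence(h, shuf, "viterbi", "glocal")$bits)
            wins <- wins + 1L
    }
    expect_gte(wins, 99L)
})

test_that("calibration rejects degenerate nulls and E-values are uniform-ish", {
    fam <- setNames(rep(strrep("ACDEFGHIKL", 3), 3), sprintf("s%d", 1:3))
    h <- build_toy_hmm(fam)
    hc <- calibrateProfile(h, nullN = 400, seed = 91)
    expect_false(anyNA(calibration(hc)))
    expect_error(calibrateProfile(h, nullN = 100), "at least 200")
    # null scores map to E-values around dbSize/2 at the median
    set.seed(92)
    db <- 1000
    evs <- vapply(1:400, function(i) {
        s <- SteroScreen:::sampleBackgroundProtein(modelLength(hc))
        profileEvalue(hc, scoreSequence(hc, s, "viterbi", "local")$bits, db)
    }, 0)
    expect_gt(median(evs), 0.35 * db)
    expect_lt(median(evs), 0.7 * db)
})

test_that("planted homologs rank above background in search (AUC 1)", {
    set.seed(51)
    anc <- random_protein(60)
    fam <- setNames(vapply(1:6, function(i)
        SteroScreen:::mutateProtein(anc, 0.2), ""), sprintf("fam%d", 1:6))
    h <- calibrateProfile(build_toy_hmm(fam), nullN = 300, seed = 1)
    planted <- setNames(vapply(1:25, function(i)
        SteroScreen:::mutateProtein(anc, 0.4), ""), sprintf("hom%d", 1:25))
    bg <- setNames(vapply(1:25, function(i) random_protein(60), ""),
                   sprintf("bg%d", 1:25))
    score <- function(s) scoreSequence(h, s, "viterbi", "local")$bits
    sp <- vapply(planted, score, 0); sb <- vapply(bg, score, 0)
    expect_true(min(sp) > max(sb))   # AUC exactly 1
})

test_that("fused two-domain proteins are decomposed near the junction", {
    set.seed(61)
    ancA <- random_protein(80); ancB <- random_protein(70)
    famA <- setNames(vapply(1:5, function(i)
        SteroScreen:::mutateProtein(ancA, 0.15), ""), sprintf("a%d", 1:5))
    famB <- setNames(vapply(1:5, function(i)
        SteroScreen:::mutateProtein(ancB, 0.15), ""), sprintf("b%d", 1:5))
    hA <- calibrateProfile(build_toy_hmm(famA), nullN = 250, seed = 2)
    hA@modelId <- "modA"
    hB <- calibrateProfile(build_toy_hmm(famB), nullN = 250, seed = 3)
    hB@modelId <- "modB"
    fused <- c(fusion1 = paste0(ancA, ancB))
    hits <- searchProteins(list(hA, hB), fused, evalueCeiling = 1e-2,
                           dbSize = 100)
    expect_setequal(hits$model, c("modA", "modB"))
    fus <- callFusions(hits)
    expect_equal(nrow(fus), 1L)
    expect_equal(fus$model_a, "modA")
    expect_equal(fus$model_b, "modB")
    expect_lt(abs(fus$split - 80), 10)
    parts <- splitFusedDomains(fused, fus)
    expect_equal(nchar(parts[["fusion1_part1"]]), fus$split)
    expect_equal(paste0(parts[["fusion1_part1"]], parts[["fusion1_part2"]]),
                 unname(fused))
    # a single-domain protein yields one hit and no fusion call
    single <- c(solo = ancA)
    hs <- searchProteins(list(hA, hB), single, evalueCeiling = 1e-2,
                         dbSize = 100)
    expect_equal(nrow(callFusions(hs)), 0L)
})

test_that("profile HMM round-trips through its text serialisation", {
    set.seed(71)
    fam <- setNames(vapply(1:4, function(i) random_protein(20), ""),
                    sprintf("s%d", 1:4))
    h <- calibrateProfile(build_toy_hmm(fam), nullN = 200, seed = 5)
    path <- tempfile(fileext = ".hmm")
    writeProfileHMM(h, path)
    h2 <- readProfileHMM(path)
    expect_equal(h2@matchEmissions, h@matchEmissions, tolerance = 1e-12)
    expect_equal(h2@transitions, h@transitions, tolerance = 1e-12)
    expect_equal(calibration(h2), calibration(h), tolerance = 1e-12)
    expect_equal(columnMap(h2), columnMap(h))
})
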