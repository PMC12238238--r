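# Read mapping, sample aggregation/CPM/QC, and the two group tests.

test_that("error-free panel reads map to their source gene; background reads do not", {
    set.seed(7)
    genes <- setNames(vapply(1:3, function(i) random_dna(800), ""),
                      c("g1", "g2", "g3"))
    bg <- random_dna(5000)
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    reads <- c(substr(genes["g2"], 101, 250),
               rc(substr(genes["g2"], 301, 450)),
               substr(bg, 1001, 1150))
    m <- mapReads(reads, genes)
    expect_equal(unname(m$assignment), c("g2", "g2", NA))
    expect_equal(unname(m$counts["g2"]), 2L)
    expect_equal(m$unassigned, 1L)
    expect_equal(m$total, 3L)
})

test_that("reads shorter than k are an error", {
    expect_error(mapReads("ACGT", c(g = random_dna(100)), k = 21),
                 "shorter than k")
})

test_that("ties between genes leave the read unassigned", {
    g <- random_dna(200)
    panel <- c(a = g, b = g)   # identical genes -> every read ties
    rd <- substr(g, 11, 160)
    m <- mapReads(rd, panel)
    expect_equal(unname(m$assignment), NA_character_)
})

test_that("mutated reads survive mapping when k-mer survival stays above theta", {
    # 150-bp read, k = 21, exactly 2 substitutions: the surviving-kmer
    # fraction is computable per read; whenever it reaches theta = 0.3 the
    # read must be assigned
    set.seed(15)
    gene <- c(g1 = random_dna(2000))
    for (i in 1:100) {
        start <- sample(1800, 1)
        rd <- substr(gene, start, start + 149)
        pos <- sort(sample(150, 2))
        ch <- strsplit(rd, "")[[1]]
        for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
        rd2 <- paste(ch, collapse = "")
        # direct survival computation: windows not covering a mutated base
        surv <- sum(vapply(1:130, function(w)
            all(pos < w | pos > w + 20), TRUE)) / 130
        m <- mapReads(rd2, gene)
        if (surv >= 0.3) expect_equal(unname(m$assignment), "g1")
    }
})

test_that("prefilter and full scan agree on simulated cohorts", {
    des <- metagenomeDesign(groups = c(female = 3L, male = 3L),
                            carriage = 0.8, depth = 3000)
    panel <- c(gA = random_dna(1000), gB = random_dna(1000))
    s1 <- simulateMetagenome(des, panel, seed = 9, output = "counts",
                             prefilter = TRUE)
    s2 <- simulateMetagenome(des, panel, seed = 9, output = "counts",
                             prefilter = FALSE)
    expect_identical(s1$counts, s2$counts)
})

test_that("read counts are conserved through mapping", {
    set.seed(19)
    des <- metagenomeDesign(groups = c(female = 2L, male = 2L),
                            carriage = 0.7, depth = 2000)
    panel <- c(gA = random_dna(900))
    sim <- simulateMetagenome(des, panel, seed = 19, output = "reads")
    for (run in names(sim$reads)) {
        m <- mapReads(sim$reads[[run]], panel)
        expect_equal(sum(m$counts) + m$unassigned, m$total)
        expect_equal(m$total, 2000L)
    }
})

make_profiles <- function(counts, totals, meta, ...) {
    profileSamples(counts, totals, meta, ...)
}

test_that("runs are summed per biosample before QC and CPM", {
    counts <- matrix(c(3L, 4L), 1, 2,
                     dimnames = list("gA", c("s1_r1", "s1_r2")))
    totals <- c(s1_r1 = 6e5, s1_r2 = 6e5)
    meta <- data.frame(run = c("s1_r1", "s1_r2"), biosample = "s1",
                       group = "female")
    sps <- profileSamples(counts, totals, meta)
    expect_equal(unname(SummarizedExperiment::assay(sps, "counts")["gA", "s1"]), 7)
    # 1.2e6 total reads -> QC passes even though each run is below 1e6
    expect_true(qcPass(sps))
    expect_equal(unname(cpm(sps)["gA", "s1"]), 7 / 1.2e6 * 1e6)
})

test_that("presence uses a strict CPM threshold and QC a 1e6 floor", {
    counts <- matrix(c(10L, 9L), 1, 2,
                     dimnames = list("gA", c("a_r1", "b_r1")))
    totals <- c(a_r1 = 1e7, b_r1 = 9e5)
    meta <- data.frame(run = c("a_r1", "b_r1"), biosample = c("a", "b"),
                       group = c("female", "male"))
    sps <- profileSamples(counts, totals, meta)
    # CPM exactly 1 is not presence
    expect_equal(unname(cpm(sps)["gA", "a"]), 1)
    expect_false(presenceCalls(sps)["gA", "a"])
    expect_equal(unname(qcPass(sps)), c(TRUE, FALSE))
})

test_that("orphan runs are rejected", {
    counts <- matrix(1L, 1, 1, dimnames = list("gA", "r9"))
    expect_error(profileSamples(counts, c(r9 = 1e6),
                                data.frame(run = "r1", biosample = "s",
                                           group = "g")),
                 "without metadata")
})

test_that("z-test matches the closed form and prop.test", {
    cases <- list(c(50, 45, 50, 30), c(60, 54, 60, 36), c(10, 9, 12, 5),
                  c(100, 80, 100, 70))
    for (cs in cases) {
        for (correct in c(TRUE, FALSE)) {
            got <- prevalenceTest(cs[1], cs[2], cs[3], cs[4],
                                  correct = correct)
            expect_equal(got$p, oracle_ztest(cs[1], cs[2], cs[3], cs[4],
                                             correct), tolerance = 1e-12)
            ref <- suppressWarnings(stats::prop.test(
                c(cs[2], cs[4]), c(cs[1], cs[3]),
                alternative = "greater", correct = correct))
            expect_equal(got$p, ref$p.value, tolerance = 1e-9)
        }
    }
})

test_that("z-test degenerate and directional conventions hold", {
    eq <- prevalenceTest(50, 25, 50, 25, correct = FALSE)
    expect_equal(eq$z, 0)
    expect_equal(eq$p, 0.5)
    none <- prevalenceTest(20, 0, 20, 0)
    expect_true(none$degenerate); expect_equal(none$p, 1)
    all_ <- prevalenceTest(20, 20, 20, 20)
    expect_true(all_$degenerate); expect_equal(all_$p, 0.5)
    # observed direction opposite to the alternative -> p > 0.5
    opp <- prevalenceTest(50, 20, 50, 40)
    expect_gt(opp$p, 0.5)
})

test_that("Wilcoxon normal approximation tracks exact enumeration (n,m <= 8)", {
    set.seed(111)
    for (i in 1:30) {
        n <- sample(3:8, 1); m <- sample(3:8, 1)
        a <- runif(n, 0, 5); b <- runif(m, 0, 5)  # distinct values a.s.
        got <- abundanceTest(a, b)
        expect_lt(abs(got$p - oracle_wilcoxon_exact(a, b)), 0.02)
    }
})

test_that("Wilcoxon degenerate and monotonicity conventions hold", {
    tied <- abundanceTest(c(1, 1, 1), c(1, 1))
    expect_true(tied$degenerate)
    expect_equal(tied$p, 0.5)
    a <- c(2, 3, 4); b <- c(1.5, 2.5, 3.5)
    p0 <- abundanceTest(a, b)$p
    p1 <- abundanceTest(a + 1, b)$p
    expect_lte(p1, p0 + 1e-12)
})

test_that("CPM sums stay below the 1e6 ceiling and zero rows drop from ln table", {
    counts <- matrix(c(500L, 0L, 250L, 100L), 2, 2,
                     dimnames = list(c("gA", "gB"), c("a_r1", "b_r1")))
    totals <- c(a_r1 = 2e6, b_r1 = 2e6)
    meta <- data.frame(run = c("a_r1", "b_r1"), biosample = c("a", "b"),
                       group = c("female", "male"))
    sps <- profileSamples(counts, totals, meta)
    expect_true(all(colSums(cpm(sps)) <= 1e6))
    ln <- lnCpmTable(sps)
    expect_false(any(ln$gene == "gB" & ln$biosample == "a"))
    expect_equal(nrow(ln), 3L)
})

test_that("per-gene group tests report BH-adjusted p-values", {
    set.seed(121)
    ng <- 4
    counts <- matrix(rpois(ng * 20, 40), ng, 20,
                     dimnames = list(sprintf("g%d", 1:ng),
                                     sprintf("s%02d_r1", 1:20)))
    counts[1, 11:20] <- 0L   # gene 1 absent in group B
    totals <- setNames(rep(2e6, 20), colnames(counts))
    meta <- data.frame(run = colnames(counts),
                       biosample = sub("_r1", "", colnames(counts)),
                       group = rep(c("female", "male"), each = 10))
    sps <- profileSamples(counts, totals, meta)
    res <- genePrevalenceTests(sps, "female", "male")
    expect_equal(nrow(res), ng)
    expect_true(all(res$p_prev_bh >= res$p_prev - 1e-12))
    expect_equal(res$p_prev_bh, stats::p.adjust(res$p_prev, "BH"))
    expect_lt(res$p_prev[res$gene == "g1"], 0.01)
})
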