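# The synthetic-data generator: determinism, planted-truth invariants,
# family evolution statistics, metagenome read laws.

test_that("pangenome simulation is byte-identical under the same seed", {
    d <- pangenomeDesign(nDecoys = 3L, nCore = 1L, familyLength = 100L)
    d1 <- tempfile("pg1"); d2 <- tempfile("pg2")
    simulatePangenome(d, seed = 11, dir = d1)
    simulatePangenome(d, seed = 11, dir = d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_identical(f1, f2)
    for (f in f1)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    # a different seed changes the content
    d3 <- tempfile("pg3")
    simulatePangenome(d, seed = 12, dir = d3)
    expect_false(identical(readLines(file.path(d1, "gpos01.faa")),
                           readLines(file.path(d3, "gpos01.faa"))))
})

test_that("planted presence equals the phenotype and decoys violate it", {
    d <- pangenomeDesign(nPositive = 4L, nNegative = 3L, nDecoys = 8L)
    sim <- simulatePangenome(d, seed = 21, nucleotide = FALSE)
    phenInd <- as.integer(sim$phenotype == "positive")
    expect_identical(unname(sim$presence["planted", ]), phenInd)
    for (f in rownames(sim$presence)[sim$truth$type == "decoy"]) {
        expect_false(identical(unname(sim$presence[f, ]), phenInd))
        expect_gt(sum(sim$presence[f, ]), 0)
    }
    # zero decoys: planted, cores and marker only
    d0 <- pangenomeDesign(nDecoys = 0L, nCore = 0L)
    sim0 <- simulatePangenome(d0, seed = 22, nucleotide = FALSE)
    expect_setequal(sim0$truth$type, c("planted", "marker"))
})

test_that("fusion carriers are a subset of planted-family carriers", {
    d <- pangenomeDesign(nFusion = 2L)
    sim <- simulatePangenome(d, seed = 31, nucleotide = FALSE)
    carriers <- names(sim$phenotype)[sim$presence["planted", ] == 1]
    expect_true(all(sim$fusionCarriers %in% carriers))
    # fused proteins are longer by the partner-domain length
    fusedGene <- sim$members$gene_id[sim$members$family == "planted" &
        sim$members$genome %in% sim$fusionCarriers]
    plainGene <- sim$members$gene_id[sim$members$family == "planted" &
        !sim$members$genome %in% sim$fusionCarriers]
    allp <- do.call(c, unname(lapply(sim$proteomes, as.character)))
    expect_true(all(nchar(allp[fusedGene]) >
                    max(nchar(allp[plainGene]))))
})

test_that("genes are tiled non-overlapping with the designed spacers", {
    d <- pangenomeDesign(nDecoys = 2L, nCore = 1L)
    sim <- simulatePangenome(d, seed = 41)
    for (g in sim$genomes) {
        gr <- genes(g)
        expect_true(validObject(g))
        for (ctg in unique(as.character(GenomicRanges::seqnames(gr)))) {
            on <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
            st <- GenomicRanges::start(on); en <- GenomicRanges::end(on)
            o <- order(st)
            if (length(on) > 1)
                expect_true(all(st[o][-1] - en[o][-length(en)] - 1 == 200))
        }
    }
})

test_that("marker genes sit adjacent to the planted gene in proximal genomes", {
    d <- pangenomeDesign(nMarkerProximal = 2L)
    sim <- simulatePangenome(d, seed = 51)
    mem <- sim$members
    for (gid in sim$markerProximal) {
        gr <- genes(sim$genomes[[gid]])
        ids <- S4Vectors::mcols(gr)$gene_id
        pos <- match(mem$gene_id[mem$genome == gid &
                                 mem$family == "planted"], ids)
        mrk <- match(mem$gene_id[mem$genome == gid &
                                 mem$family == "marker"], ids)
        expect_equal(abs(pos - mrk), 1L, info = gid)
    }
})

test_that("a positive-negative class is required", {
    expect_error(pangenomeDesign(nPositive = 0L), "at least one")
})

test_that("family evolution keeps diagnostic residues and zero-rate identity", {
    tree <- "((l1:0.1,l2:0.1):0.05,(l3:0.1,l4:0.1):0.05);"
    clades <- c(l1 = "steroid", l2 = "steroid", l3 = "bile", l4 = "bile")
    fm <- familyModel(tree, clades, ancestorLength = 200L,
                      diagnosticColumns = list(
                          `166` = c(steroid = "N", bile = "Y"),
                          `171` = c(steroid = "S", bile = "E")))
    fam <- simulateHomologFamily(fm, seed = 61)
    ch <- function(s, i) substr(s, i, i)
    for (nm in names(fam$clades)) {
        s <- as.character(fam$sequences[[nm]])
        if (fam$clades[[nm]] == "steroid") {
            expect_equal(ch(s, 166), "N"); expect_equal(ch(s, 171), "S")
        } else {
            expect_equal(ch(s, 166), "Y"); expect_equal(ch(s, 171), "E")
        }
    }
    # zero substitution probability: all leaves identical to the ancestor
    tree0 <- "((l1:0,l2:0):0,(l3:0,l4:0):0);"
    fam0 <- simulateHomologFamily(familyModel(tree0, clades,
                                              ancestorLength = 50L), seed = 62)
    expect_true(all(as.character(fam0$sequences) ==
                    fam0$ancestor))
    # out-of-range diagnostic column errors
    expect_error(simulateHomologFamily(
        familyModel(tree, clades, ancestorLength = 100L,
                    diagnosticColumns = list(`166` = c(steroid = "N"))),
        seed = 63), "out of range")
})

test_that("within-clade pairwise identity matches the closed-form expectation", {
    # star-like clade: 24 leaves hanging off one ancestor, each branch p=0.1;
    # a leaf pair is separated by two branches
    n <- 24
    tips <- paste0("(", paste(sprintf("l%d:0.1", 1:n), collapse = ","), ")")
    tree <- ape::read.tree(text = paste0(tips, ";"))
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length) | tree$edge.length == 0] <- 0
    clades <- setNames(rep("one", n), sprintf("l%d", 1:n))
    fm <- familyModel(tree, clades, ancestorLength = 400L)
    fam <- simulateHomologFamily(fm, seed = 71)
    seqs <- as.character(fam$sequences)
    idm <- function(a, b) {
        va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
        mean(va == vb)
    }
    ids <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
        ids <- c(ids, idm(seqs[i], seqs[j]))
    want <- oracle_identity_after_path(c(0.1, 0.1))
    expect_lt(abs(mean(ids) - want), 0.03)
})

test_that("metagenome reads obey depth, determinism and the error law", {
    des <- metagenomeDesign(groups = c(female = 2L, male = 2L),
                            carriage = 1.0, depth = 1000,
                            errorProb = 0)
    panel <- c(gA = random_dna(1000))
    sim <- simulateMetagenome(des, panel, seed = 81, output = "reads")
    expect_equal(length(sim$reads), 4L)
    for (run in names(sim$reads)) {
        expect_length(sim$reads[[run]], 1000L)
        expect_true(all(nchar(sim$reads[[run]]) == 150L))
    }
    # error-free reads are exact substrings of a source sequence
    sources <- c(sim$background, sim$panel)
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    some <- sim$reads[[1]][1:50]
    expect_true(all(vapply(some, function(r)
        any(vapply(sources, function(s) grepl(r, s, fixed = TRUE), TRUE)),
        TRUE)))
    # carriage 1 -> truth marks the gene carried everywhere
    expect_true(all(sim$truth$carried))
    # byte-identical FASTQ under the same seed
    d1 <- tempfile(); d2 <- tempfile()
    writeMetagenome(simulateMetagenome(des, panel, seed = 82,
                                       output = "reads"), d1)
    writeMetagenome(simulateMetagenome(des, panel, seed = 82,
                                       output = "reads"), d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
})

test_that("metagenome preconditions are enforced", {
    des <- metagenomeDesign(groups = c(female = 1L, male = 1L),
                            carriage = 0.5, depth = 100)
    expect_error(simulateMetagenome(des, character(), seed = 1),
                 "empty")
    shortPanel <- c(g = random_dna(50))   # shorter than the read length
    expect_error(simulateMetagenome(des, shortPanel, seed = 1),
                 "read length")
    expect_error(metagenomeDesign(groups = c(female = 2L, male = 2L),
                                  carriage = 1.5, depth = 10),
                 "probability|\\[0, 1\\]")
    expect_error(metagenomeDesign(groups = c(a = 1L, b = 1L),
                                  carriage = 0.5, depth = 0), "depth")
})

test_that("run aggregation: reads per biosample equal depth times run count", {
    des <- metagenomeDesign(groups = c(female = 2L, male = 1L),
                            carriage = 0.8, depth = 500, runsPerSample = 2L)
    panel <- c(gA = random_dna(600))
    sim <- simulateMetagenome(des, panel, seed = 91, output = "counts")
    expect_equal(ncol(sim$counts), 6L)   # 3 biosamples x 2 runs
    perSample <- tapply(sim$totals, sim$metadata$biosample[
        match(names(sim$totals), sim$metadata$run)], sum)
    expect_true(all(perSample == 1000))
})
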