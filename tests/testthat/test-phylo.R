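# Neighbor joining, clade assignment, residue maps and Fitch parsimony.

random_additive_tree <- function(ntaxa) {
    tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.1, 1))
    tr
}

test_that("three-taxon branch lengths follow the closed-form formulas", {
    D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- njTree(D)
    len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
    expect_equal(unname(len["A"]), (5 + 9 - 10) / 2)
    expect_equal(unname(len["B"]), (5 + 10 - 9) / 2)
    expect_equal(unname(len["C"]), (9 + 10 - 5) / 2)
})

test_that("additive five-taxon distances recover the generating topology", {
    tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2,e:4);")
    D <- ape::cophenetic.phylo(tr)
    got <- njTree(D[sort(rownames(D)), sort(rownames(D))])
    expect_equal(phangorn::RF.dist(got, tr), 0)
    # and the branch lengths are reproduced on an additive input
    Dg <- ape::cophenetic.phylo(got)
    expect_equal(Dg[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("all-zero distances give a zero-length tree deterministically", {
    D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    tr <- njTree(D)
    expect_true(all(tr$edge.length == 0))
    tr2 <- njTree(D)
    expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("invalid distance matrices are rejected", {
    D <- matrix(c(0, 1, 1, 0), 2, 2)
    expect_error(njTree(D), "at least three")
    D3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
    expect_error(njTree(D3), "symmetric")
})

test_that("random additive trees are recovered with RF distance zero", {
    set.seed(77)
    for (i in 1:20) {
        tr <- random_additive_tree(sample(4:10, 1))
        D <- ape::cophenetic.phylo(tr)
        got <- njTree(D)
        expect_equal(phangorn::RF.dist(ape::unroot(tr), got), 0,
                     info = paste("trial", i))
    }
})

test_that("njTree topology agrees with the ape reference implementation", {
    set.seed(79)
    for (i in 1:10) {
        n <- sample(4:9, 1)
        D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
        v <- runif(n * (n - 1) / 2, 0.1, 2)
        D[lower.tri(D)] <- v
        D <- D + t(D)
        expect_equal(phangorn::RF.dist(njTree(D), ape::nj(D)), 0,
                     info = paste("trial", i))
    }
})

make_clade_tree <- function() {
    ape::read.tree(text = paste0(
        "(((a1:1,a2:1):1,(q1:1,(b1:1,b2:1):1):1):1,(og1:1,og2:1):3);"))
}

test_that("anchor-defined clades label enclosed leaves", {
    tr <- make_clade_tree()
    ct <- assignClades(tr, anchors = list(A = c("a1", "a2"),
                                          B = c("b1", "b2")),
                       outgroup = c("og1", "og2"))
    lab <- cladeLabels(ct)
    expect_equal(unname(lab[c("a1", "a2")]), c("A", "A"))
    expect_equal(unname(lab[c("b1", "b2")]), c("B", "B"))
    # q1 sits above clade B and outside A -> unassigned
    expect_equal(unname(lab["q1"]), "unassigned")
    expect_equal(unname(lab[c("og1", "og2")]), c("outgroup", "outgroup"))
})

test_that("nested claims leave non-anchor leaves unassigned", {
    tr <- make_clade_tree()
    # clade "wide" spans everything non-outgroup; clade B nested inside it
    ct <- assignClades(tr, anchors = list(wide = c("a1", "q1"),
                                          B = c("b1", "b2")),
                       outgroup = c("og1", "og2"))
    lab <- cladeLabels(ct)
    # b1/b2 sit in both claims but keep their own anchor label
    expect_equal(unname(lab[c("b1", "b2")]), c("B", "B"))
    expect_equal(unname(lab["a2"]), "wide")
})

test_that("anchors overlapping the outgroup are rejected", {
    tr <- make_clade_tree()
    expect_error(assignClades(tr, anchors = list(bad = c("a1", "og1")),
                              outgroup = c("og1", "og2")),
                 "disjoint")
    expect_error(assignClades(tr, anchors = list(A = "a1"),
                              outgroup = character()),
                 "non-empty")
})

test_that("clade assignment is invariant to leaf input order", {
    set.seed(83)
    tr <- ape::rtree(12)
    tr$tip.label <- sprintf("t%02d", 1:12)
    anchors <- list(X = c("t01", "t02"))
    out <- "t12"
    ct1 <- assignClades(tr, anchors, out)
    perm <- ape::rotateConstr(tr, sample(tr$tip.label))
    ct2 <- assignClades(perm, anchors, out)
    expect_equal(cladeLabels(ct1)[sort(names(cladeLabels(ct1)))],
                 cladeLabels(ct2)[sort(names(cladeLabels(ct2)))])
})

test_that("reference positions map across gaps to alignment columns", {
    aln <- ProteinMSA(c(ref = "---MKVLITG", other = "AAAMKVLITG"))
    rm <- mapReferencePositions(aln, "ref", c(1L, 4L))
    expect_equal(rm$column, c(4L, 7L))
    expect_error(mapReferencePositions(aln, "ref", c(1L, 50L)),
                 "beyond the reference")
    # a 3-gap prefix shifts reference position p to column p + 3
    expect_equal(mapReferencePositions(aln, "ref", 7L)$column, 10L)
})

test_that("per-clade residue frequencies are normalised and correct", {
    aln <- ProteinMSA(c(s1 = "NK", s2 = "NK", s3 = "NK", s4 = "SK",
                        o1 = "YK"))
    labels <- c(s1 = "steroid", s2 = "steroid", s3 = "steroid",
                s4 = "steroid", o1 = "outgroup")
    rm <- data.frame(position = 1L, column = 1L)
    fr <- columnFrequencies(aln, rm, labels)
    expect_equal(unname(fr$steroid["N", "1"]), 0.75)
    expect_equal(unname(fr$steroid["S", "1"]), 0.25)
    expect_equal(sum(fr$steroid[, "1"]), 1)
    expect_false("outgroup" %in% names(fr))
})

test_that("uniform leaves give zero parsimony score", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
    f <- fitchAncestral(tr, c(a = "N", b = "N", c = "N", d = "N"))
    expect_equal(f$score, 0L)
    expect_true(all(vapply(f$sets[[1]], identical, TRUE, "N")))
})

test_that("two-state split yields root ambiguity and one change", {
    tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
    f <- fitchAncestral(tr, c(a = "A", b = "A", c = "B", d = "B"))
    expect_equal(f$score, 1L)
    root <- f$sets[[1]][[length(f$sets[[1]])]]
    expect_setequal(root, c("A", "B"))
})

test_that("Fitch score and ancestral sets match exhaustive minimisation", {
    set.seed(101)
    for (i in 1:25) {
        tr <- ape::rtree(6)
        tr$tip.label <- letters[1:6]
        st <- setNames(sample(c("A", "B", "C"), 6, replace = TRUE),
                       letters[1:6])
        got <- fitchAncestral(tr, st)
        ora <- oracle_fitch(tr, st)
        expect_equal(got$score[1], ora$score, info = paste("trial", i))
        # compare sets: package sets are keyed by postorder internal index
        edges <- ape::reorder.phylo(tr, "postorder")$edge
        internalPost <- unique(edges[, 1])
        for (k in seq_along(internalPost)) {
            expect_setequal(got$sets[[1]][[as.character(k)]],
                            ora$sets[[internalPost[k]]])
        }
    }
})

test_that("Fitch score is bounded and invariant to leaf relabelling", {
    set.seed(103)
    tr <- ape::rtree(8)
    tr$tip.label <- letters[1:8]
    st <- setNames(sample(c("A", "B", "C"), 8, TRUE), letters[1:8])
    f1 <- fitchAncestral(tr, st)
    # at least (#distinct - 1) changes, at most the minority leaf count
    expect_gte(f1$score[1], length(unique(st)) - 1L)
    expect_lte(f1$score[1], 8L - max(table(st)))
    # swapping two leaves with equal states leaves the score unchanged
    sw <- which(st == st[1])
    if (length(sw) >= 2) {
        st2 <- st
        st2[c(sw[1], sw[2])] <- st[c(sw[2], sw[1])]
        expect_equal(fitchAncestral(tr, st2)$score, f1$score)
    }
})

test_that("distances from an alignment saturate at the cap", {
    aln <- ProteinMSA(c(a = "AAAA", b = "AAAC", c = "WWWW"))
    d <- alignmentDistances(aln, maxDistance = 5)
    expect_equal(d["a", "b"], -log(1 - 0.25))
    expect_equal(d["a", "c"], 5)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
})
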