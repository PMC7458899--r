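# Checker behaviour: scores, purity, stereo cross-validation.

test_that("clean drawings produce empty reports", {
    for (nm in c("ethanol", "benzene", "propane")) {
        rep <- checkMolblock(exampleMolblock(nm))
        expect_identical(maxScore(rep), 0L)
        expect_identical(nrow(issues(rep)), 0L)
    }
})

test_that("the checker never modifies its input and is deterministic", {
    mb <- makeIssueFixture("Molecule has a stereo bond in a ring")$molblock
    copy <- mb
    r1 <- checkMolblock(mb)
    r2 <- checkMolblock(mb)
    expect_identical(mb, copy)
    expect_identical(issues(r1), issues(r2))
    expect_true(nzchar(r1@engineVersion))
})

test_that("format checks score V3000, polymer, truncation and bond codes", {
    expect_identical(issues(checkMolblock(
        makeIssueFixture("V3000 mol file")$molblock)),
        data.frame(score = 6L, label = "V3000 mol file",
                   stringsAsFactors = FALSE))
    rep <- checkMolblock(makeIssueFixture("Illegal input")$molblock)
    expect_identical(maxScore(rep), 7L)
    expect_true("Illegal input" %in% issues(rep)$label)

    rec <- parseMolblock(chainMolblock(c("C", "C", "C"),
                                       orders = c(8L, 1L)))
    expect_true("Molecule has a bond with an illegal type" %in%
                checkFormat(rec)$label)
    rec <- parseMolblock(chainMolblock(c("C", "C", "C"),
                                       stereo = c(4L, 0L)))
    expect_true("Molecule has a bond with an illegal stereo flag" %in%
                checkFormat(rec)$label)
    # wedge codes on single bonds and a crossed double bond are legal
    rec <- parseMolblock(chainMolblock(c("C", "C", "C", "C"),
                                       orders = c(1L, 2L, 1L),
                                       stereo = c(1L, 3L, 6L)))
    expect_identical(nrow(checkFormat(rec)), 0L)
})

test_that("coordinate checks follow the tolerance and exclusivity rules", {
    zero <- parseMolblock(
        makeIssueFixture("All atoms have zero coordinates")$molblock)
    labs <- checkCoordinates(zero)$label
    expect_true("All atoms have zero coordinates" %in% labs)

    # a single atom at the origin is legitimate
    one <- parseMolblock(writeMolblock(newMolecule(
        data.frame(element = "C", x = 0, y = 0))))
    expect_false("All atoms have zero coordinates" %in%
                 checkCoordinates(one)$label)

    # 6 stacked atoms: only the score-6 flag; 2 stacked: only the score-5
    six <- parseMolblock(makeIssueFixture(
        "Molecule has six (or more) atoms with exactly the same coordinates")$molblock)
    labs6 <- checkCoordinates(six)$label
    expect_true(any(grepl("six \\(or more\\)", labs6)))
    expect_false(any(grepl("two \\(or more\\)", labs6)))
    two <- parseMolblock(makeIssueFixture(
        "Molecule has two (or more) atoms with exactly the same coordinates")$molblock)
    labs2 <- checkCoordinates(two)$label
    expect_true(any(grepl("two \\(or more\\)", labs2)))
    expect_false(any(grepl("six \\(or more\\)", labs2)))

    flag3d <- parseMolblock(makeIssueFixture(
        "Molecule has the 3D flag set for a 2D conformer")$molblock)
    expect_identical(checkCoordinates(flag3d),
        data.frame(score = 2L,
                   label = "Molecule has the 3D flag set for a 2D conformer",
                   stringsAsFactors = FALSE))
})

test_that("radicals are flagged unless on the known list", {
    methyl <- parseMolblock(makeIssueFixture(
        "Molecule has a radical that is not found in the known list")$molblock)
    expect_identical(checkRadicals(methyl)$score, 6L)

    no <- smilesToMolecule("[N]=O", "nitric oxide")
    expect_identical(nrow(checkRadicals(no)), 0L)

    tempo <- smilesToMolecule("CC1(C)CCCC(C)(C)N1[O]", "TEMPO")
    expect_identical(nrow(checkRadicals(tempo)), 0L)

    plain <- parseMolblock(exampleMolblock("ethanol"))
    expect_identical(nrow(checkRadicals(plain)), 0L)
})

test_that("stereocentre counts come from three genuinely different routes", {
    counts <- countStereo(wedgedStereocentre())
    expect_identical(unname(counts), c(1L, 1L, 1L))

    flat <- parseMolblock(exampleMolblock("flat_2_butanol"))
    expect_identical(unname(countStereo(flat)), c(0L, 0L, 0L))

    spurious <- parseMolblock(
        makeIssueFixture("InChI_RDKit/Mol stereo mismatch")$molblock)
    expect_identical(unname(countStereo(spurious)), c(1L, 0L, 0L))

    phosphine <- parseMolblock(
        makeIssueFixture("InChI_Mol/RDKit stereo mismatch")$molblock)
    expect_identical(unname(countStereo(phosphine)), c(1L, 1L, 0L))
})

test_that("mismatch classification agrees with brute-force enumeration", {
    for (m in 0:3) for (i in 0:3) for (p in 0:3) {
        got <- classifyStereoMismatch(c(m, i, p))
        want <- oracleMismatch(m, i, p)
        if (is.null(want)) {
            expect_null(got)
        } else {
            expect_identical(got$score, as.integer(want[1]))
            expect_identical(got$label, want[2])
        }
    }
})

test_that("stereo drawing flags fire on the drawing, not the chemistry", {
    ringWedge <- parseMolblock(
        makeIssueFixture("Molecule has a stereo bond in a ring")$molblock)
    expect_true("Molecule has a stereo bond in a ring" %in%
                checkStereoDrawing(ringWedge)$label)

    # acyclic, single wedge from a genuine stereocentre: clean
    expect_identical(nrow(checkStereoDrawing(wedgedStereocentre())), 0L)

    crossed <- parseMolblock(
        makeIssueFixture("Molecule has a crossed bond in a ring")$molblock)
    got <- checkStereoDrawing(crossed)
    expect_true(all(c(5L) %in% got$score[
        got$label == "Molecule has a crossed bond in a ring"]))
})

test_that("InChI warnings map data-driven, unmapped ones land at score 2", {
    rep <- checkMolblock(exampleMolblock("flat_2_butanol"))
    iss <- issues(rep)
    expect_true("InChI: Omitted undefined stereo" %in% iss$label)
    expect_identical(iss$score[iss$label == "InChI: Omitted undefined stereo"],
                     2L)

    rep <- checkMolblock(makeIssueFixture(
        "InChI: Accepted unusual valence(s)")$molblock)
    expect_identical(maxScore(rep), 6L)
})

test_that("reports are deduplicated, ordered, and score the maximum", {
    rep <- checkMolblock(makeIssueFixture("InChI: Empty structure")$molblock)
    iss <- issues(rep)
    expect_identical(maxScore(rep), 6L)
    expect_true(all(c("InChI: Empty structure",
                      "Number of atoms less than 1") %in% iss$label))
    expect_false(any(duplicated(paste(iss$score, iss$label))))
    expect_true(all(diff(iss$score) <= 0))
    # composite: spurious wedge record reaches 5 via the mismatch class
    rep <- checkMolblock(
        makeIssueFixture("InChI_RDKit/Mol stereo mismatch")$molblock)
    expect_identical(maxScore(rep), 5L)
})

test_that("every emitted label carries the registry score", {
    reg <- issueRegistry()
    expect_false(any(duplicated(reg$label)))
    for (lab in issueFixtureLabels()) {
        fx <- makeIssueFixture(lab)
        iss <- issues(checkMolblock(fx$molblock))
        for (k in seq_len(nrow(iss))) {
            expected <- reg$score[match(iss$label[k], reg$label)]
            if (is.na(expected)) {
                # dynamic InChI warning family
                expect_match(iss$label[k], "^InChI: ")
                expected <- 2L
            }
            expect_identical(iss$score[k], expected)
        }
    }
})
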