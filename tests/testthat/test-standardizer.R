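# Standardizer: exclusion, pipeline rules, neutralization, geometry.

test_that("exclusion flags metals and the boron threshold exactly", {
    rules <- exclusionRules()
    expect_true(computeExcludeFlag(
        smilesToMolecule("N.N.[Cl-].[Cl-].[Pt+2]"), rules))
    expect_false(computeExcludeFlag(
        parseMolblock(exampleMolblock("ethanol")), rules))
    for (n in 1:10) {
        mol <- parseMolblock(chainMolblock(rep("B", n)))
        expect_identical(computeExcludeFlag(mol, rules), n > 7)
    }
    # any listed metal, alone, triggers exclusion
    for (sym in rules$metals) {
        mol <- newMolecule(data.frame(element = sym, x = 0, y = 0))
        expect_true(computeExcludeFlag(mol, rules))
    }
})

test_that("excluded records pass through byte-identical", {
    mb <- writeMolblock(smilesToMolecule("N.N.[Cl-].[Cl-].[Pt+2]",
                                         "transplatin"))
    res <- standardizeMolblock(mb)
    expect_true(res@excludeFlag)
    expect_identical(res@molblock, mb)
    expect_length(res@appliedRules, 0L)
})

test_that("each normalization rule pair converges and is a fixpoint", {
    for (nm in rulePairNames()) {
        pr <- makeRulePair(nm)
        rb <- standardizeMolblock(pr$before)
        ra <- standardizeMolblock(pr$after)
        expect_true(nzchar(rb@inchikeyAfter), info = nm)
        expect_identical(rb@inchikeyAfter, ra@inchikeyAfter, info = nm)
        expect_true(nm %in% rb@appliedRules, info = nm)
        # the after-form is already standard
        expect_identical(standardizeMolblock(ra@molblock)@molblock,
                         ra@molblock, info = nm)
    }
})

test_that("either-wedges are reset; real wedges and crossings are kept", {
    mb <- chainMolblock(c("C", "C", "C", "C"), orders = c(1L, 2L, 1L),
                        stereo = c(4L, 3L, 1L))
    res <- standardizeMolblock(mb)
    st <- bonds(parseMolblock(res@molblock))$stereo
    expect_identical(st, c(0L, 3L, 1L))
    expect_true("unknown_stereo" %in% res@appliedRules)
})

test_that("kekulization replaces aromatic codes and failure is an error", {
    arom <- parseMolblock(exampleMolblock("benzene"))
    b <- bonds(arom); b$order <- 4L
    mb <- writeMolblock(MolCurate:::.withGraph(arom, bonds = b))
    res <- standardizeMolblock(mb)
    out <- bonds(parseMolblock(res@molblock))$order
    expect_identical(sort(out), c(rep(1L, 3), rep(2L, 3)))
    expect_false(res@changed)   # same molecule, same InChIKey

    odd <- makeIssueFixture("Error-9986 (Cannot process aromatic bonds)")
    expect_error(standardizeMolblock(odd$molblock), "kekulize")
})

test_that("explicit H removal honours all four exceptions", {
    # plain explicit H fold into the heavy-atom graph
    mb <- chainMolblock(c("C", "H"))
    res <- standardizeMolblock(mb)
    expect_identical(atoms(parseMolblock(res@molblock))$element, "C")

    # isotopic hydrogen is kept
    a <- data.frame(element = c("C", "H"), x = c(0, 0.9), y = c(0, 0.5),
                    isotope = c(0L, 2L))
    b <- data.frame(begin = 1, end = 2, order = 1L)
    res <- standardizeMolblock(writeMolblock(newMolecule(a, b)))
    expect_true("H" %in% atoms(parseMolblock(res@molblock))$element)

    # wedge-held hydrogen is kept
    a <- data.frame(element = c("C", "H", "F", "Cl"),
                    x = c(0, 0.9, -0.9, 0), y = c(0, 0.5, 0.5, -1))
    b <- data.frame(begin = c(1, 1, 1), end = c(2, 3, 4), order = 1L,
                    stereo = c(1L, 0L, 0L))
    res <- standardizeMolblock(writeMolblock(newMolecule(a, b)))
    expect_true("H" %in% atoms(parseMolblock(res@molblock))$element)

    # phosphinic acid: P-H in a non-default valence state is kept
    a <- data.frame(element = c("P", "O", "O", "H", "H"),
                    x = c(0, 0.9, -0.9, 0, 0.6), y = c(0, 0.5, 0.5, -1, -0.8))
    b <- data.frame(begin = rep(1, 4), end = 2:5,
                    order = c(2L, 1L, 1L, 1L))
    res <- standardizeMolblock(writeMolblock(newMolecule(a, b)))
    expect_identical(sum(atoms(parseMolblock(res@molblock))$element == "H"),
                     2L)
})

test_that("neutralization balances charge by hydrogen bookkeeping", {
    # acetate -> acetic acid
    res <- standardizeMolblock(writeMolblock(smilesToMolecule("CC(=O)[O-]")))
    expect_identical(netCharge(res@molblock), 0L)
    # zwitterion: H moves from the ammonium to the carboxylate
    res <- standardizeMolblock(
        writeMolblock(smilesToMolecule("[NH3+]CC([O-])=O")))
    expect_true(all(atoms(parseMolblock(res@molblock))$charge == 0L))
    # permanent cation stays
    res <- standardizeMolblock(writeMolblock(smilesToMolecule("C[N+](C)(C)C")))
    expect_identical(netCharge(res@molblock), 1L)
    # balanced ion pair is left ionic (no proton exists to move)
    res <- standardizeMolblock(
        writeMolblock(smilesToMolecule("CC(=O)[O-].[Na+]")))
    expect_identical(netCharge(res@molblock), 0L)
    expect_identical(sort(atoms(parseMolblock(res@molblock))$charge),
                     c(-1L, 0L, 0L, 0L, 1L))
})

test_that("triple bonds and allenes are straightened to collinearity", {
    angleAt <- function(mb, i, j, k) {
        a <- atoms(parseMolblock(mb))
        u <- c(a$x[i] - a$x[j], a$y[i] - a$y[j], a$z[i] - a$z[j])
        v <- c(a$x[k] - a$x[j], a$y[k] - a$y[j], a$z[k] - a$z[j])
        acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    }
    # bent propyne
    a <- data.frame(element = c("C", "C", "C"), x = c(0, 0.87, 1.2),
                    y = c(0, 0.5, 1.4))
    b <- data.frame(begin = 1:2, end = 2:3, order = c(3L, 1L))
    res <- standardizeMolblock(writeMolblock(newMolecule(a, b)))
    expect_lt(abs(angleAt(res@molblock, 1, 2, 3) - pi), 1e-3)
    expect_true("straighten" %in% res@appliedRules)
    # bent allene
    a <- data.frame(element = c("C", "C", "C"), x = c(0, 0.87, 1.2),
                    y = c(0, 0.5, 1.4))
    b <- data.frame(begin = 1:2, end = 2:3, order = 2L)
    res <- standardizeMolblock(writeMolblock(newMolecule(a, b)))
    expect_lt(abs(angleAt(res@molblock, 1, 2, 3) - pi), 1e-3)
    # molecules without linear groups keep their coordinates
    mb <- exampleMolblock("ethanol")
    res <- standardizeMolblock(mb)
    expect_identical(atoms(parseMolblock(res@molblock))$x,
                     atoms(parseMolblock(mb))$x)
})

test_that("standardization is idempotent and conserves heavy atoms", {
    mbs <- randomMolecules(120, seed = 5)
    for (mb in mbs) {
        r1 <- standardizeMolblock(mb, computeChanged = FALSE)
        r2 <- standardizeMolblock(r1@molblock, computeChanged = FALSE)
        expect_identical(r2@molblock, r1@molblock)
        expect_identical(heavyMultiset(r1@molblock), heavyMultiset(mb))
    }
})

test_that("the changed flag reflects an InChIKey difference", {
    res <- standardizeMolblock(writeMolblock(smilesToMolecule("CC(=O)[O-]")))
    expect_true(res@changed)
    expect_false(identical(res@inchikeyBefore, res@inchikeyAfter))
    res <- standardizeMolblock(exampleMolblock("ethanol"))
    expect_false(res@changed)
})
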