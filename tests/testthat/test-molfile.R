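# V2000 parsing/writing and component handling.

test_that("parsing a well-formed molblock exposes the deposited graph", {
    mol <- parseMolblock(exampleMolblock("ethanol"))
    expect_true(parseOk(mol))
    expect_identical(natoms(mol), 3L)
    expect_identical(atoms(mol)$element, c("C", "C", "O"))
    expect_identical(mol@version, "V2000")
    expect_identical(bonds(mol)$order, c(1L, 1L))
})

test_that("structural problems are encoded in fields, never raised", {
    v3 <- MolCurate:::.setCountsVersion(exampleMolblock("ethanol"), "V3000")
    mol <- parseMolblock(v3)
    expect_false(parseOk(mol))
    expect_identical(mol@version, "V3000")

    poly <- MolCurate:::.injectBeforeEnd(exampleMolblock("ethanol"),
                                         "M  STY  1   1 SRU")
    expect_true(parseMolblock(poly)@hasPolymerSgroup)

    trunc <- makeIssueFixture("Illegal input")$molblock
    bad <- parseMolblock(trunc)
    expect_false(parseOk(bad))
    expect_match(bad@parseError, "truncated")
    expect_identical(rawText(bad), trunc)

    expect_error(parseMolblock(""), "non-empty")
})

test_that("illegal bond codes are preserved verbatim, not repaired", {
    mb <- chainMolblock(c("C", "C", "C"), orders = c(5L, 1L),
                        stereo = c(0L, 4L))
    mol <- parseMolblock(mb)
    expect_identical(bonds(mol)$order, c(5L, 1L))
    expect_identical(bonds(mol)$stereo, c(0L, 4L))
})

test_that("write/parse round-trips preserve the chemical fields", {
    mbs <- c(exampleMolblock("sodium_acetate"), exampleMolblock("benzene"),
             randomMolecules(25, seed = 11))
    for (mb in mbs) {
        m1 <- parseMolblock(mb)
        m2 <- parseMolblock(writeMolblock(m1))
        for (col in c("element", "charge", "isotope", "radical"))
            expect_identical(atoms(m2)[[col]], atoms(m1)[[col]])
        for (col in c("begin", "end", "order", "stereo"))
            expect_identical(bonds(m2)[[col]], bonds(m1)[[col]])
    }
})

test_that("charges, isotopes and radicals travel via M lines", {
    a <- data.frame(element = c("C", "O"), x = c(0, 1), y = 0,
                    charge = c(0L, -1L), isotope = c(13L, 0L),
                    radical = c(2L, 0L))
    b <- data.frame(begin = 1, end = 2, order = 1L)
    mb <- writeMolblock(newMolecule(a, b))
    expect_match(mb, "M  CHG", fixed = TRUE)
    expect_match(mb, "M  ISO", fixed = TRUE)
    expect_match(mb, "M  RAD", fixed = TRUE)
    back <- parseMolblock(mb)
    expect_identical(atoms(back)$charge, c(0L, -1L))
    expect_identical(atoms(back)$isotope, c(13L, 0L))
    expect_identical(atoms(back)$radical, c(2L, 0L))
})

test_that("legacy atom-block charge column is honoured without M CHG", {
    mb <- paste(c("legacy", "", "",
        "  1  0  0  0  0  0  0  0  0  0999 V2000",
        "    0.0000    0.0000    0.0000 O   0  5  0  0  0  0  0  0  0  0  0  0",
        "M  END"), collapse = "\n")
    expect_identical(atoms(parseMolblock(mb))$charge, -1L)
})

test_that("capacity limits of the V2000 field widths are enforced", {
    a <- data.frame(element = rep("C", 1000), x = seq_len(1000), y = 0)
    expect_error(writeMolblock(newMolecule(a)), "capacity")
})

test_that("splitComponents partitions atoms in input order", {
    mol <- parseMolblock(exampleMolblock("sodium_acetate"))
    comps <- splitComponents(mol)
    expect_length(comps, 2L)
    expect_identical(sum(vapply(comps, natoms, integer(1))), natoms(mol))
    expect_identical(atoms(comps[[1]])$element, c("C", "C", "O", "O"))
    expect_identical(atoms(comps[[2]])$element, "Na")

    tp <- smilesToMolecule("N.N.[Cl-].[Cl-].[Pt+2]", "transplatin")
    expect_length(splitComponents(tp), 5L)

    single <- parseMolblock(exampleMolblock("ethanol"))
    expect_length(splitComponents(single), 1L)
})

test_that("SDF reading preserves record framing and data fields", {
    tf <- tempfile(fileext = ".sdf")
    writeSDF(c(exampleMolblock("ethanol"), exampleMolblock("propane")), tf,
             fields = list(c(ID = "one", Note = "a\nb"), c(ID = "two")))
    mols <- readSDF(tf)
    expect_length(mols, 2L)
    expect_identical(mols[[1]]@sdfFields[["ID"]], "one")
    expect_identical(mols[[1]]@sdfFields[["Note"]], "a\nb")
    expect_identical(molName(mols[[2]]), "propane")
})
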