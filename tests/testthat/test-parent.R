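# GetParent: match keys, dictionary, branch logic.

dict <- loadSaltDictionary()

test_that("match keys are charge-, stereo- and cis/trans-insensitive", {
    key <- function(smi) buildMatchKey(smilesToMolecule(smi))
    expect_identical(key("CC(=O)O"), key("CC(=O)[O-]"))       # acid/anion
    expect_identical(key("Cl"), key("[Cl-]"))                 # HCl/chloride
    expect_identical(key("OC(=O)/C=C\\C(=O)O"),
                     key("OC(=O)/C=C/C(=O)O"))                # maleic/fumaric
    expect_identical(key("OC(=O)[C@H](O)[C@@H](O)C(=O)O"),
                     key("OC(=O)C(O)C(O)C(=O)O"))             # tartaric
    expect_identical(key("CC(=O)O"),
                     buildMatchKey(removeIsotopes(
                         smilesToMolecule("[14CH3]C(=O)O"))))
    expect_false(identical(key("CC(=O)O"), key("CCC(=O)O")))
})

test_that("isotope erasure is total and idempotent", {
    mol <- smilesToMolecule("[13CH3][C@H](N)C(=O)O")
    a <- atoms(mol)
    expect_true(any(a$isotope != 0L))
    clean <- removeIsotopes(mol)
    expect_true(all(atoms(clean)$isotope == 0L))
    expect_identical(removeIsotopes(clean), clean)
})

test_that("the dictionary loads with both roles and rejects duplicates", {
    ent <- dictEntries(dict)
    expect_true(all(c("salt", "solvent") %in% ent$role))
    expect_gt(sum(ent$role == "salt"), 20L)
    expect_identical(sum(ent$role == "solvent"), 9L)
    expect_false(any(duplicated(paste(ent$matchKey, ent$role))))

    twice <- tempfile(fileext = ".smi")
    writeLines(c("CC(=O)O\tacetic acid", "CC(=O)[O-]\tacetate"), twice)
    empty <- tempfile(fileext = ".smi")
    writeLines("# nothing", empty)
    expect_error(loadSaltDictionary(twice, empty), "duplicate")
    # an empty solvent file is a valid dictionary
    d2 <- loadSaltDictionary(defaultSaltsFile(), empty)
    expect_identical(sum(dictEntries(d2)$role == "solvent"), 0L)
})

test_that("single-component isotope-free records are their own parent", {
    mb <- exampleMolblock("ethanol")
    res <- getParent(mb, dict)
    expect_identical(branch(res), "identity")
    expect_identical(res@parentMolblock, mb)
    expect_identical(nrow(res@removed), 0L)
})

test_that("a matched salt is stripped and the remainder neutralized", {
    mb <- makeSaltFixture("c1ccccc1C(=O)O", "hydrochloride", dict)
    res <- getParent(mb, dict)
    expect_identical(branch(res), "salts_stripped")
    expect_identical(res@removed$name, "hydrochloride")
    out <- parseMolblock(res@parentMolblock)
    expect_length(splitComponents(out), 1L)
    expect_identical(sum(atoms(out)$charge), 0L)
    expect_identical(
        MolCurate:::.inchikeyOf(res@parentMolblock),
        MolCurate:::.inchikeyOf(writeMolblock(
            smilesToMolecule("c1ccccc1C(=O)O"))))
})

test_that("all-salt records are kept whole (the sodium chloride case)", {
    mb <- makeSaltFixture(NULL, c("sodium", "hydrochloride"), dict)
    res <- getParent(mb, dict)
    expect_identical(branch(res), "all_salt_unchanged")
    expect_identical(nrow(res@removed), 0L)
    expect_identical(MolCurate:::.inchikeyOf(res@parentMolblock),
                     MolCurate:::.inchikeyOf(mb))
})

test_that("true mixtures pass through as the identical mixture", {
    m1 <- smilesToMolecule("Cc1cc(C)nc(N)n1")
    m2 <- smilesToMolecule("CCCCCCO")
    a2 <- atoms(m2); a2$x <- a2$x + 12
    mix <- writeMolblock(MolCurate:::.combineComponents(
        list(m1, MolCurate:::.withGraph(m2, a2)), "mixture"))
    res <- getParent(mix, dict)
    expect_identical(branch(res), "true_mixture_unchanged")
    expect_length(splitComponents(parseMolblock(res@parentMolblock)), 2L)
})

test_that("the 2:1 complex collapses to a single neutral parent", {
    mb <- makeSaltFixture("CC(C)Cc1ccc(cc1)C(C)C(=O)[O-]", "calcium", dict,
                          copies = 2)
    res <- getParent(mb, dict)
    expect_identical(branch(res), "salts_stripped")
    expect_true(res@deduplicated)
    out <- parseMolblock(res@parentMolblock)
    expect_length(splitComponents(out), 1L)
    expect_identical(sum(atoms(out)$charge), 0L)
})

test_that("excluded records lose solvents but never salts", {
    tp <- writeMolblock(smilesToMolecule("N.N.[Cl-].[Cl-].[Pt+2]",
                                         "transplatin"))
    res <- getParent(tp, dict)
    expect_identical(branch(res), "excluded_solvent_only")
    expect_identical(nrow(res@removed), 0L)
    expect_length(splitComponents(parseMolblock(res@parentMolblock)), 5L)

    # the same complex crystallized with water: only the water goes
    tpm <- parseMolblock(tp)
    w <- smilesToMolecule("O")
    aw <- atoms(w); aw$x <- aw$x + 15
    withWater <- writeMolblock(MolCurate:::.combineComponents(
        list(tpm, MolCurate:::.withGraph(w, aw)), "transplatin hydrate"))
    res <- getParent(withWater, dict)
    expect_identical(branch(res), "excluded_solvent_only")
    expect_identical(res@removed$role, "solvent")
    expect_length(splitComponents(parseMolblock(res@parentMolblock)), 5L)
})

test_that("quaternary ammonium parents stay cationic after salt removal", {
    mb <- makeSaltFixture("C[N+](C)(C)Cc1ccccc1", "hydrochloride", dict)
    res <- getParent(mb, dict)
    expect_identical(branch(res), "salts_stripped")
    expect_identical(netCharge(res@parentMolblock), 1L)
})

test_that("isotope labels are removed on the way to the parent", {
    mb <- makeSaltFixture("CC(C)Cc1ccc(cc1)C(C)C(=O)O", character(), dict,
                          isotopeFirstAtom = 14L)
    res <- getParent(mb, dict)
    expect_true(res@isotopesRemoved)
    expect_true(all(atoms(parseMolblock(res@parentMolblock))$isotope == 0L))
    # and the parent equals the unlabelled compound
    expect_identical(
        MolCurate:::.inchikeyOf(res@parentMolblock),
        MolCurate:::.inchikeyOf(standardizeMolblock(writeMolblock(
            smilesToMolecule("CC(C)Cc1ccc(cc1)C(C)C(=O)O")))@molblock))
})

test_that("getParent is idempotent and invents no components", {
    for (mb in randomSaltFixtures(40, seed = 19)) {
        r1 <- getParent(mb, dict)
        r2 <- getParent(r1@parentMolblock, dict)
        expect_identical(r2@parentMolblock, r1@parentMolblock)
        inKeys <- vapply(splitComponents(removeIsotopes(parseMolblock(mb))),
                         buildMatchKey, character(1))
        outKeys <- vapply(
            splitComponents(parseMolblock(r1@parentMolblock)),
            buildMatchKey, character(1))
        expect_true(all(outKeys %in% inKeys))
    }
})

test_that("any salt form of a parent converges to the parent's key", {
    base <- getParent(writeMolblock(smilesToMolecule("CC(N)Cc1ccccc1")), dict)
    k0 <- MolCurate:::.inchikeyOf(base@parentMolblock)
    for (s in c("hydrochloride", "sulfate", "tartrate", "maleate")) {
        ps <- getParent(makeSaltFixture("CC(N)Cc1ccccc1", s, dict), dict)
        expect_identical(MolCurate:::.inchikeyOf(ps@parentMolblock), k0,
                         info = s)
    }
})
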