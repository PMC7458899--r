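# Shared builders and small oracles for the test suite.

heavyMultiset <- function(molblock) {
    el <- atoms(parseMolblock(molblock))$element
    sort(el[el != "H"])
}

netCharge <- function(molblock) {
    sum(atoms(parseMolblock(molblock))$charge)
}

# simple linear chain builder mirroring typical 2D sketches
chainMolblock <- function(elements, orders = NULL, stereo = NULL,
                          name = "chain") {
    n <- length(elements)
    a <- data.frame(element = elements,
                    x = (seq_len(n) - 1) * 0.866,
                    y = (seq_len(n) - 1) %% 2 * 0.5)
    b <- if (n > 1)
        data.frame(begin = 1:(n - 1), end = 2:n,
                   order = if (is.null(orders)) 1L else orders,
                   stereo = if (is.null(stereo)) 0L else stereo)
    else NULL
    writeMolblock(newMolecule(a, b, name = name))
}

# one-wedge (R)-bromochlorofluoromethane sketch: a genuine stereocentre
wedgedStereocentre <- function() {
    a <- data.frame(element = c("C", "Br", "Cl", "F"),
                    x = c(0, 0.866, -0.866, 0), y = c(0, 0.5, 0.5, -1))
    b <- data.frame(begin = c(1, 1, 1), end = c(2, 3, 4), order = 1L,
                    stereo = c(1L, 0L, 0L))
    newMolecule(a, b, name = "bromochlorofluoromethane")
}

# independent re-derivation of the mismatch classification used as the
# brute-force oracle: count agreement patterns directly
oracleMismatch <- function(m, i, p) {
    if (m == i && i == p) return(NULL)
    eq <- c(mi = m == i, mp = m == p, ip = i == p)
    if (sum(eq) == 0) return(c(5L, "Mol/Inchi/RDKit stereo mismatch"))
    if (eq[["ip"]]) return(c(5L, "InChI_RDKit/Mol stereo mismatch"))
    if (eq[["mp"]]) return(c(5L, "RDKit_Mol/InChI stereo mismatch"))
    c(2L, "InChI_Mol/RDKit stereo mismatch")
}

# randomized multi-component salt-form fixtures for parent property tests;
# components are drawn from cached parsed structures, so generation is cheap
saltFixturePool <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        parents <- c("CC(C)Cc1ccc(cc1)C(C)C(=O)O",  # profen-like acid
                     "CC(N)Cc1ccccc1",              # amphetamine-like amine
                     "OCCN1CCN(CC1)C(c1ccccc1)c1ccccc1",
                     "CCOC(=O)C1CCCN1C",
                     "Nc1ncnc2[nH]cnc12")
        dict <- loadSaltDictionary()
        ent <- dictEntries(dict)
        salts <- c("hydrochloride", "sodium", "calcium", "sulfate",
                   "tartrate", "maleate", "mesylate")
        solvents <- c("water", "ethanol")
        parse1 <- function(s) smilesToMolecule(s)
        cache <<- list(
            parents = lapply(parents, parse1),
            salts = lapply(salts, function(nm)
                parse1(ent$smiles[match(nm, ent$name)])),
            dict = dict)
        cache
    }
})

randomSaltFixtures <- function(n, seed) {
    pool <- saltFixturePool()
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    offset <- function(m, dx) {
        a <- atoms(m); a$x <- a$x + dx
        MolCurate:::.withGraph(m, a)
    }
    vapply(seq_len(n), function(i) {
        comps <- list(pool$parents[[sample(length(pool$parents), 1)]])
        for (k in seq_len(sample(0:2, 1)))
            comps <- c(comps, pool$salts[sample(length(pool$salts), 1)])
        if (runif(1) < 0.2) {
            a <- atoms(comps[[1]])
            a$isotope[1] <- 13L
            comps[[1]] <- MolCurate:::.withGraph(comps[[1]], a)
        }
        dx <- 0
        for (j in seq_along(comps)) {
            comps[[j]] <- offset(comps[[j]], dx)
            dx <- dx + diff(range(atoms(comps[[j]])$x)) + 3
        }
        writeMolblock(MolCurate:::.combineComponents(comps,
                                                     sprintf("salt-%03d", i)))
    }, character(1))
}
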