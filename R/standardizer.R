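# The Standardizer: exclusion rule + ordered normalization pipeline.
#
# Pipeline order (fixed): reset unknown stereo -> clear S-group data ->
# kekulize -> remove explicit hydrogens (four exceptions) -> normalize
# functional groups (ordered sub-rules, iterated to a fixpoint) ->
# neutralize -> straighten triple bonds and allenes. Excluded records
# (organometallics, polyboranes) pass through byte-identical.

#' Default exclusion metal list file
#' @return path to the shipped one-symbol-per-line file.
#' @export
defaultMetalsFile <- function() {
    system.file("extdata", "exclude_metals.txt", package = "MolCurate",
                mustWork = TRUE)
}

#' Exclusion rules for the standardizer
#'
#' Molecules containing more than \code{boronThreshold} boron atoms, or any
#' atom of the listed metals, are excluded from standardization: V2000
#' connection tables cannot represent their coordination bonds faithfully,
#' so no automated edit is safe.
#'
#' @param metalsFile path to a one-symbol-per-line element list.
#' @param boronThreshold largest permitted boron count (default 7).
#' @return list with elements \code{metals} (character) and
#'   \code{boronThreshold} (integer).
#' @export
exclusionRules <- function(metalsFile = defaultMetalsFile(),
                           boronThreshold = 7L) {
    lines <- trimws(readLines(metalsFile, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    list(metals = lines, boronThreshold = as.integer(boronThreshold))
}

#' Exclude-flag computation
#'
#' @param record a parsed \linkS4class{Molecule}.
#' @param rules result of [exclusionRules()].
#' @return logical: TRUE iff the boron count exceeds the threshold or any
#'   atom is a listed metal.
#' @examples
#' computeExcludeFlag(parseMolblock(exampleMolblock("ethanol")))
#' @export
computeExcludeFlag <- function(record, rules = exclusionRules()) {
    stopifnot(is(record, "Molecule"), parseOk(record))
    el <- atoms(record)$element
    sum(el == "B") > rules$boronThreshold || any(el %in% rules$metals)
}

# --- individual pipeline steps; each returns list(mol=, changed=) ---------

# Reset "either"-wedge single bonds (stereo code 4) to plain bonds and clear
# atom parity that was carried only by them. Crossed double bonds (unknown
# cis/trans, code 3) are kept: they express unknown geometry deliberately.
.stepUnknownStereo <- function(mol) {
    b <- bonds(mol)
    hit <- b$order == 1L & b$stereo == 4L
    if (!any(hit)) return(list(mol = mol, changed = FALSE))
    origins <- unique(b$begin[hit])
    b$stereo[hit] <- 0L
    a <- atoms(mol)
    stillWedged <- unique(b$begin[b$stereo %in% .WEDGE_CODES])
    clear <- setdiff(origins, stillWedged)
    a$parity[clear] <- 0L
    list(mol = .withGraph(mol, a, b), changed = TRUE)
}

.stepKekulize <- function(mol) {
    if (!any(bonds(mol)$order == 4L)) return(list(mol = mol, changed = FALSE))
    list(mol = .kekulizeMolecule(mol), changed = TRUE)
}

# Remove explicit hydrogens except: isotopic H; H held by a wedged/hashed
# bond; H on an atom with tetrahedral stereo set; H on atoms in a
# non-default valence state that is not simply protonated (charge-adjusted
# default valences count as default, so protonated amines fold normally but
# e.g. the P-H of phosphinic acid is kept). H whose neighbour cannot carry
# implicit hydrogens (metals), charged/radical H, bridging H and lone H
# atoms are also kept, since folding them would change the formula.
.stepRemoveExplicitH <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    hIdx <- which(a$element == "H")
    if (!length(hIdx)) return(list(mol = mol, changed = FALSE))
    adj <- .adjacency(mol)
    bos <- .bondOrderSums(mol)
    stereoSet <- unique(c(which(a$parity != 0L),
                          b$begin[b$stereo %in% .WEDGE_CODES]))
    removable <- logical(length(hIdx))
    for (k in seq_along(hIdx)) {
        h <- hIdx[k]
        if (a$isotope[h] != 0L || a$charge[h] != 0L || a$radical[h] != 0L)
            next
        nbrs <- adj[[h]]
        if (length(nbrs) != 1L) next
        v <- nbrs[1]
        if (a$element[v] == "H") next
        hBonds <- b$begin == h | b$end == h
        if (any(b$stereo[hBonds] %in% .WEDGE_CODES)) next
        if (any(b$order[hBonds] != 1L)) next
        if (v %in% stereoSet) next
        vals <- .defaultValences(a$element[v], a$charge[v])
        if (!length(vals)) next
        if (bos[v] > min(vals)) next   # non-default valence state: keep H
        removable[k] <- TRUE
    }
    drop <- hIdx[removable]
    if (!length(drop)) return(list(mol = mol, changed = FALSE))
    keep <- setdiff(seq_len(nrow(a)), drop)
    list(mol = .subsetAtoms(mol, keep), changed = TRUE)
}

# --- normalization sub-rules ----------------------------------------------

.ruleNitro <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- .adjacency(mol)
    changed <- FALSE
    deg <- lengths(adj)
    for (n in which(a$element == "N" & a$charge == 0L)) {
        dbl <- which((b$begin == n | b$end == n) & b$order == 2L)
        oxy <- vapply(dbl, function(e) {
            o <- if (b$begin[e] == n) b$end[e] else b$begin[e]
            a$element[o] == "O" && a$charge[o] == 0L && deg[o] == 1L
        }, logical(1))
        if (sum(oxy) < 2L) next
        e <- dbl[oxy][1]   # the two oxygens are equivalent; take the first
        o <- if (b$begin[e] == n) b$end[e] else b$begin[e]
        b$order[e] <- 1L
        a$charge[o] <- -1L
        a$charge[n] <- 1L
        changed <- TRUE
    }
    list(mol = .withGraph(mol, a, b), changed = changed)
}

.ruleAlkaliMetal <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    changed <- FALSE
    repeat {
        hit <- which(b$order == 1L & (
            (a$element[b$begin] %in% .ALKALI_METALS & a$charge[b$begin] == 0L &
             a$element[b$end] %in% c("O", "N") & a$charge[b$end] == 0L) |
            (a$element[b$end] %in% .ALKALI_METALS & a$charge[b$end] == 0L &
             a$element[b$begin] %in% c("O", "N") & a$charge[b$begin] == 0L)))
        if (!length(hit)) break
        e <- hit[1]
        m <- if (a$element[b$begin[e]] %in% .ALKALI_METALS) b$begin[e] else b$end[e]
        x <- if (m == b$begin[e]) b$end[e] else b$begin[e]
        a$charge[m] <- 1L
        a$charge[x] <- -1L
        b <- b[-e, , drop = FALSE]
        changed <- TRUE
    }
    list(mol = .withGraph(mol, a, b), changed = changed)
}

# N=C-OH -> N-C(=O); acyclic C=N only, so ring tautomers (2-pyridinone and
# friends) are never rewritten -- tautomer canonicalization is a non-goal.
.ruleAmideTautomer <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- .adjacency(mol)
    deg <- lengths(adj)
    ring <- .ringBonds(mol)
    hs <- .implicitH(mol)
    changed <- FALSE
    for (e in which(b$order == 2L & !ring)) {
        ends <- c(b$begin[e], b$end[e])
        cn <- ends[a$element[ends] == "C"]
        nn <- ends[a$element[ends] == "N"]
        if (length(cn) != 1L || length(nn) != 1L) next
        if (a$charge[cn] != 0L || a$charge[nn] != 0L) next
        oEdge <- which((b$begin == cn | b$end == cn) & b$order == 1L)
        for (oe in oEdge) {
            o <- if (b$begin[oe] == cn) b$end[oe] else b$begin[oe]
            if (a$element[o] != "O" || a$charge[o] != 0L || deg[o] != 1L) next
            if (hs[o] < 1L) next
            b$order[e] <- 1L
            b$order[oe] <- 2L
            changed <- TRUE
            hs <- .implicitH(.withGraph(mol, a, b))
            break
        }
    }
    list(mol = .withGraph(mol, a, b), changed = changed)
}

.ruleSulfoxide <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- .adjacency(mol)
    deg <- lengths(adj)
    changed <- FALSE
    for (s in which(a$element == "S" & a$charge == 0L & lengths(adj) == 3L)) {
        se <- which(b$begin == s | b$end == s)
        dbl <- se[b$order[se] == 2L]
        if (length(dbl) != 1L || any(b$order[se] == 3L)) next
        o <- if (b$begin[dbl] == s) b$end[dbl] else b$begin[dbl]
        if (a$element[o] != "O" || a$charge[o] != 0L || deg[o] != 1L) next
        b$order[dbl] <- 1L
        a$charge[s] <- 1L
        a$charge[o] <- -1L
        changed <- TRUE
    }
    list(mol = .withGraph(mol, a, b), changed = changed)
}

.ruleDiazonium <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- .adjacency(mol)
    deg <- lengths(adj)
    changed <- FALSE
    for (e in which(b$order == 2L)) {
        ends <- c(b$begin[e], b$end[e])
        if (!all(a$element[ends] == "N") || any(a$charge[ends] != 0L)) next
        term <- ends[deg[ends] == 1L]
        inner <- ends[deg[ends] == 2L]
        if (length(term) != 1L || length(inner) != 1L) next
        other <- which((b$begin == inner | b$end == inner) &
                       seq_len(nrow(b)) != e)
        if (length(other) != 1L || b$order[other] != 1L) next
        b$order[e] <- 3L
        a$charge[inner] <- 1L
        changed <- TRUE
        deg <- lengths(.adjacency(.withGraph(mol, a, b)))
    }
    list(mol = .withGraph(mol, a, b), changed = changed)
}

.ruleQuaternaryN <- function(mol) {
    a <- atoms(mol)
    adj <- .adjacency(mol)
    bos <- .bondOrderSums(mol)
    hit <- a$element == "N" & a$charge == 0L & lengths(adj) == 4L & bos == 4
    if (!any(hit)) return(list(mol = mol, changed = FALSE))
    a$charge[hit] <- 1L
    list(mol = .withGraph(mol, a), changed = TRUE)
}

.ruleTrivalentO <- function(mol) {
    a <- atoms(mol)
    bos <- .bondOrderSums(mol)
    hit <- a$element == "O" & a$charge == 0L & bos == 3
    if (!any(hit)) return(list(mol = mol, changed = FALSE))
    a$charge[hit] <- 1L
    list(mol = .withGraph(mol, a), changed = TRUE)
}

.ruleTrivalentS <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- .adjacency(mol)
    bos <- .bondOrderSums(mol)
    hasDouble <- unique(c(b$begin[b$order > 1L], b$end[b$order > 1L]))
    hit <- a$element == "S" & a$charge == 0L & lengths(adj) == 3L & bos == 3
    hit[hasDouble] <- FALSE
    if (!any(hit)) return(list(mol = mol, changed = FALSE))
    a$charge[hit] <- 1L
    list(mol = .withGraph(mol, a), changed = TRUE)
}

# A disconnected neutral halogen is charged only while the record carries a
# cationic surplus for it to balance; otherwise the added negative charge
# would immediately be re-protonated by neutralization (a rule cycle).
.ruleLoneHalogen <- function(mol) {
    a <- atoms(mol)
    adj <- .adjacency(mol)
    hit <- which(a$element %in% .HALOGENS & a$charge == 0L &
                 lengths(adj) == 0L)
    net <- sum(a$charge)
    k <- min(length(hit), max(net, 0L))
    if (k == 0L) return(list(mol = mol, changed = FALSE))
    a$charge[hit[seq_len(k)]] <- -1L
    list(mol = .withGraph(mol, a), changed = TRUE)
}

.NORMALIZATION_RULES <- list(
    nitro = .ruleNitro,
    alkali_metal = .ruleAlkaliMetal,
    amide_tautomer = .ruleAmideTautomer,
    sulfoxide = .ruleSulfoxide,
    diazonium = .ruleDiazonium,
    quaternary_N = .ruleQuaternaryN,
    trivalent_O = .ruleTrivalentO,
    trivalent_S = .ruleTrivalentS,
    lone_halogen = .ruleLoneHalogen
)

#' Default normalization rule table
#'
#' The shipped rule registry (name, SMARTS pattern, transform description).
#' The rule names present in the file select which rules run and document
#' their patterns; the graph edits are implemented in the package.
#' @return path to the shipped TSV file.
#' @export
defaultRulesFile <- function() {
    system.file("extdata", "normalization_rules.tsv", package = "MolCurate",
                mustWork = TRUE)
}

.enabledRuleNames <- function(rulesFile) {
    tab <- utils::read.delim(rulesFile, header = TRUE,
                             stringsAsFactors = FALSE, comment.char = "#")
    nm <- tab$name[tab$name %in% names(.NORMALIZATION_RULES)]
    unknown <- setdiff(tab$name, names(.NORMALIZATION_RULES))
    if (length(unknown))
        warning("ignoring unimplemented rule name(s): ",
                paste(unknown, collapse = ", "))
    nm
}

.MAX_NORMALIZE_PASSES <- 200L

# Apply the ordered rule set to convergence.
.stepNormalize <- function(mol, ruleNames) {
    applied <- character()
    for (pass in seq_len(.MAX_NORMALIZE_PASSES)) {
        passChanged <- FALSE
        for (nm in ruleNames) {
            res <- .NORMALIZATION_RULES[[nm]](mol)
            if (res$changed) {
                mol <- res$mol
                applied <- c(applied, nm)
                passChanged <- TRUE
            }
        }
        if (!passChanged)
            return(list(mol = mol, applied = unique(applied)))
    }
    stop("normalization did not converge within ", .MAX_NORMALIZE_PASSES,
         " passes (rule cycle)")
}

# --- neutralization --------------------------------------------------------

.H_ACCEPTORS <- c("C", "N", "O", "S", "P", "Se", "Te", .HALOGENS)

# Drive the net formal charge to zero where hydrogen bookkeeping allows:
# move H from protonated centres to deprotonated ones (including across
# components), then add or remove H for the remaining imbalance. Atoms in a
# (+,-) adjacent pair (nitro, sulfoxide, ylides) are left charge-separated
# unless nothing else can absorb the imbalance. When several atoms qualify
# the one with the smallest canonical rank is chosen, so the result is
# independent of input atom order. Permanent cations (quaternary N) have no
# removable H and keep their charge.
.stepNeutralize <- function(mol) {
    changed <- FALSE
    repeat {
        a <- atoms(mol)
        if (!nrow(a) || all(a$charge == 0L)) break
        adj <- .adjacency(mol)
        hs <- .implicitH(mol)
        rank <- .canonicalRanks(mol)
        paired <- vapply(seq_len(nrow(a)), function(i) {
            any(sign(a$charge[adj[[i]]]) == -sign(a$charge[i]) &
                a$charge[adj[[i]]] != 0L)
        }, logical(1))
        posRem <- which(a$charge > 0L & hs > 0L)
        negAcc <- which(a$charge < 0L & a$element %in% .H_ACCEPTORS)
        pick <- function(idx) idx[order(rank[idx], idx)][1]
        net <- sum(a$charge)
        freePos <- posRem[!paired[posRem]]
        freeNeg <- negAcc[!paired[negAcc]]
        if (length(freePos) && length(freeNeg)) {
            p <- pick(freePos); q <- pick(freeNeg)
            a$charge[p] <- a$charge[p] - 1L
            a$charge[q] <- a$charge[q] + 1L
        } else if (net > 0L && length(freePos)) {
            p <- pick(freePos)
            a$charge[p] <- a$charge[p] - 1L
        } else if (net < 0L && length(negAcc)) {
            q <- if (length(freeNeg)) pick(freeNeg) else pick(negAcc)
            a$charge[q] <- a$charge[q] + 1L
        } else break
        mol <- .withGraph(mol, a)
        changed <- TRUE
    }
    list(mol = mol, changed = changed)
}

# --- geometry --------------------------------------------------------------

.STRAIGHT_TOL <- 1e-3  # radians

.angleAt <- function(a, centre, c) {
    u <- a - centre; v <- c - centre
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-9 || nv < 1e-9) return(NA_real_)
    acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

# Make the atoms around triple bonds and allene centres collinear by moving
# the outer substituent onto the extended axis, preserving its distance.
# Topology is untouched; only coordinates change, and only when the angle
# deviates by more than the tolerance (so 4-decimal coordinate rounding in
# the written molblock cannot cause drift on re-standardization).
.stepStraighten <- function(mol) {
    b <- bonds(mol)
    if (!nrow(b)) return(list(mol = mol, changed = FALSE))
    a <- atoms(mol)
    adj <- .adjacency(mol)
    coords <- function(i) c(a$x[i], a$y[i], a$z[i])
    setc <- function(i, p) { a$x[i] <<- p[1]; a$y[i] <<- p[2]; a$z[i] <<- p[3] }
    changed <- FALSE
    fix <- function(anchor, centre, outer) {
        # move `outer` onto the line anchor->centre, beyond centre
        pa <- coords(anchor); pc <- coords(centre); po <- coords(outer)
        ang <- .angleAt(pa, pc, po)
        if (is.na(ang) || abs(ang - pi) <= .STRAIGHT_TOL) return()
        u <- pc - pa
        nu <- sqrt(sum(u^2))
        if (nu < 1e-9) return()
        d <- sqrt(sum((po - pc)^2))
        setc(outer, pc + u / nu * d)
        changed <<- TRUE
    }
    for (sweep in 1:2) {
        for (e in which(b$order == 3L)) {
            p <- b$begin[e]; q <- b$end[e]
            for (o in setdiff(adj[[p]], q)) fix(q, p, o)
            for (o in setdiff(adj[[q]], p)) fix(p, q, o)
        }
        dblCount <- integer(nrow(a))
        for (e in which(b$order == 2L)) {
            dblCount[b$begin[e]] <- dblCount[b$begin[e]] + 1L
            dblCount[b$end[e]] <- dblCount[b$end[e]] + 1L
        }
        for (m in which(dblCount == 2L & lengths(adj) == 2L)) {
            nb <- adj[[m]]
            fix(nb[1], m, nb[2])
        }
    }
    list(mol = .withGraph(mol, a), changed = changed)
}

# --- the full pipeline -----------------------------------------------------

# Internal: run the standardization steps on a parsed, non-excluded
# Molecule. Returns list(mol=, applied=).
.standardizeMolecule <- function(mol, ruleNames) {
    applied <- character()
    note <- function(nm, res) {
        if (res$changed) applied <<- c(applied, nm)
        res$mol
    }
    mol <- note("unknown_stereo", .stepUnknownStereo(mol))
    if (mol@hasAnySgroup) {
        applied <- c(applied, "clear_sgroups")
        mol@hasAnySgroup <- FALSE
        mol@hasPolymerSgroup <- FALSE
    }
    mol <- note("kekulize", .stepKekulize(mol))
    mol <- note("remove_explicit_hs", .stepRemoveExplicitH(mol))
    # neutralization is the closing sub-rule of the normalization block and
    # can expose new rule matches (a protonation-balanced N=C-OH, say), so
    # the two iterate jointly to a fixpoint
    for (pass in seq_len(.MAX_NORMALIZE_PASSES)) {
        res <- .stepNormalize(mol, ruleNames)
        mol <- res$mol
        applied <- c(applied, res$applied)
        resU <- .stepNeutralize(mol)
        mol <- resU$mol
        if (resU$changed) applied <- c(applied, "neutralize")
        if (!length(res$applied) && !resU$changed) break
        if (pass == .MAX_NORMALIZE_PASSES)
            stop("normalization/neutralization did not converge (rule cycle)")
    }
    applied <- unique(applied)
    mol <- note("straighten", .stepStraighten(mol))
    list(mol = mol, applied = applied)
}

#' Standardize a molblock
#'
#' Applies the exclusion rule and, for non-excluded records, the full
#' ordered standardization pipeline. Excluded records are returned
#' byte-identical with \code{excludeFlag=TRUE}. The pipeline is idempotent:
#' feeding the output back in reproduces it exactly.
#'
#' @param text a parseable molblock string (parse failure is an error here,
#'   unlike the checker, which scores it).
#' @param computeChanged logical; compute InChIKeys before/after and the
#'   \code{changed} flag (two engine calls). Set FALSE for bulk runs where
#'   only the structure is needed.
#' @param rulesFile,metalsFile configuration files (see
#'   [defaultRulesFile()], [defaultMetalsFile()]).
#' @param boronThreshold largest permitted boron count.
#' @return a \linkS4class{StandardizationResult}.
#' @examples
#' res <- standardizeMolblock(exampleMolblock("sodium_acetate"))
#' res@appliedRules
#' @export
standardizeMolblock <- function(text, computeChanged = TRUE,
                                rulesFile = defaultRulesFile(),
                                metalsFile = defaultMetalsFile(),
                                boronThreshold = 7L) {
    mol <- parseMolblock(text)
    if (!parseOk(mol))
        stop("cannot standardize: ", mol@parseError)
    rules <- exclusionRules(metalsFile, boronThreshold)
    if (computeExcludeFlag(mol, rules)) {
        return(new("StandardizationResult", molblock = text,
                   excludeFlag = TRUE, appliedRules = character(),
                   changed = FALSE, inchikeyBefore = "", inchikeyAfter = ""))
    }
    res <- .standardizeMolecule(mol, .enabledRuleNames(rulesFile))
    out <- writeMolblock(res$mol)
    keyBefore <- ""; keyAfter <- ""; chg <- NA
    if (computeChanged) {
        keyBefore <- .inchikeyOf(text)
        keyAfter <- .inchikeyOf(out)
        chg <- !identical(keyBefore, keyAfter)
    }
    new("StandardizationResult", molblock = out, excludeFlag = FALSE,
        appliedRules = res$applied, changed = chg,
        inchikeyBefore = keyBefore, inchikeyAfter = keyAfter)
}
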