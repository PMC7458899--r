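# Stereocentre counting and cross-validation.
#
# Three independent counts are compared for every record:
#   mol        - atoms from which a wedged/hashed bond (stereo code 1 or 6)
#                originates, i.e. what the depositor drew;
#   inchi      - tetrahedral centres in the main /t layer of the Standard
#                InChI computed from the molfile;
#   perception - tetrahedral centres assigned by algorithmic stereo
#                perception (the engine's canonical SMILES).
# Disagreements between the three are classified into the four mismatch
# flags; molfile-vs-InChI disagreements carry the higher penalty because the
# database identifier is derived from the molfile.

.WEDGE_CODES <- c(1L, 6L)

.wedgeOriginAtoms <- function(mol) {
    b <- bonds(mol)
    unique(b$begin[b$stereo %in% .WEDGE_CODES])
}

#' Count stereocentres by the three perception routes
#'
#' @param mol a parsed \linkS4class{Molecule}.
#' @param inchi optional precomputed result of [computeInchi()] for the same
#'   record (recomputed when missing).
#' @return a named integer vector with elements \code{mol}, \code{inchi},
#'   \code{perception}.
#' @seealso [classifyStereoMismatch()]
#' @export
countStereo <- function(mol, inchi = NULL) {
    stopifnot(is(mol, "Molecule"), parseOk(mol))
    if (is.null(inchi)) inchi <- computeInchi(mol)
    c(mol = length(.wedgeOriginAtoms(mol)),
      inchi = .inchiTetraCount(inchi$inchi),
      perception = .perceivedStereoCount(mol))
}

#' Classify a stereocentre-count disagreement
#'
#' Total over non-negative integer triples: agreement of all three counts
#' yields no issue; the two routes that agree determine which mismatch flag
#' is raised, and all-distinct triples get their own flag.
#'
#' @param counts integer vector (or named vector from [countStereo()]) of
#'   the three counts in the order mol, inchi, perception.
#' @return NULL, or a one-row issue data.frame (columns \code{score},
#'   \code{label}).
#' @export
classifyStereoMismatch <- function(counts) {
    stopifnot(length(counts) == 3L, all(counts >= 0))
    m <- counts[[1]]; i <- counts[[2]]; p <- counts[[3]]
    if (m == i && i == p) return(NULL)
    if (i == p)  # molfile is the odd one out
        return(data.frame(score = 5L, label = "InChI_RDKit/Mol stereo mismatch",
                          stringsAsFactors = FALSE))
    if (m == p)  # InChI is the odd one out
        return(data.frame(score = 5L, label = "RDKit_Mol/InChI stereo mismatch",
                          stringsAsFactors = FALSE))
    if (m == i)  # perception is the odd one out: least serious
        return(data.frame(score = 2L, label = "InChI_Mol/RDKit stereo mismatch",
                          stringsAsFactors = FALSE))
    data.frame(score = 5L, label = "Mol/Inchi/RDKit stereo mismatch",
               stringsAsFactors = FALSE)
}

# Potential tetrahedral stereocentre test used by the stereo-drawing checks:
# a carbon/silicon with four substituents (implicit+explicit H <= 1) whose
# heavy neighbours fall in pairwise distinct canonical-rank classes. Morgan
# ranks equate constitutionally equivalent branches; rare rank collisions of
# genuinely different branches would under-report, which is acceptable for a
# drawing-quality flag.
.potentialStereocentres <- function(mol) {
    a <- atoms(mol)
    n <- nrow(a)
    if (!n) return(integer())
    adj <- .adjacency(mol)
    b <- bonds(mol)
    multi <- unique(c(b$begin[b$order %in% c(2L, 3L, 4L)],
                      b$end[b$order %in% c(2L, 3L, 4L)]))
    hs <- .implicitH(mol)
    rank <- .canonicalRanks(mol)
    out <- integer()
    for (v in seq_len(n)) {
        if (!a$element[v] %in% c("C", "Si")) next
        if (v %in% multi) next
        nbrs <- adj[[v]]
        hNbrs <- nbrs[a$element[nbrs] == "H"]
        heavy <- nbrs[a$element[nbrs] != "H"]
        totalH <- hs[v] + length(hNbrs)
        if (length(heavy) + totalH != 4L || totalH > 1L) next
        rks <- rank[heavy]
        if (anyDuplicated(rks)) next
        out <- c(out, v)
    }
    out
}
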