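# Element data and the molfile implicit-hydrogen valence model.

.ELEMENTS <- c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
    "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
    "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
    "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
    "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
    "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
    "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
    "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
    "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# CTfile default valence lists for the elements that take implicit hydrogens;
# everything else (metals, noble gases) gets none.
.VALENCES <- list(
    H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
    Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
    As = c(3L, 5L), Se = c(2L, 4L, 6L), Br = 1L,
    Te = c(2L, 4L, 6L), I = 1L, Al = 3L
)

.HALOGENS <- c("F", "Cl", "Br", "I", "At")
.ALKALI_METALS <- c("Li", "Na", "K", "Rb", "Cs", "Fr")

.isKnownElement <- function(sym) sym %in% .ELEMENTS

# Charge-adjusted default valence list for an element. Follows the usual
# SMILES/CTfile convention: carbon and silicon lose capacity with charge of
# either sign, boron/aluminium gain on the anion, other main-group elements
# shift by +charge (N+ -> 4, O- -> 1, Cl- -> 0, ...).
.defaultValences <- function(element, charge = 0L) {
    v <- .VALENCES[[element]]
    if (is.null(v)) return(integer())
    if (element %in% c("C", "Si")) {
        pmax(v - abs(charge), 0L)
    } else if (element %in% c("B", "Al")) {
        pmax(v - charge, 0L)
    } else {
        pmax(v + charge, 0L)
    }
}

# Implicit hydrogen count under the molfile convention: the smallest default
# valence that accommodates the explicit bond-order sum, minus that sum.
# Hypervalent atoms drawn explicitly (sum exceeds every default) get none.
# Aromatic bonds (code 4) count 1.5, rounded down on the total, matching the
# usual reading of un-kekulized input; query codes count 1.
.implicitHCount <- function(element, charge, bondOrderSum) {
    vals <- .defaultValences(element, charge)
    if (!length(vals)) return(0L)
    ok <- vals[vals >= bondOrderSum]
    if (!length(ok)) return(0L)
    as.integer(min(ok) - floor(bondOrderSum))
}

# Per-atom explicit bond-order sum for a Molecule (aromatic code 4 as 1.5;
# codes outside 1:4 treated as single so malformed input still gets a number).
.bondOrderSums <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    s <- numeric(nrow(a))
    if (nrow(b)) {
        ord <- ifelse(b$order == 4L, 1.5,
                      ifelse(b$order %in% 1:3, b$order, 1))
        for (i in seq_len(nrow(b))) {
            s[b$begin[i]] <- s[b$begin[i]] + ord[i]
            s[b$end[i]] <- s[b$end[i]] + ord[i]
        }
    }
    s
}

# Implicit H for every atom of a Molecule.
.implicitH <- function(mol) {
    a <- atoms(mol)
    if (!nrow(a)) return(integer())
    s <- .bondOrderSums(mol)
    vapply(seq_len(nrow(a)), function(i) {
        .implicitHCount(a$element[i], a$charge[i], s[i])
    }, integer(1))
}
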