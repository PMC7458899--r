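# Kekulization of aromatic (bond code 4) systems.
#
# Every atom incident to an aromatic bond either takes exactly one double
# bond within the aromatic subgraph or contributes a lone pair. Atoms with
# remaining valence capacity must take a double bond; N/P/As/O/S/Se
# heteroatoms (and charged carbons) may instead stay all-single. A perfect
# matching over the must-atoms is searched by backtracking; failure is the
# classic "cannot process aromatic bonds" error.

.kekulizeMolecule <- function(mol) {
    b <- bonds(mol)
    arom <- which(b$order == 4L)
    if (!length(arom)) return(mol)
    a <- atoms(mol)
    aromAtoms <- sort(unique(c(b$begin[arom], b$end[arom])))

    # valence already used by non-aromatic bonds + 1 per aromatic bond
    used <- numeric(nrow(a))
    for (i in seq_len(nrow(b))) {
        o <- if (b$order[i] == 4L) 1 else if (b$order[i] %in% 1:3) b$order[i] else 1
        used[b$begin[i]] <- used[b$begin[i]] + o
        used[b$end[i]] <- used[b$end[i]] + o
    }
    capacity <- vapply(aromAtoms, function(i) {
        vals <- .defaultValences(a$element[i], a$charge[i])
        if (!length(vals)) return(0L)
        ok <- vals[vals >= used[i]]
        # a radical electron occupies one valence slot
        rad <- if (a$radical[i] > 0L) 1L else 0L
        if (!length(ok)) 0L else as.integer(min(ok) - used[i] - rad)
    }, integer(1))
    canDouble <- capacity >= 1L
    optional <- a$element[aromAtoms] %in% c("N", "P", "As", "O", "S", "Se") |
        a$charge[aromAtoms] != 0L | a$radical[aromAtoms] > 0L
    must <- canDouble & !optional

    # neighbour lists within the aromatic subgraph (positions into aromAtoms)
    pos <- integer(nrow(a)); pos[aromAtoms] <- seq_along(aromAtoms)
    nbr <- vector("list", length(aromAtoms))
    for (e in arom) {
        p <- pos[b$begin[e]]; q <- pos[b$end[e]]
        nbr[[p]] <- rbind(nbr[[p]], c(q, e))
        nbr[[q]] <- rbind(nbr[[q]], c(p, e))
    }

    matched <- integer(length(aromAtoms))  # 0 = unmatched, else bond row id
    assign_ <- function(k) {
        if (k > length(aromAtoms)) return(TRUE)
        if (matched[k] || !canDouble[k]) return(assign_(k + 1L))
        edges <- nbr[[k]]
        if (!is.null(edges)) {
            for (r in seq_len(nrow(edges))) {
                q <- edges[r, 1]
                if (matched[q] || !canDouble[q]) next
                matched[k] <<- edges[r, 2]
                matched[q] <<- edges[r, 2]
                if (assign_(k + 1L)) return(TRUE)
                matched[k] <<- 0L
                matched[q] <<- 0L
            }
        }
        # leaving k unmatched is allowed only for optional atoms
        if (!must[k]) return(assign_(k + 1L))
        FALSE
    }
    if (!assign_(1L))
        stop("cannot kekulize aromatic bonds: no alternating assignment exists")

    doubleEdges <- unique(matched[matched > 0L])
    b$order[arom] <- 1L
    b$order[doubleEdges] <- 2L
    .withGraph(mol, bonds = b)
}
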