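# Small-molecule graph utilities: connectivity, ring membership, canonical
# ranks. Molecules here are tiny (<= 999 atoms), so plain R adjacency lists
# are entirely adequate.

.adjacency <- function(mol) {
    a <- atoms(mol); b <- bonds(mol)
    adj <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) adj[[i]] <- integer()
    if (nrow(b)) {
        for (i in seq_len(nrow(b))) {
            adj[[b$begin[i]]] <- c(adj[[b$begin[i]]], b$end[i])
            adj[[b$end[i]]] <- c(adj[[b$end[i]]], b$begin[i])
        }
    }
    adj
}

.componentLabels <- function(mol) {
    n <- natoms(mol)
    if (!n) return(integer())
    adj <- .adjacency(mol)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s]) next
        cur <- cur + 1L
        stack <- s
        while (length(stack)) {
            v <- stack[length(stack)]; stack <- stack[-length(stack)]
            if (comp[v]) next
            comp[v] <- cur
            stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
        }
    }
    comp
}

#' Split a Molecule into connected components
#'
#' Components are returned in order of first appearance of their atoms in
#' the input atom block; atom order within a component is preserved, and the
#' component atom counts sum to the input atom count.
#'
#' @param mol a parsed \linkS4class{Molecule} with \code{parseOk=TRUE}.
#' @return a list of \linkS4class{Molecule} objects.
#' @examples
#' mols <- splitComponents(parseMolblock(exampleMolblock("sodium_acetate")))
#' length(mols)
#' @export
splitComponents <- function(mol) {
    stopifnot(is(mol, "Molecule"), parseOk(mol))
    comp <- .componentLabels(mol)
    if (!length(comp)) return(list())
    lapply(seq_len(max(comp)), function(k) .subsetAtoms(mol, which(comp == k)))
}

# Extract the sub-molecule induced by `keep` (atom indices, input order kept).
.subsetAtoms <- function(mol, keep) {
    a <- atoms(mol)[keep, , drop = FALSE]
    b <- bonds(mol)
    remap <- integer(natoms(mol))
    remap[keep] <- seq_along(keep)
    if (nrow(b)) {
        sel <- b$begin %in% keep & b$end %in% keep
        b <- b[sel, , drop = FALSE]
        b$begin <- remap[b$begin]
        b$end <- remap[b$end]
    }
    rownames(a) <- NULL; rownames(b) <- NULL
    out <- mol
    out@atoms <- a
    out@bonds <- b
    out@rawText <- ""
    out
}

# Bond ring membership: a bond is in a ring iff it is not a bridge.
# Tarjan bridge finding via iterative DFS.
.ringBonds <- function(mol) {
    b <- bonds(mol)
    nb <- nrow(b)
    if (!nb) return(logical(0))
    n <- natoms(mol)
    # adjacency carrying bond ids
    adj <- vector("list", n)
    for (i in seq_len(nb)) {
        adj[[b$begin[i]]] <- rbind(adj[[b$begin[i]]], c(b$end[i], i))
        adj[[b$end[i]]] <- rbind(adj[[b$end[i]]], c(b$begin[i], i))
    }
    disc <- integer(n); low <- integer(n)
    isBridge <- logical(nb)
    timer <- 0L
    for (root in seq_len(n)) {
        if (disc[root]) next
        # iterative DFS with explicit stack of (vertex, parent-bond, next-edge)
        stack <- list(list(v = root, pb = 0L, i = 1L))
        while (length(stack)) {
            fr <- stack[[length(stack)]]
            v <- fr$v
            if (fr$i == 1L && !disc[v]) {
                timer <- timer + 1L
                disc[v] <- timer; low[v] <- timer
            }
            edges <- adj[[v]]
            if (is.null(edges) || fr$i > nrow(edges)) {
                stack[[length(stack)]] <- NULL
                if (length(stack)) {
                    pf <- stack[[length(stack)]]
                    u <- pf$v
                    low[u] <- min(low[u], low[v])
                    if (low[v] > disc[u]) isBridge[fr$pb] <- TRUE
                }
                next
            }
            w <- edges[fr$i, 1]; eid <- edges[fr$i, 2]
            stack[[length(stack)]]$i <- fr$i + 1L
            if (eid == fr$pb) next
            if (disc[w]) {
                low[v] <- min(low[v], disc[w])
            } else {
                stack[[length(stack) + 1L]] <- list(v = w, pb = eid, i = 1L)
            }
        }
    }
    !isBridge
}

# Morgan-style canonical ranks: iterative partition refinement over
# (element, charge, isotope, radical, degree, bond-order sum, implicit H),
# then neighbour-rank multisets. Equal final ranks identify constitutionally
# equivalent atoms (up to the usual Morgan limitations, ample for the
# canonical tie-breaks they serve here).
.canonicalRanks <- function(mol) {
    a <- atoms(mol)
    n <- nrow(a)
    if (!n) return(integer())
    adj <- .adjacency(mol)
    bos <- .bondOrderSums(mol)
    hs <- .implicitH(mol)
    key <- paste(a$element, a$charge, a$isotope, a$radical,
                 lengths(adj), bos, hs, sep = "|")
    rank <- as.integer(factor(key, levels = sort(unique(key))))
    for (iter in seq_len(n)) {
        nb <- vapply(seq_len(n), function(i) {
            paste(sort(rank[adj[[i]]]), collapse = ",")
        }, character(1))
        key2 <- paste(rank, nb, sep = ";")
        rank2 <- as.integer(factor(key2, levels = sort(unique(key2))))
        if (identical(rank2, rank)) break
        rank <- rank2
    }
    rank
}

# Reorder atoms by a permutation (perm[i] = old index placed at position i).
.permuteAtoms <- function(mol, perm) {
    stopifnot(length(perm) == natoms(mol))
    a <- atoms(mol)[perm, , drop = FALSE]
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    b <- bonds(mol)
    if (nrow(b)) {
        b$begin <- inv[b$begin]
        b$end <- inv[b$end]
    }
    .withGraph(mol, a, b)
}
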