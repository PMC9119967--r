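# Circular (Morgan) fingerprints on the graph container, Bemis-Murcko
# scaffolds by graph pruning, bit-vector similarity metrics and the
# scaffold-distance threshold calibration used by the augmentation engine.
#
# The fingerprint is computed directly on `mol_graph` objects so that
# bond-deleted (augmented) structures and scaffold subgraphs can be
# fingerprinted without a SMILES round trip. Atom invariants are the schema
# descriptors; neighbour environments are hashed order-independently.

.hash_mod <- 2147483647  # 2^31 - 1; doubles keep exact integers well beyond this

hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x %% .hash_mod)) %% .hash_mod
  h
}

fp_bond_code <- function(bonds) {
  ifelse(bonds$aromatic, 4L, bonds$order)
}

#' Morgan (circular) fingerprint of a molecular graph
#'
#' Hashed circular-substructure fingerprint: atom invariants are derived from
#' the schema descriptors (element, degree, charge, hydrogen count, ring and
#' aromatic flags); each iteration hashes the atom's invariant with the
#' sorted (bond type, neighbour invariant) list, and every environment from
#' radius 0 to `radius` sets one bit modulo `nbits`.
#'
#' @param graph A `mol_graph`.
#' @param radius Neighborhood radius (default 2).
#' @param nbits Fingerprint length in bits (default 2048).
#' @return Logical vector of length `nbits`.
#' @export
morgan_fp <- function(graph, radius = 2L, nbits = 2048L) {
  stopifnot(inherits(graph, "mol_graph"))
  a <- graph$atoms
  n <- graph$node_count
  inv <- vapply(seq_len(n), function(i) {
    hash_ints(c(a$atomic_num[i], a$degree[i], a$formal_charge[i],
                a$num_hs[i], as.integer(a$aromatic[i]), as.integer(a$in_ring[i])))
  }, numeric(1))
  b <- graph$bonds
  bcode <- fp_bond_code(b)
  nb <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(b) > 0) {
    for (j in seq_len(nrow(b))) {
      nb[[b$a1[j]]] <- c(nb[[b$a1[j]]], j)
      nb[[b$a2[j]]] <- c(nb[[b$a2[j]]], j)
    }
  }
  bits <- inv %% nbits
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      inv_new <- inv
      for (i in seq_len(n)) {
        js <- nb[[i]]
        if (length(js) == 0) { inv_new[i] <- hash_ints(c(r, inv[i])); next }
        other <- ifelse(b$a1[js] == i, b$a2[js], b$a1[js])
        ord <- order(bcode[js], inv[other])
        inv_new[i] <- hash_ints(c(r, inv[i],
                                  rbind(bcode[js][ord], inv[other][ord])))
      }
      inv <- inv_new
      bits <- c(bits, inv %% nbits)
    }
  }
  out <- logical(nbits)
  out[bits + 1] <- TRUE
  out
}

## ---- bit-vector similarities -----------------------------------------------

fp_counts <- function(x, y) {
  if (length(x) != length(y)) stop("fingerprint length mismatch", call. = FALSE)
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y)
  list(a = a, b = b, c = c, d0 = length(x) - a - b - c)
}

#' Rogot-Goldberg similarity
#'
#' `RGS = a/(2a+b+c) + d0/(2d0+b+c)` over common on-bits `a`, exclusive bits
#' `b`, `c` and common off-bits `d0`. Identical vectors give exactly 1; a
#' term with zero denominator contributes 0 (reachable only when the vectors
#' differ and one term is empty).
#'
#' @param x,y Logical (or 0/1) vectors of equal length, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' a <- c(FALSE, TRUE, TRUE, rep(FALSE, 5))
#' b <- c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 4))
#' rogot_goldberg(a, b)  # 1/4 + 5/12
rogot_goldberg <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (identical(x, y)) {
    if (length(x) == 0) stop("empty fingerprints", call. = FALSE)
    return(1)
  }
  k <- fp_counts(x, y)
  t1 <- if (2 * k$a + k$b + k$c > 0) k$a / (2 * k$a + k$b + k$c) else 0
  t2 <- if (2 * k$d0 + k$b + k$c > 0) k$d0 / (2 * k$d0 + k$b + k$c) else 0
  t1 + t2
}

#' @rdname fingerprint_similarities
#' @export
tanimoto_sim <- function(x, y) {
  k <- fp_counts(as.logical(x), as.logical(y))
  if (k$a + k$b + k$c == 0) return(1)
  k$a / (k$a + k$b + k$c)
}

#' Fingerprint similarity metrics
#'
#' Classical binary-fingerprint similarities used for the metric comparison:
#' Tanimoto `a/(a+b+c)`, Dice `2a/(2a+b+c)`, Sokal-Sneath `a/(a+2b+2c)`,
#' Russel-Rao `a/n` and Rogot-Goldberg (see [rogot_goldberg()]).
#'
#' @param x,y Logical (or 0/1) vectors of equal length.
#' @return Similarity value.
#' @name fingerprint_similarities
#' @export
dice_sim <- function(x, y) {
  k <- fp_counts(as.logical(x), as.logical(y))
  if (2 * k$a + k$b + k$c == 0) return(1)
  2 * k$a / (2 * k$a + k$b + k$c)
}

#' @rdname fingerprint_similarities
#' @export
sokal_sim <- function(x, y) {
  k <- fp_counts(as.logical(x), as.logical(y))
  if (k$a + 2 * (k$b + k$c) == 0) return(1)
  k$a / (k$a + 2 * (k$b + k$c))
}

#' @rdname fingerprint_similarities
#' @export
russel_sim <- function(x, y) {
  k <- fp_counts(as.logical(x), as.logical(y))
  k$a / length(x)
}

## ---- Bemis-Murcko scaffold -------------------------------------------------

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them: terminal non-ring atoms are
#' pruned iteratively, then atoms double- or triple-bonded directly to the
#' remaining framework are restored (so exocyclic carbonyls on a ring stay).
#' Acyclic molecules have an empty scaffold.
#'
#' @param graph A `mol_graph`.
#' @return A list of class `murcko_scaffold`: `graph` (the scaffold as a
#'   `mol_graph`, or `NULL`), `atoms` (indices into the input graph) and
#'   `empty`.
#' @export
murcko_scaffold <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  n <- graph$node_count
  b <- graph$bonds
  if (!any(graph$atoms$in_ring)) {
    return(structure(list(graph = NULL, atoms = integer(0), empty = TRUE),
                     class = "murcko_scaffold"))
  }
  keep <- rep(TRUE, n)
  repeat {
    deg <- numeric(n)
    sel <- keep[b$a1] & keep[b$a2]
    if (any(sel)) {
      tab <- table(c(b$a1[sel], b$a2[sel]))
      deg[as.integer(names(tab))] <- tab
    }
    drop <- keep & !graph$atoms$in_ring & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # restore atoms multiple-bonded directly to the framework
  readd <- !keep[b$a1] & keep[b$a2] & b$order >= 2 & !b$aromatic
  readd2 <- keep[b$a1] & !keep[b$a2] & b$order >= 2 & !b$aromatic
  keep[b$a1[readd]] <- TRUE
  keep[b$a2[readd2]] <- TRUE
  atoms <- which(keep)
  structure(list(graph = induce_subgraph(graph, atoms), atoms = atoms,
                 empty = FALSE),
            class = "murcko_scaffold")
}

#' Augmentation configuration
#'
#' @param mu Scaffold-distance threshold (`NULL` until calibrated with
#'   [calibrate_mu()] or supplied explicitly).
#' @param radius,nbits Morgan fingerprint parameters (defaults 2 and 2048).
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(mu = NULL, radius = 2L, nbits = 2048L) {
  if (!is.null(mu)) stopifnot(mu >= 0)
  structure(list(mu = mu, radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "augmentation_config")
}

# Scaffold reference: scaffold graph + its fingerprint, reused across
# candidate evaluations.
scaffold_ref <- function(graph, config = augmentation_config()) {
  sc <- murcko_scaffold(graph)
  fp <- if (sc$empty) NULL else morgan_fp(sc$graph, config$radius, config$nbits)
  structure(list(scaffold = sc, fp = fp, empty = sc$empty, config = config),
            class = "scaffold_ref")
}

#' Distance of a molecule to a scaffold reference
#'
#' `d(M_s, M') = 1 - RGS(M_s, M')` over Morgan fingerprints, where `M_s` is
#' the fixed scaffold reference of the original molecule and `M'` the
#' (possibly bond-deleted) structure being evaluated.
#'
#' @param graph A `mol_graph` (e.g. an augmented molecule).
#' @param ref A `scaffold_ref` (or a `mol_graph`, whose scaffold is taken).
#' @param config Fingerprint parameters when `ref` is a `mol_graph`.
#' @return Distance in `[0, 1]`.
#' @export
scaffold_distance <- function(graph, ref, config = augmentation_config()) {
  if (inherits(ref, "mol_graph")) ref <- scaffold_ref(ref, config)
  if (ref$empty) stop("scaffold is empty (acyclic molecule)", call. = FALSE)
  1 - rogot_goldberg(ref$fp, morgan_fp(graph, ref$config$radius, ref$config$nbits))
}

#' Calibrate the scaffold-distance threshold
#'
#' `mu` is the largest distance from any active molecule to its own
#' Bemis-Murcko scaffold. Acyclic actives (empty scaffold) are excluded from
#' the maximum and reported via the `excluded` attribute.
#'
#' @param actives List of `mol_graph`s (the target's training actives).
#' @param config An [augmentation_config()].
#' @return The calibrated threshold, a number in `[0, 1]`, with attribute
#'   `excluded` (number of acyclic actives skipped).
#' @export
calibrate_mu <- function(actives, config = augmentation_config()) {
  if (length(actives) == 0) stop("empty active set", call. = FALSE)
  d <- rep(NA_real_, length(actives))
  for (i in seq_along(actives)) {
    ref <- scaffold_ref(actives[[i]], config)
    if (!ref$empty) d[i] <- scaffold_distance(actives[[i]], ref)
  }
  if (all(is.na(d))) stop("all actives have empty scaffolds; cannot calibrate mu",
                          call. = FALSE)
  structure(max(d, na.rm = TRUE), excluded = sum(is.na(d)))
}
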