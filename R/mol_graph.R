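# Bidirected molecular graphs with the nine-atom / three-bond one-hot schema.
#
# Nodes are heavy atoms (hydrogens enter only through the hydrogen-count
# descriptor); every chemical bond is stored as two directed edges with
# identical feature rows. Atom order follows the input SMILES.

# valence electrons for lone-pair counting (main-group elements)
.valence_e <- c(`1` = 1, `5` = 3, `6` = 4, `7` = 5, `8` = 6, `9` = 7,
                `14` = 4, `15` = 5, `16` = 6, `17` = 7, `33` = 5, `34` = 6,
                `35` = 7, `53` = 7)

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba")

# Derived per-atom descriptors reproducing the reference (RDKit) semantics of
# the schema: hybridization from the steric number with promotion of
# lone-pair heteroatoms that sit in a conjugated bond, conjugation as
# "both endpoints are conjugation candidates".
derive_perception <- function(atoms, bonds) {
  n <- nrow(atoms)
  degree <- integer(n)
  tbo <- numeric(n) # total bond order over heavy neighbours (kekulized orders)
  has_multiple <- logical(n)
  if (nrow(bonds) > 0) {
    for (j in seq_len(nrow(bonds))) {
      a1 <- bonds$a1[j]; a2 <- bonds$a2[j]
      degree[a1] <- degree[a1] + 1L; degree[a2] <- degree[a2] + 1L
      tbo[a1] <- tbo[a1] + bonds$order[j]; tbo[a2] <- tbo[a2] + bonds$order[j]
      if (bonds$order[j] > 1L || bonds$aromatic[j]) {
        has_multiple[a1] <- TRUE; has_multiple[a2] <- TRUE
      }
    }
  }
  nsigma <- degree + atoms$num_hs
  ve <- .valence_e[as.character(atoms$atomic_num)]
  ve[is.na(ve)] <- 0
  lone_pairs <- pmax(0, floor((ve - atoms$formal_charge - (tbo + atoms$num_hs)) / 2))
  steric <- nsigma + lone_pairs

  hyb <- ifelse(atoms$aromatic, "sp2",
         ifelse(steric <= 2, "sp",
         ifelse(steric == 3, "sp2",
         ifelse(steric == 4, "sp3",
         ifelse(steric == 5, "sp3d", "sp3d2")))))

  candidate <- atoms$atomic_num %in% c(6L, 7L, 8L, 15L, 16L) &
    nsigma <= 3 & (has_multiple | atoms$aromatic | lone_pairs > 0)

  # a bond is conjugated when it belongs to a conjugated system: both of its
  # atoms are candidates and at least one endpoint has a further candidate
  # neighbour (an isolated multiple bond is not conjugated)
  conj <- logical(nrow(bonds))
  if (nrow(bonds) > 0) {
    n_cand_nb <- integer(n)
    for (j in seq_len(nrow(bonds))) {
      if (candidate[bonds$a2[j]]) n_cand_nb[bonds$a1[j]] <- n_cand_nb[bonds$a1[j]] + 1L
      if (candidate[bonds$a1[j]]) n_cand_nb[bonds$a2[j]] <- n_cand_nb[bonds$a2[j]] + 1L
    }
    for (j in seq_len(nrow(bonds))) {
      u <- bonds$a1[j]; v <- bonds$a2[j]
      if (!candidate[u] || !candidate[v]) next
      # candidate neighbours beyond this bond's partner
      conj[j] <- (n_cand_nb[u] - 1L) > 0 || (n_cand_nb[v] - 1L) > 0
    }
  }

  promote <- !atoms$aromatic & hyb == "sp3" & lone_pairs > 0 &
    atoms$atomic_num %in% c(7L, 8L, 15L, 16L)
  if (any(promote) && nrow(bonds) > 0) {
    in_conj <- logical(n)
    in_conj[bonds$a1[conj]] <- TRUE; in_conj[bonds$a2[conj]] <- TRUE
    hyb[promote & in_conj] <- "sp2"
  }
  list(degree = degree, hybridization = hyb, conjugated = conj)
}

new_mol_graph <- function(source, atoms, bonds, perception) {
  n <- nrow(atoms)
  aschema <- atom_feature_schema()
  bschema <- bond_feature_schema()
  node_features <- matrix(0, nrow = n, ncol = sum(aschema$sizes))
  for (i in seq_len(n)) {
    node_features[i, ] <- encode_atom(list(
      atomic_num    = atoms$atomic_num[i],
      chirality     = "unspecified",
      degree        = perception$degree[i],
      formal_charge = atoms$formal_charge[i],
      num_hs        = atoms$num_hs[i],
      num_radical_e = max(0L, atoms$spin[i] - 1L),
      hybridization = perception$hybridization[i],
      aromatic      = as.integer(atoms$aromatic[i]),
      in_ring       = as.integer(atoms$in_ring[i])
    ))
  }
  m <- nrow(bonds)
  edges <- matrix(integer(0), ncol = 2)
  bond_id <- integer(0)
  edge_features <- matrix(0, nrow = 0, ncol = sum(bschema$sizes))
  if (m > 0) {
    brow <- matrix(0, nrow = m, ncol = sum(bschema$sizes))
    btype <- character(m)
    for (j in seq_len(m)) {
      btype[j] <- if (bonds$aromatic[j]) "aromatic"
        else switch(as.character(bonds$order[j]),
                    "1" = "single", "2" = "double", "3" = "triple",
                    stop(sprintf("bond descriptor 'bond_type': order %d outside vocabulary",
                                 bonds$order[j]), call. = FALSE))
      brow[j, ] <- encode_bond(list(
        bond_type  = btype[j],
        stereo     = "none",
        conjugated = as.integer(perception$conjugated[j])
      ))
    }
    # rows 2j-1 and 2j are the two directions of chemical bond j
    edges <- cbind(rep(bonds$a1, each = 2), rep(bonds$a2, each = 2))
    rev_rows <- seq(2, 2 * m, by = 2)
    edges[rev_rows, ] <- edges[rev_rows, c(2, 1)]
    bond_id <- rep(seq_len(m), each = 2)
    edge_features <- brow[bond_id, , drop = FALSE]
    bonds$bond_type <- btype
    bonds$conjugated <- perception$conjugated
  }
  structure(
    list(source = source,
         node_count = n,
         edges = edges,             # |directed edges| x 2 (src, dst), 1-based
         bond_id = bond_id,         # chemical-bond index per directed edge
         node_features = node_features,
         edge_features = edge_features,
         atoms = cbind(atoms, degree = perception$degree,
                       hybridization = perception$hybridization),
         bonds = bonds),
    class = "mol_graph"
  )
}

#' Convert a SMILES string to a bidirected molecular graph
#'
#' Parses the SMILES with OpenBabel (via ChemmineOB) and featurizes every
#' heavy atom with the nine-descriptor schema and every bond (both directions)
#' with the three-descriptor schema. Node order follows the atom order of the
#' input string, so repeated calls are identical.
#'
#' @param smiles A single non-empty SMILES string.
#' @return A `mol_graph`: `node_count`, `edges` (directed pairs, two per
#'   chemical bond), `node_features`, `edge_features`, plus the raw perception
#'   tables `atoms` and `bonds`.
#' @export
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$node_count        # 6
#' nrow(g$edges)       # 12 directed edges
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("smiles must be a single non-empty string", call. = FALSE)
  parsed <- ob_read_smiles(smiles)
  if (is.null(parsed))
    stop(sprintf("unparseable SMILES: '%s'", smiles), call. = FALSE)
  perception <- derive_perception(parsed$atoms, parsed$bonds)
  new_mol_graph(smiles, parsed$atoms, parsed$bonds, perception)
}

#' Validate a molecular graph against the type invariants
#'
#' Checks the one-hot block structure of node and edge feature rows, the
#' closure of the directed edge set under reversal with equal feature rows,
#' absence of self loops, and node-index bounds.
#'
#' @param graph A `mol_graph`.
#' @return Character vector of violated invariants; empty when valid.
#' @export
validate_graph <- function(graph) {
  bad <- character(0)
  aschema <- atom_feature_schema(); bschema <- bond_feature_schema()
  n <- graph$node_count
  if (!is.numeric(n) || n < 1) bad <- c(bad, "node_count must be >= 1")
  block_ok <- function(feat, schema) {
    off <- schema_offsets(schema)
    for (i in seq_along(schema$sizes)) {
      cols <- (off[i] + 1):(off[i] + schema$sizes[i])
      s <- rowSums(feat[, cols, drop = FALSE])
      if (any(s != 1)) return(names(schema$descriptors)[i])
    }
    NULL
  }
  if (nrow(graph$node_features) != n) {
    bad <- c(bad, "node_features row count differs from node_count")
  } else if (n > 0) {
    nb <- block_ok(graph$node_features, aschema)
    if (!is.null(nb)) bad <- c(bad, sprintf("node one-hot block '%s' does not sum to 1", nb))
  }
  E <- nrow(graph$edges)
  if (nrow(graph$edge_features) != E) {
    bad <- c(bad, "edge_features row count differs from number of directed edges")
  } else if (E > 0) {
    eb <- block_ok(graph$edge_features, bschema)
    if (!is.null(eb)) bad <- c(bad, sprintf("edge one-hot block '%s' does not sum to 1", eb))
  }
  if (E > 0) {
    if (any(graph$edges[, 1] == graph$edges[, 2])) bad <- c(bad, "self-loop present")
    if (any(graph$edges < 1) || any(graph$edges > n))
      bad <- c(bad, "edge endpoint outside [1, node_count]")
    key <- paste(graph$edges[, 1], graph$edges[, 2])
    rkey <- paste(graph$edges[, 2], graph$edges[, 1])
    miss <- !(rkey %in% key)
    if (any(miss)) {
      bad <- c(bad, "bidirectionality violated: reverse edge missing")
    } else if (nrow(graph$edge_features) == E) {
      ridx <- match(rkey, key)
      if (any(abs(graph$edge_features - graph$edge_features[ridx, , drop = FALSE]) > 0))
        bad <- c(bad, "bidirectionality violated: reverse edge has different features")
    }
  }
  bad
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds (%d directed edges)\n  source: %s\n",
              x$node_count, nrow(x$bonds), nrow(x$edges),
              substr(x$source, 1, 60)))
  invisible(x)
}

# Induced subgraph on `keep` (node indices). Hydrogen counts of retained atoms
# are topped up by the number of severed single bonds so that fingerprint
# invariants see valence-filled atoms; degree is recomputed.
induce_subgraph <- function(graph, keep) {
  keep <- sort(unique(keep))
  remap <- integer(graph$node_count); remap[keep] <- seq_along(keep)
  atoms <- graph$atoms[keep, , drop = FALSE]
  b <- graph$bonds
  sel <- b$a1 %in% keep & b$a2 %in% keep
  lost1 <- tabulate(c(b$a1[!sel & b$a1 %in% keep], b$a2[!sel & b$a2 %in% keep]),
                    nbins = graph$node_count)
  atoms$num_hs <- atoms$num_hs + lost1[keep]
  bonds <- b[sel, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  perception <- derive_perception(atoms, bonds[, c("a1", "a2", "order", "aromatic", "in_ring")])
  new_mol_graph(paste0(graph$source, " [subgraph]"),
                atoms[, c("atomic_num", "formal_charge", "num_hs", "spin",
                          "aromatic", "in_ring")],
                bonds[, c("a1", "a2", "order", "aromatic", "in_ring")],
                perception)
}

# Remove one chemical bond (both directed edges). Atom feature rows keep the
# original perception except hydrogen count/degree, which are refilled; the
# result is a valid mol_graph with exactly one bond fewer.
delete_bond <- function(graph, bond) {
  stopifnot(bond >= 1, bond <= nrow(graph$bonds))
  atoms <- graph$atoms
  b <- graph$bonds
  atoms$num_hs[b$a1[bond]] <- atoms$num_hs[b$a1[bond]] + b$order[bond]
  atoms$num_hs[b$a2[bond]] <- atoms$num_hs[b$a2[bond]] + b$order[bond]
  bonds <- b[-bond, , drop = FALSE]
  rownames(bonds) <- NULL
  perception <- derive_perception(atoms, bonds[, c("a1", "a2", "order", "aromatic", "in_ring")])
  new_mol_graph(paste0(graph$source, " [-bond ", bond, "]"),
                atoms[, c("atomic_num", "formal_charge", "num_hs", "spin",
                          "aromatic", "in_ring")],
                bonds[, c("a1", "a2", "order", "aromatic", "in_ring")],
                perception)
}

# Serialize a mol_graph to a V2000 molblock (aromatic bonds written as order
# 4) -- used for best-effort SMILES export of augmented molecules.
graph_to_molblock <- function(graph) {
  n <- graph$node_count; m <- nrow(graph$bonds)
  lines <- c("", " planet", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    sym <- .element_symbols[graph$atoms$atomic_num[i]]
    if (is.na(sym)) sym <- "X"
    lines <- c(lines, sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", sym))
  }
  for (j in seq_len(m)) {
    ord <- if (graph$bonds$aromatic[j]) 4L else graph$bonds$order[j]
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", graph$bonds$a1[j], graph$bonds$a2[j], ord))
  }
  chg <- which(graph$atoms$formal_charge != 0)
  for (i in chg) {
    lines <- c(lines, sprintf("M  CHG  1 %3d %3d", i, graph$atoms$formal_charge[i]))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

#' Best-effort SMILES for a graph
#'
#' Serializes the graph to a molblock and asks OpenBabel for a canonical
#' SMILES. Useful for exporting augmented (bond-deleted) molecules; returns
#' `NA` when the structure cannot be converted.
#'
#' @param graph A `mol_graph`.
#' @return A SMILES string or `NA`.
#' @export
graph_to_smiles <- function(graph) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", graph_to_molblock(graph))),
    error = function(e) ""
  )
  out <- sub("\\s.*$", "", trimws(out))
  if (!nzchar(out)) NA_character_ else out
}
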