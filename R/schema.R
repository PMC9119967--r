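#' Atom feature schema
#'
#' The nine-descriptor categorical schema used to featurize heavy atoms.
#' Each descriptor has a closed, ordered vocabulary; an atom is encoded as the
#' concatenation of nine one-hot blocks in this order:
#' atomic number (1..119), chirality (4 classes), heavy-atom degree (0..10),
#' formal charge (-5..5), total number of hydrogens (0..8), number of radical
#' electrons (0..4), hybridization (Sp, Sp2, Sp3, Sp3d, Sp3d2), aromaticity
#' (0/1) and ring membership (0/1).
#'
#' @return A list of class `atom_schema` with elements `descriptors` (named
#'   list of character vocabularies) and `sizes` (integer vector of block
#'   sizes, totalling the one-hot length).
#' @export
#' @examples
#' s <- atom_feature_schema()
#' s$sizes
#' sum(s$sizes)  # atom one-hot length
atom_feature_schema <- function() {
  descriptors <- list(
    atomic_num    = as.character(1:119),
    chirality     = c("unspecified", "tetrahedral_cw", "tetrahedral_ccw", "other"),
    degree        = as.character(0:10),
    formal_charge = as.character(-5:5),
    num_hs        = as.character(0:8),
    num_radical_e = as.character(0:4),
    hybridization = c("sp", "sp2", "sp3", "sp3d", "sp3d2"),
    aromatic      = c("0", "1"),
    in_ring       = c("0", "1")
  )
  structure(
    list(descriptors = descriptors,
         sizes = vapply(descriptors, length, integer(1))),
    class = "atom_schema"
  )
}

#' Bond feature schema
#'
#' Three-descriptor categorical schema for bonds: bond type (single, double,
#' triple, aromatic), stereochemistry (none, Z, E, cis, trans, any) and
#' conjugation (0/1). A bond is encoded as the concatenation of the three
#' one-hot blocks.
#'
#' @return A list of class `bond_schema`, see [atom_feature_schema()].
#' @export
bond_feature_schema <- function() {
  descriptors <- list(
    bond_type  = c("single", "double", "triple", "aromatic"),
    stereo     = c("none", "z", "e", "cis", "trans", "any"),
    conjugated = c("0", "1")
  )
  structure(
    list(descriptors = descriptors,
         sizes = vapply(descriptors, length, integer(1))),
    class = "bond_schema"
  )
}

# 0-based offset of each one-hot block inside the concatenated vector
schema_offsets <- function(schema) {
  c(0L, cumsum(schema$sizes))[seq_along(schema$sizes)]
}

# Encode one categorical value vector against a schema. `values` is a named
# list/vector, one entry per descriptor, in any order; values are matched
# against the descriptor vocabularies as characters.
encode_against_schema <- function(values, schema, what) {
  n <- length(schema$sizes)
  if (!all(names(schema$descriptors) %in% names(values))) {
    missing <- setdiff(names(schema$descriptors), names(values))
    stop(sprintf("missing %s descriptor(s): %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- numeric(sum(schema$sizes))
  off <- schema_offsets(schema)
  for (i in seq_len(n)) {
    nm <- names(schema$descriptors)[i]
    vocab <- schema$descriptors[[nm]]
    pos <- match(as.character(values[[nm]]), vocab)
    if (is.na(pos)) {
      stop(sprintf("%s descriptor '%s': value '%s' outside vocabulary",
                   what, nm, as.character(values[[nm]])), call. = FALSE)
    }
    out[off[i] + pos] <- 1
  }
  out
}

#' One-hot encode a single atom
#'
#' @param properties Named list with one entry per atom descriptor (see
#'   [atom_feature_schema()] for names and vocabularies). Values outside a
#'   descriptor's vocabulary raise an error naming the descriptor.
#' @return Numeric 0/1 vector of length `sum(atom_feature_schema()$sizes)`
#'   with exactly nine ones.
#' @export
#' @examples
#' v <- encode_atom(list(atomic_num = 6, chirality = "unspecified", degree = 4,
#'                       formal_charge = 0, num_hs = 0, num_radical_e = 0,
#'                       hybridization = "sp3", aromatic = 0, in_ring = 0))
#' sum(v)  # 9
encode_atom <- function(properties) {
  encode_against_schema(properties, atom_feature_schema(), "atom")
}

#' One-hot encode a single bond
#'
#' @param properties Named list with entries `bond_type`, `stereo`,
#'   `conjugated` (see [bond_feature_schema()]).
#' @return Numeric 0/1 vector with exactly three ones.
#' @export
encode_bond <- function(properties) {
  encode_against_schema(properties, bond_feature_schema(), "bond")
}
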