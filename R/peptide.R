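# Protein sequences as molecular graphs.
#
# A FASTA amino-acid sequence is turned into the SMILES of the linear peptide
# (free N- and C-termini, no disulfides, no modifications, no stereo
# annotations) and featurized exactly like a ligand. Side-chain fragments are
# written as branches on the alpha carbon.

# side chains as SMILES branches on C-alpha ("" = glycine)
.aa_side_chains <- c(
  A = "(C)",
  R = "(CCCNC(=N)N)",
  N = "(CC(N)=O)",
  D = "(CC(O)=O)",
  C = "(CS)",
  E = "(CCC(O)=O)",
  Q = "(CCC(N)=O)",
  G = "",
  H = "(Cc1c[nH]cn1)",
  I = "(C(C)CC)",
  L = "(CC(C)C)",
  K = "(CCCCN)",
  M = "(CCSC)",
  F = "(Cc1ccccc1)",
  P = NA,  # backbone N and C-alpha are part of the pyrrolidine ring
  S = "(CO)",
  T = "(C(C)O)",
  W = "(Cc1c[nH]c2ccccc12)",
  Y = "(Cc1ccc(O)cc1)",
  V = "(C(C)C)"
)

# Strip FASTA headers/whitespace and validate the 20-letter alphabet.
clean_sequence <- function(sequence) {
  lines <- strsplit(sequence, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(trimws(lines), ">")]
  seq <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
  if (!nzchar(seq)) stop("empty amino-acid sequence", call. = FALSE)
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters, names(.aa_side_chains))
  if (length(bad) > 0)
    stop(sprintf("non-standard amino-acid letter(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  letters
}

#' Peptide SMILES for an amino-acid sequence
#'
#' @param sequence One-letter amino-acid sequence (FASTA headers and
#'   whitespace are stripped; only the 20 standard residues are accepted).
#' @return The SMILES of the linear peptide with free termini.
#' @export
#' @examples
#' peptide_smiles("G")   # "NCC(=O)O"
peptide_smiles <- function(sequence) {
  letters <- clean_sequence(sequence)
  frag <- vapply(letters, function(aa) {
    if (aa == "P") "N9CCCC9C(=O)"
    else paste0("N", "C", .aa_side_chains[[aa]], "C(=O)")
  }, character(1))
  paste0(paste(frag, collapse = ""), "O")
}

#' Convert a FASTA amino-acid sequence to a molecular graph
#'
#' Builds the linear peptide molecule of the sequence and featurizes it
#' identically to [smiles_to_graph()].
#'
#' @param sequence Amino-acid sequence text (possibly with FASTA header
#'   lines, which are ignored).
#' @return A `mol_graph` whose `source` records the cleaned sequence.
#' @export
fasta_to_graph <- function(sequence) {
  smi <- peptide_smiles(sequence)
  g <- smiles_to_graph(smi)
  g$source <- paste0("peptide:", paste(clean_sequence(sequence), collapse = ""))
  g
}

#' Read sequences from a FASTA file
#'
#' Reads protein target sequences (via seqinr) into a named character
#' vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], character(1)))
  names(out) <- names(seqs)
  out
}
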