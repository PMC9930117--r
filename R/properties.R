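#' Physicochemical properties
#'
#' Adds the descriptor columns the drug-likeness filters and the decoy
#' matcher work with: molecular weight (`mw`, g/mol), computed logP
#' (`clogp`, Wildman--Crippen atom-contribution method as implemented in
#' Open Babel), hydrogen-bond donors (`hbd`, O-H/N-H groups), acceptors
#' (`hba`, Lipinski N+O count), rotatable bonds (`rotb`, non-ring single
#' bonds between non-terminal heavy atoms, triple-bond neighbours excluded)
#' and topological polar surface area (`tpsa`, \eqn{\mbox{\AA}^2}).
#' Descriptors are deterministic functions of the canonical structure, so
#' the operation is idempotent.
#'
#' @param mols molecule tibble from [parse_molecules()] or [read_library()].
#' @return the tibble with property columns filled.
#' @examples
#' compute_properties(parse_molecules("CCO", "ethanol"))
#' @export
compute_properties <- function(mols) {
  stopifnot(nrow(mols) > 0, all(c("id", "smiles") %in% names(mols)))
  refs <- obmols_from_smiles(mols$smiles, mols$id)
  props <- suppressWarnings(ChemmineOB::prop_OB(refs))
  rotb <- suppressWarnings(ChemmineOB::smartsSearch_OB(
    refs, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))
  mols$mw <- props$MW
  mols$clogp <- props$logP
  mols$hbd <- as.integer(props$HBD)
  mols$hba <- as.integer(props$HBA2)
  mols$rotb <- as.integer(rotb)
  mols$tpsa <- props$TPSA
  mols
}

has_properties <- function(mols) {
  all(c("mw", "clogp", "hbd", "hba", "rotb", "tpsa") %in% names(mols)) &&
    !anyNA(mols$mw)
}
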