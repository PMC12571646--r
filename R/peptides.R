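# Chaperonin C-terminal tail peptide constructs.

#' Chaperonin C-terminal tail peptides
#'
#' The peptide constructs covering the disordered C-terminal tails of
#' GroEL, mitochondrial Hsp60 and the chloroplastic Cpn60 alpha/beta
#' subunits. `full_sequence` is the synthesized, N-acetylated construct
#' including C-terminal solubility tags (extra Lys or His residues);
#' `sequence` is the tail segment itself, the part analyzed, since the
#' tags are absent in the protein. "CtC" constructs span the complete
#' tail, "CtS" only the final Gly/Met-rich stretch.
#'
#' @return Tibble with columns `peptide`, `source`, `construct`,
#'   `sequence`, `full_sequence`, `tag`.
#' @examples
#' chaperonin_tail_peptides()
#' @export
chaperonin_tail_peptides <- function() {
  tibble(
    peptide = c(
      "GroELCtC", "mHsp60CtC", "GroELCtS", "mHsp60CtS",
      "AtCpn60aCt", "WheatCpn60aCt", "AtCpn60bCt", "WheatCpn60bCt"
    ),
    source = c(
      "E. coli GroEL", "human mitochondrial Hsp60",
      "E. coli GroEL", "human mitochondrial Hsp60",
      "A. thaliana Cpn60 alpha", "wheat Cpn60 alpha",
      "A. thaliana Cpn60 beta", "wheat Cpn60 beta"
    ),
    construct = c("CtC", "CtC", "CtS", "CtS", "Ct", "Ct", "Ct", "Ct"),
    sequence = c(
      "PKNDAADLGAAGGMGGMGGMGGMM",
      "PKEEKDPGMGAMGGMGGGMGGGMF",
      "AGGMGGMGGMGGMM",
      "AMGGMGGGMGGGMF",
      "PKPKAPAAAPEGLMV",
      "PKPKPKVAEPAEGQLSV",
      "EPEPVPVGNPMDNSGYGY",
      "EPEAAPLANPMDNSGFGY"
    ),
    full_sequence = c(
      "PKNDAADLGAAGGMGGMGGMGGMMKKK",
      "PKEEKDPGMGAMGGMGGGMGGGMFKKK",
      "AGGMGGMGGMGGMMH",
      "AMGGMGGGMGGGMFGH",
      "PKPKAPAAAPEGLMV",
      "PKPKPKVAEPAEGQLSV",
      "EPEPVPVGNPMDNSGYGY",
      "EPEAAPLANPMDNSGFGY"
    ),
    tag = c("KKK", "KKK", "H", "GH", "", "", "", "")
  )
}
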