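#' Match candidate neoantigens against an MS-eluted ligandome
#'
#' Queries a mass-spectrometry-identified MHC ligand list for the mutant
#' peptides of candidate neoantigens under exact string equality.
#' Because mass spectrometry cannot distinguish leucine from isoleucine,
#' an optional I/L-equivalent mode treats the two residues as identical;
#' it is off by default so that matches mean database-search identity.
#' Wild-type-only hits (the wild-type counterpart eluted, but not the
#' mutant) are reported separately.
#'
#' @param ligandome character vector of eluted peptides.
#' @param candidates candidate tibble (see [enumerate_mutant_windows()]).
#' @param il_equivalent treat I and L as equivalent (default FALSE).
#' @return a list with `overlap` (candidate rows whose mutant peptide is
#'   in the ligandome), `wt_only` (candidate rows where only the wild-type
#'   is), `n_ligandome` and `il_equivalent`.
#' @export
#' @examples
#' cands <- tibble::tibble(
#'   mutant_peptide = "NLAPYIKSV", wt_peptide = "NLAPYIESV",
#'   mut_offset = 7L, length = 9L, source_variant = "v1",
#'   protein_id = "P", allele = "HLA-A*02:01"
#' )
#' match_candidates(c("NLAPYLKSV"), cands)$overlap            # empty
#' nrow(match_candidates("NLAPYLKSV", cands,
#'                       il_equivalent = TRUE)$overlap)       # 1
match_candidates <- function(ligandome, candidates, il_equivalent = FALSE) {
  canon <- function(x) {
    x <- toupper(x)
    if (il_equivalent) gsub("I", "L", x, fixed = TRUE) else x
  }
  lig <- unique(canon(ligandome))
  mut_hit <- canon(candidates$mutant_peptide) %in% lig
  wt_hit <- canon(candidates$wt_peptide) %in% lig
  list(
    overlap = candidates[mut_hit, , drop = FALSE],
    wt_only = candidates[wt_hit & !mut_hit, , drop = FALSE],
    n_ligandome = length(lig),
    il_equivalent = il_equivalent
  )
}
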