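#' Design a 31-mer long peptide carrying two minimal epitopes
#'
#' Long peptides (LP) for vaccination are 31-residue windows of the
#' mutated protein that contain one H2-Db and one H2-Kb minimal epitope
#' derived from the same somatic variant, together with the mutant
#' residue. The window keeps the natural flanking sequence (no linkers or
#' concatenation) and is centered on the mutation as nearly as the protein
#' termini and epitope coverage allow, ties broken toward the N-terminus.
#' Epitope pairs whose union cannot fit a native 31-residue window are
#' reported as an error, never forced.
#'
#' @param db,kb one-row candidate tibbles (see
#'   [enumerate_mutant_windows()]) for the H2-Db and H2-Kb epitope; both
#'   must derive from the same variant.
#' @param ctx the `protein_context` of that variant (see
#'   [apply_mutation()]).
#' @param cfg a [neovax_config()] supplying `lp_len`.
#' @return a `long_peptide` list: `sequence` (length `lp_len`),
#'   `db_epitope`, `kb_epitope`, `db_offset`, `kb_offset` (1-based starts
#'   within the LP), `mut_offset`, `source_variant`, `start` (1-based
#'   start in the protein).
#' @export
design_31mer <- function(db, kb, ctx, cfg = neovax_config()) {
  stopifnot(inherits(ctx, "protein_context"))
  validate_config(cfg)
  lp_len <- cfg$lp_len
  if (!identical(db$source_variant, kb$source_variant)) {
    stop("consistency error: epitopes derive from different variants ('",
         db$source_variant, "' vs '", kb$source_variant, "')",
         call. = FALSE)
  }
  prot <- ctx$sequence
  plen <- nchar(prot)
  epitope_start <- function(cand, label) {
    start <- ctx$aa_pos - cand$mut_offset + 1
    end <- start + cand$length - 1
    if (start < 1 || end > plen ||
        substr(prot, start, end) != cand$mutant_peptide) {
      stop("consistency error: ", label, " epitope '",
           cand$mutant_peptide, "' is not found in the mutated protein ",
           "at the position implied by its mut_offset", call. = FALSE)
    }
    c(start = start, end = end)
  }
  db_span <- epitope_start(db, "H2-Db")
  kb_span <- epitope_start(kb, "H2-Kb")
  union_start <- min(db_span["start"], kb_span["start"])
  union_end <- max(db_span["end"], kb_span["end"])
  span <- union_end - union_start + 1
  if (span > lp_len) {
    stop("not coverable: the two epitopes span ", span,
         " residues, more than the ", lp_len, "-mer long peptide",
         call. = FALSE)
  }
  if (plen < lp_len) {
    stop("not coverable: protein of length ", plen,
         " is shorter than the ", lp_len, "-mer long peptide",
         call. = FALSE)
  }
  # admissible starts: cover the epitope union and stay inside the protein
  lo <- max(1, union_end - lp_len + 1)
  hi <- min(union_start, plen - lp_len + 1)
  # center the mutation: ideal start puts it at offset ceil((lp_len+1)/2)
  ideal <- ctx$aa_pos - floor((lp_len + 1) / 2) + 1
  start <- min(max(ideal, lo), hi)
  seqs <- substr(prot, start, start + lp_len - 1)
  structure(
    list(
      sequence = seqs,
      db_epitope = db$mutant_peptide,
      kb_epitope = kb$mutant_peptide,
      db_offset = unname(db_span["start"]) - start + 1,
      kb_offset = unname(kb_span["start"]) - start + 1,
      mut_offset = ctx$aa_pos - start + 1,
      source_variant = db$source_variant,
      start = start
    ),
    class = "long_peptide"
  )
}
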