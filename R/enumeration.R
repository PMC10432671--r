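#' Apply a missense mutation to a protein sequence
#'
#' Substitutes `alt_aa` for `ref_aa` at 1-based residue `aa_pos`, after
#' verifying that the reference residue matches the sequence.
#'
#' @param sequence protein sequence (amino-acid string).
#' @param aa_pos 1-based residue index of the mutation.
#' @param ref_aa,alt_aa reference and alternate residues (single letters).
#' @param protein_id,variant_id identifiers carried through to candidates.
#' @return a `protein_context` list: `protein_id`, `variant_id`, `sequence`
#'   (mutated), `wt_sequence`, `aa_pos`, `ref_aa`, `alt_aa`.
#' @export
#' @examples
#' ctx <- apply_mutation("ACDEF", 3, "D", "Y")
#' ctx$sequence  # "ACYEF"
apply_mutation <- function(sequence, aa_pos, ref_aa, alt_aa,
                           protein_id = NA_character_,
                           variant_id = NA_character_) {
  len <- nchar(sequence)
  if (aa_pos < 1 || aa_pos > len) {
    stop("aa_pos ", aa_pos, " outside protein of length ", len,
         call. = FALSE)
  }
  observed <- substr(sequence, aa_pos, aa_pos)
  if (observed != ref_aa) {
    stop("reference mismatch at position ", aa_pos, ": expected '", ref_aa,
         "', found '", observed, "'", call. = FALSE)
  }
  if (ref_aa == alt_aa) {
    stop("not a missense change: ref_aa equals alt_aa", call. = FALSE)
  }
  mutated <- sequence
  substr(mutated, aa_pos, aa_pos) <- alt_aa
  structure(
    list(protein_id = protein_id, variant_id = variant_id,
         sequence = mutated, wt_sequence = sequence, aa_pos = aa_pos,
         ref_aa = ref_aa, alt_aa = alt_aa),
    class = "protein_context"
  )
}

#' Mutation-centered sequence context
#'
#' Extracts the window of `flank_len` residues on each side of the mutated
#' residue (a 21-mer for the default flank of 10). Windows are truncated,
#' never padded, at the protein termini, so a mutation near a terminus
#' yields a shorter context with the mutant residue at the appropriate
#' offset.
#'
#' @param ctx a `protein_context` from [apply_mutation()].
#' @param flank_len residues of flank on each side (default 10).
#' @return list with `peptide` (mutant context), `wt_peptide`,
#'   `mut_offset` (1-based position of the mutant residue in the window)
#'   and `start` (1-based start in the protein).
#' @export
build_context_21mer <- function(ctx, flank_len = 10) {
  stopifnot(inherits(ctx, "protein_context"))
  len <- nchar(ctx$sequence)
  start <- max(1, ctx$aa_pos - flank_len)
  end <- min(len, ctx$aa_pos + flank_len)
  list(
    peptide = substr(ctx$sequence, start, end),
    wt_peptide = substr(ctx$wt_sequence, start, end),
    mut_offset = ctx$aa_pos - start + 1,
    start = start
  )
}

# Closed-form number of length-L windows of an n-residue protein that
# contain position p.
n_windows_containing <- function(p, L, n) {
  max(0, min(p, n - L + 1) - max(1, p - L + 1) + 1)
}

#' Enumerate mutant epitope candidates
#'
#' Slides windows of each requested length over the mutated protein and
#' keeps every window that contains the mutated residue, pairing it with
#' the corresponding wild-type window. For an interior mutation each
#' length L contributes exactly L candidates (the mutant residue can occupy
#' any position of the peptide). Duplicate mutant peptides of the same
#' length are collapsed; windows containing X are dropped.
#'
#' @param ctx a `protein_context` from [apply_mutation()].
#' @param lengths integer vector of peptide lengths (subset of 8:11;
#'   the human pipeline uses 9, the murine pipeline 8:10).
#' @return a tibble with columns `mutant_peptide, wt_peptide, mut_offset,
#'   length, source_variant, protein_id, allele` (allele unset, NA).
#' @export
#' @examples
#' ctx <- apply_mutation(strrep("A", 30), 15, "A", "W", variant_id = "v1")
#' nrow(enumerate_mutant_windows(ctx, 9))   # 9
enumerate_mutant_windows <- function(ctx, lengths = c(8L, 9L, 10L)) {
  stopifnot(inherits(ctx, "protein_context"))
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 8 | lengths > 11)) {
    stop("peptide lengths must lie in 8..11", call. = FALSE)
  }
  len <- nchar(ctx$sequence)
  out <- list()
  for (L in lengths) {
    starts <- seq(max(1, ctx$aa_pos - L + 1), min(ctx$aa_pos, len - L + 1))
    starts <- starts[starts >= 1 & starts + L - 1 <= len]
    if (!length(starts)) next
    mut <- substring(ctx$sequence, starts, starts + L - 1)
    wt <- substring(ctx$wt_sequence, starts, starts + L - 1)
    keep <- !grepl("X", mut, fixed = TRUE) & !grepl("X", wt, fixed = TRUE)
    if (!any(keep)) next
    out[[as.character(L)]] <- tibble(
      mutant_peptide = mut[keep],
      wt_peptide = wt[keep],
      mut_offset = ctx$aa_pos - starts[keep] + 1,
      length = L,
      source_variant = ctx$variant_id,
      protein_id = ctx$protein_id,
      allele = NA_character_
    )
  }
  if (!length(out)) {
    return(tibble(mutant_peptide = character(0), wt_peptide = character(0),
                  mut_offset = integer(0), length = integer(0),
                  source_variant = character(0), protein_id = character(0),
                  allele = character(0)))
  }
  res <- bind_rows(out)
  res[!duplicated(res[c("mutant_peptide", "length")]), , drop = FALSE]
}

#' Enumerate candidates for a set of filtered variants
#'
#' Convenience wrapper: applies each variant's mutation to its protein and
#' enumerates candidate windows, dropping (with a message) variants whose
#' protein is absent from `proteins`.
#'
#' @param variants retained variant tibble.
#' @param proteins named character vector (id -> sequence), e.g. from
#'   [read_fasta()].
#' @param lengths peptide lengths to enumerate.
#' @return a tibble of candidates (see [enumerate_mutant_windows()]).
#' @export
enumerate_candidates <- function(variants, proteins, lengths = 9L) {
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    seqc <- proteins[[v$protein_id]]
    if (is.null(seqc)) {
      message("skipping variant '", v$id, "': protein '", v$protein_id,
              "' not in FASTA")
      next
    }
    ctx <- apply_mutation(seqc, v$aa_pos, v$ref_aa, v$alt_aa,
                          protein_id = v$protein_id, variant_id = v$id)
    out[[i]] <- enumerate_mutant_windows(ctx, lengths)
  }
  bind_rows(out)
}
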