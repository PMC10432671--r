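# Independent straight-line oracles used to cross-check the pipeline's
# decision logic, plus small fixture constructors.

# One well-formed somatic variant row with overridable fields.
make_variant <- function(id = "v1", ...) {
  v <- tibble::tibble(
    id = id, gene = "GENE1", protein_id = "prot1", aa_pos = 5,
    ref_aa = "A", alt_aa = "V", tumor_depth = 50, normal_depth = 40,
    tumor_alt_reads = 10, normal_alt_reads = 0, alt_fwd = 5, alt_rev = 5,
    pop_maf = 0
  )
  over <- list(...)
  v[names(over)] <- over
  v
}

# Brute-force re-evaluation of the six-rule somatic filter conjunction,
# written independently of apply_somatic_filters.
oracle_filter <- function(v, cfg) {
  ok <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    ok[i] <- (r$tumor_depth > cfg$coverage_min) &&
      (r$normal_depth > cfg$coverage_min) &&
      (r$normal_alt_reads / r$normal_depth < cfg$normal_vaf_max) &&
      (r$tumor_alt_reads / r$tumor_depth > cfg$tumor_vaf_min) &&
      (r$alt_fwd >= 1) && (r$alt_rev >= 1) &&
      (r$pop_maf <= cfg$pop_maf_max)
  }
  ok
}

# 64-variant grid toggling each filter rule near its boundary (one toggle
# per rule; expected outcomes come from oracle_filter, not from intent).
boundary_grid_variants <- function() {
  grid <- expand.grid(
    td = c(11, 10), nd = c(11, 10), na = c(0, 1),
    ta = c(3, 1), onesided = c(FALSE, TRUE), maf = c(0.01, 0.02)
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    fwd <- if (g$onesided) g$ta else max(1, g$ta - 1)
    make_variant(
      id = sprintf("g%02d", i),
      tumor_depth = g$td, normal_depth = g$nd,
      normal_alt_reads = g$na, tumor_alt_reads = g$ta,
      alt_fwd = fwd, alt_rev = g$ta - fwd, pop_maf = g$maf
    )
  })
  dplyr::bind_rows(rows)
}

# Number of length-L windows of an n-residue sequence containing
# position p, counted by exhaustive scan.
oracle_window_count <- function(p, L, n) {
  if (n < L) return(0L)
  sum(vapply(seq_len(n - L + 1),
             function(s) s <= p && p <= s + L - 1, logical(1)))
}

# Straight-line transcription of the human selection rule text.
oracle_select_human <- function(mut_nm, wt_nm, mut_offset, length,
                                thr, wt_min, fold) {
  anchor <- mut_offset %in% c(1, 2, length)
  if (!(mut_nm < thr)) {
    return(list(selected = FALSE, rule_path = "rejected_affinity"))
  }
  if (wt_nm > wt_min) {
    return(list(selected = TRUE, rule_path = "anchor_differential"))
  }
  similar <- (wt_nm < thr) &&
    (max(mut_nm, wt_nm) / min(mut_nm, wt_nm) <= fold)
  if (similar && !anchor) {
    list(selected = TRUE, rule_path = "nonanchor_similar")
  } else if (similar) {
    list(selected = FALSE, rule_path = "rejected_position")
  } else {
    list(selected = FALSE, rule_path = "rejected_wt")
  }
}

# A one-row candidate tibble.
make_candidate <- function(mutant, wt, mut_offset,
                           allele = "HLA-A*02:01", variant = "v1") {
  tibble::tibble(
    mutant_peptide = mutant, wt_peptide = wt,
    mut_offset = mut_offset, length = nchar(mutant),
    source_variant = variant, protein_id = "prot1", allele = allele
  )
}
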