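#' Variant allele fraction
#'
#' Fraction of reads supporting the variant at a site: variant-supporting
#' reads divided by total depth, computed from read counts so the filter is
#' self-contained rather than trusting an upstream caller's field.
#'
#' @param variants variant tibble (see [read_variant_table()]).
#' @return numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' v <- tibble::tibble(
#'   id = "v1", gene = "G", protein_id = "P", aa_pos = 5, ref_aa = "A",
#'   alt_aa = "V", tumor_depth = 50, normal_depth = 40,
#'   tumor_alt_reads = 10, normal_alt_reads = 0, alt_fwd = 5, alt_rev = 5,
#'   pop_maf = 0
#' )
#' tumor_vaf(v)   # 0.2
tumor_vaf <- function(variants) {
  if (any(variants$tumor_depth <= 0)) {
    stop("undefined VAF: tumor_depth is zero for variant '",
         variants$id[which(variants$tumor_depth <= 0)[1]], "'",
         call. = FALSE)
  }
  variants$tumor_alt_reads / variants$tumor_depth
}

#' @rdname tumor_vaf
#' @export
normal_vaf <- function(variants) {
  if (any(variants$normal_depth <= 0)) {
    stop("undefined VAF: normal_depth is zero for variant '",
         variants$id[which(variants$normal_depth <= 0)[1]], "'",
         call. = FALSE)
  }
  variants$normal_alt_reads / variants$normal_depth
}

# Rule names in evaluation order; the audit reports the first failure.
FILTER_RULES <- c("tumor_coverage", "normal_coverage", "normal_vaf",
                  "tumor_vaf", "strand_support", "pop_maf")

#' Somatic mutation filter
#'
#' Retains a somatic missense call when all six post-call rules hold:
#' tumor coverage strictly above `coverage_min` reads, normal coverage
#' strictly above `coverage_min` reads, normal-tissue VAF strictly below
#' `normal_vaf_max`, tumor VAF strictly above `tumor_vaf_min`, at least one
#' variant-supporting read on each strand, and population MAF at most
#' `pop_maf_max` (variants with MAF above 1% in population databases are
#' removed; an absent MAF counts as 0).
#'
#' @param variants variant tibble.
#' @param cfg a [neovax_config()].
#' @return a list with `retained` (the passing variants, input order
#'   preserved) and `audit` (a tibble `id, retained, failed_rule` naming
#'   the first failed rule per rejected variant, NA when retained).
#' @export
apply_somatic_filters <- function(variants, cfg = neovax_config()) {
  validate_config(cfg)
  if (nrow(variants) == 0) {
    return(list(
      retained = variants,
      audit = tibble(id = character(0), retained = logical(0),
                     failed_rule = character(0))
    ))
  }
  validate_variants(variants)
  rules <- cbind(
    tumor_coverage = variants$tumor_depth > cfg$coverage_min,
    normal_coverage = variants$normal_depth > cfg$coverage_min,
    normal_vaf = normal_vaf(variants) < cfg$normal_vaf_max,
    tumor_vaf = tumor_vaf(variants) > cfg$tumor_vaf_min,
    strand_support = variants$alt_fwd >= 1 & variants$alt_rev >= 1,
    pop_maf = variants$pop_maf <= cfg$pop_maf_max
  )
  pass <- rowSums(rules) == ncol(rules)
  first_fail <- apply(rules, 1, function(r) {
    if (all(r)) NA_character_ else FILTER_RULES[which(!r)[1]]
  })
  list(
    retained = variants[pass, , drop = FALSE],
    audit = tibble(id = variants$id, retained = pass,
                   failed_rule = first_fail)
  )
}
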