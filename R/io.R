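#' @title Tabular and sequence input/output
#' @description Readers and writers for the TSV and FASTA dialects the
#'   pipeline consumes. All reader/writer pairs are lossless round trips on
#'   valid data; parsing uses the decimal point regardless of locale.
#' @name neovax-io
NULL

VARIANT_COLUMNS <- c(
  "id", "gene", "protein_id", "aa_pos", "ref_aa", "alt_aa",
  "tumor_depth", "normal_depth", "tumor_alt_reads", "normal_alt_reads",
  "alt_fwd", "alt_rev", "pop_maf"
)
VARIANT_NUMERIC <- c(
  "aa_pos", "tumor_depth", "normal_depth", "tumor_alt_reads",
  "normal_alt_reads", "alt_fwd", "alt_rev", "pop_maf"
)

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(NULL)
  }
  if (!grepl("\t", first) && grepl("[,;]", first)) {
    stop("format error: '", path, "' does not look like a TSV ",
         "(delimiter in header line is not a tab)", call. = FALSE)
  }
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             check.names = FALSE, na.strings = "NA", quote = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("configuration error: ", what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

parse_numeric_cols <- function(df, cols, what) {
  for (col in cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("malformed numeric value in ", what, ", column '", col,
           "', row ", bad[1], ": '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}

#' Read and write a somatic variant table
#'
#' The variant table is a post-annotation, protein-level TSV with one row
#' per somatic missense call: identifiers, the protein change (1-based
#' `aa_pos`, `ref_aa`, `alt_aa`), tumor/normal depths and variant read
#' counts, strand-split variant reads and population minor allele
#' frequency. Only single-residue missense substitutions are accepted;
#' indel/frameshift notations are rejected at read time. An absent
#' (empty/NA) `pop_maf` is treated as 0, i.e. a novel variant.
#'
#' @param path TSV file path.
#' @return a tibble with columns `id, gene, protein_id, aa_pos, ref_aa,
#'   alt_aa, tumor_depth, normal_depth, tumor_alt_reads, normal_alt_reads,
#'   alt_fwd, alt_rev, pop_maf`.
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_raw(path)
  if (is.null(df)) {
    stop("format error: empty variant table file: ", path, call. = FALSE)
  }
  require_columns(df, VARIANT_COLUMNS, "variant table")
  df <- df[VARIANT_COLUMNS]
  df$pop_maf[is.na(df$pop_maf) | df$pop_maf == ""] <- "0"
  df <- parse_numeric_cols(df, VARIANT_NUMERIC, "variant table")
  validate_variants(as_tibble(df))
}

#' @rdname read_variant_table
#' @param variants a variant tibble as returned by [read_variant_table()].
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_variants <- function(variants) {
  require_columns(variants, VARIANT_COLUMNS, "variant table")
  aa_ok <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWY]$", x)
  check <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad)) {
      stop("invalid variant (row ", bad[1], ", id '",
           variants$id[bad[1]], "'): ", msg, call. = FALSE)
    }
  }
  if (nrow(variants) == 0) return(as_tibble(variants))
  check(aa_ok(variants$ref_aa) & aa_ok(variants$alt_aa),
        "ref_aa/alt_aa must each be one standard amino acid (missense only)")
  check(variants$ref_aa != variants$alt_aa, "ref_aa equals alt_aa")
  check(variants$aa_pos >= 1 & variants$aa_pos == round(variants$aa_pos),
        "aa_pos must be a positive 1-based integer index")
  check(variants$tumor_alt_reads <= variants$tumor_depth,
        "tumor_alt_reads exceeds tumor_depth")
  check(variants$normal_alt_reads <= variants$normal_depth,
        "normal_alt_reads exceeds normal_depth")
  check(variants$alt_fwd + variants$alt_rev == variants$tumor_alt_reads,
        "alt_fwd + alt_rev must equal tumor_alt_reads")
  check(variants$pop_maf >= 0 & variants$pop_maf <= 1,
        "pop_maf must lie in [0, 1]")
  as_tibble(variants)
}

#' Read and write protein/peptide FASTA
#'
#' Sequences are upper-cased on read; the alphabet is the 20 standard amino
#' acids plus X. Duplicated record identifiers are an error. An empty file
#' yields an empty map with a warning.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    stop("non-amino-acid character in FASTA record '", ids[bad][1], "'",
         call. = FALSE)
  }
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids", call. = FALSE)
  }
  set <- Biostrings::BStringSet(toupper(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read and write a predicted-affinity table
#'
#' TSV with columns `peptide, allele, affinity_nm, rank_pct`, the shape an
#' external MHC-I binding predictor (e.g. NetMHC-style output, reformatted)
#' produces. Affinities must be positive; percentile ranks in \[0, 100\].
#'
#' @param path TSV file path.
#' @return a tibble of predictions.
#' @export
read_affinity_table <- function(path) {
  df <- read_tsv_raw(path)
  if (is.null(df)) {
    stop("format error: empty affinity table file: ", path, call. = FALSE)
  }
  require_columns(df, c("peptide", "allele", "affinity_nm", "rank_pct"),
                  "affinity table")
  df <- parse_numeric_cols(df, c("affinity_nm", "rank_pct"),
                           "affinity table")
  bad <- which(!(df$affinity_nm > 0))
  if (length(bad)) {
    stop("affinity table row ", bad[1], ": affinity_nm must be > 0 (got ",
         df$affinity_nm[bad[1]], ")", call. = FALSE)
  }
  bad <- which(df$rank_pct < 0 | df$rank_pct > 100)
  if (length(bad)) {
    stop("affinity table row ", bad[1], ": rank_pct must lie in [0, 100] ",
         "(got ", df$rank_pct[bad[1]], ")", call. = FALSE)
  }
  as_tibble(df[c("peptide", "allele", "affinity_nm", "rank_pct")])
}

#' @rdname read_affinity_table
#' @param predictions a tibble as returned by [read_affinity_table()].
#' @export
write_affinity_table <- function(predictions, path) {
  require_columns(predictions,
                  c("peptide", "allele", "affinity_nm", "rank_pct"),
                  "affinity table")
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write binding-assay dilution series
#'
#' Long-format TSV of concentration/signal pairs per peptide curve. Rows
#' with `concentration_um == 0` are the no-peptide control for
#' stabilization assays; `reference_no_competitor` carries the
#' FITC-reference signal for competition assays (NA otherwise).
#'
#' @param path TSV file path.
#' @return a tibble with columns `peptide_id, assay_type, concentration_um,
#'   signal, reference_no_competitor`.
#' @export
read_binding_curves <- function(path) {
  df <- read_tsv_raw(path)
  if (is.null(df)) {
    stop("format error: empty binding-curve file: ", path, call. = FALSE)
  }
  cols <- c("peptide_id", "assay_type", "concentration_um", "signal",
            "reference_no_competitor")
  require_columns(df, cols, "binding-curve table")
  df <- parse_numeric_cols(df, c("concentration_um", "signal",
                                 "reference_no_competitor"),
                           "binding-curve table")
  if (any(!df$assay_type %in% c("stabilization", "competition"))) {
    stop("binding-curve table: assay_type must be 'stabilization' or ",
         "'competition'", call. = FALSE)
  }
  if (any(df$signal < 0, na.rm = TRUE)) {
    stop("binding-curve table: negative signal", call. = FALSE)
  }
  as_tibble(df[cols])
}

#' @rdname read_binding_curves
#' @param curves a tibble as returned by [read_binding_curves()].
#' @export
write_binding_curves <- function(curves, path) {
  write.table(curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write T-cell assay readouts
#'
#' TSV with one row per (subject, peptide): percentage of IFN-gamma-positive
#' cells within the CD8+ population for the peptide-stimulated and the
#' unstimulated culture.
#'
#' @param path TSV file path.
#' @return a tibble with columns `subject_id, peptide_id, stim_pct,
#'   unstim_pct`.
#' @export
read_tcell_table <- function(path) {
  df <- read_tsv_raw(path)
  if (is.null(df)) {
    stop("format error: empty T-cell table file: ", path, call. = FALSE)
  }
  cols <- c("subject_id", "peptide_id", "stim_pct", "unstim_pct")
  require_columns(df, cols, "T-cell table")
  df <- parse_numeric_cols(df, c("stim_pct", "unstim_pct"), "T-cell table")
  bad <- which(df$stim_pct < 0 | df$stim_pct > 100 |
                 df$unstim_pct < 0 | df$unstim_pct > 100)
  if (length(bad)) {
    stop("T-cell table row ", bad[1], ": percentages must lie in [0, 100]",
         call. = FALSE)
  }
  as_tibble(df[cols])
}

#' @rdname read_tcell_table
#' @param records a tibble as returned by [read_tcell_table()].
#' @export
write_tcell_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write an MS-eluted peptide list
#'
#' A single-column TSV (column `peptide`) of peptides eluted from MHC
#' molecules and identified by mass spectrometry.
#'
#' @param path TSV file path.
#' @return a character vector of peptides.
#' @export
read_ms_peptides <- function(path) {
  df <- read_tsv_raw(path)
  if (is.null(df)) {
    return(character(0))
  }
  if (!"peptide" %in% names(df)) {
    stop("configuration error: MS peptide list is missing required ",
         "column(s): peptide", call. = FALSE)
  }
  toupper(df$peptide)
}

#' @rdname read_ms_peptides
#' @param peptides a character vector of peptides.
#' @export
write_ms_peptides <- function(peptides, path) {
  write.table(data.frame(peptide = peptides), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
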