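#' Candidate funnel summary table
#'
#' Tallies, per (sample, allele), the neoantigen candidate funnel: number
#' of predicted binders, number confirmed to bind in cell-based assays,
#' number immunogenic (at least one responding subject among the binders)
#' and number displayed by the tumor (found in the MS-eluted ligandome or
#' flagged as recognized on the tumor by specific CD8+ T cells). A totals
#' row sums the columns; binding and immunogenicity rates are percentages
#' truncated to one decimal (so 44/66 prints as 66.6).
#'
#' @param decisions tibble with columns `sample, allele, peptide_id,
#'   selected` — the prediction/selection outcome per candidate peptide.
#' @param binding tibble with columns `sample, peptide_id, binder` for the
#'   tested peptides.
#' @param responders tibble with columns `sample, peptide_id, responder`
#'   (one row per subject x peptide).
#' @param ms_overlap tibble with columns `sample, peptide_id` of candidates
#'   found in the immunopeptidome, or NULL.
#' @param tumor_recognized tibble with columns `sample, peptide_id` of
#'   candidates recognized on tumor cells by specific T cells, or NULL.
#' @param displayed_samples samples in which tumor display was assessed;
#'   rows for other samples report `n_displayed = NA` (not determined).
#'   Defaults to the samples appearing in `ms_overlap`/`tumor_recognized`.
#' @return a tibble with columns `sample, allele, n_predicted, n_bound,
#'   n_immunogenic, n_displayed, binding_rate_pct, immunogenic_rate_pct`,
#'   ending in a `Total` row.
#' @export
summarize_counts <- function(decisions, binding, responders,
                             ms_overlap = NULL, tumor_recognized = NULL,
                             displayed_samples = NULL) {
  for (col in c("sample", "allele", "peptide_id", "selected")) {
    if (!col %in% names(decisions)) {
      stop("decisions table is missing column '", col, "'", call. = FALSE)
    }
  }
  check_known <- function(tbl, what) {
    if (is.null(tbl) || nrow(tbl) == 0) return(invisible())
    key <- paste(tbl$sample, tbl$peptide_id)
    known <- paste(decisions$sample, decisions$peptide_id)
    bad <- setdiff(key, known)
    if (length(bad)) {
      stop("consistency error: ", what, " refers to peptide(s) absent ",
           "from the decisions table: ", bad[1], call. = FALSE)
    }
  }
  check_known(binding, "binding table")
  check_known(responders, "responder table")
  check_known(ms_overlap, "MS overlap")
  check_known(tumor_recognized, "tumor-recognition flags")

  if (is.null(displayed_samples)) {
    displayed_samples <- unique(c(
      if (!is.null(ms_overlap)) ms_overlap$sample,
      if (!is.null(tumor_recognized)) tumor_recognized$sample
    ))
  }
  bound_key <- if (!is.null(binding) && nrow(binding)) {
    paste(binding$sample, binding$peptide_id)[binding$binder]
  } else {
    character(0)
  }
  resp_key <- if (!is.null(responders) && nrow(responders)) {
    unique(paste(responders$sample,
                 responders$peptide_id)[responders$responder])
  } else {
    character(0)
  }
  disp_key <- unique(c(
    if (!is.null(ms_overlap) && nrow(ms_overlap)) {
      paste(ms_overlap$sample, ms_overlap$peptide_id)
    },
    if (!is.null(tumor_recognized) && nrow(tumor_recognized)) {
      paste(tumor_recognized$sample, tumor_recognized$peptide_id)
    }
  ))

  sel <- decisions[decisions$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    rows <- tibble(sample = character(0), allele = character(0),
                   n_predicted = integer(0), n_bound = integer(0),
                   n_immunogenic = integer(0), n_displayed = integer(0))
  } else {
    key <- paste(sel$sample, sel$peptide_id)
    sel$is_bound <- key %in% bound_key
    sel$is_immunogenic <- sel$is_bound & key %in% resp_key
    sel$is_displayed <- key %in% disp_key
    rows <- sel |>
      group_by(.data$sample, .data$allele) |>
      summarise(
        n_predicted = dplyr::n(),
        n_bound = sum(.data$is_bound),
        n_immunogenic = sum(.data$is_immunogenic),
        n_displayed = if (.data$sample[1] %in% displayed_samples) {
          sum(.data$is_displayed)
        } else {
          NA_integer_
        },
        .groups = "drop"
      ) |>
      arrange(.data$sample, .data$allele)
  }
  total <- tibble(
    sample = "Total", allele = "",
    n_predicted = sum(rows$n_predicted),
    n_bound = sum(rows$n_bound),
    n_immunogenic = sum(rows$n_immunogenic),
    n_displayed = if (all(is.na(rows$n_displayed))) {
      NA_integer_
    } else {
      sum(rows$n_displayed, na.rm = TRUE)
    }
  )
  out <- bind_rows(rows, total)
  out$binding_rate_pct <- rate_pct(out$n_bound, out$n_predicted)
  out$immunogenic_rate_pct <- rate_pct(out$n_immunogenic, out$n_bound)
  out
}

# Percentage truncated (not rounded) to one decimal, matching funnel
# tables that print 44/66 as 66.6%. Guard against floating error by
# nudging up half an ulp before flooring.
rate_pct <- function(num, den) {
  pct <- ifelse(den > 0, 100 * num / den, NA_real_)
  floor(pct * 10 + 1e-9) / 10
}

#' Expand a per-group count table into per-peptide records
#'
#' The inverse of [summarize_counts()]: given rows of (sample, allele,
#' n_predicted, n_bound, n_immunogenic, n_displayed), synthesizes
#' per-peptide decision, binding, responder and display records with
#' generated peptide ids such that `summarize_counts()` on the result
#' reproduces the counts. Used to feed published summary tables through
#' the same tallying code as pipeline output.
#'
#' @param counts tibble with columns `sample, allele, n_predicted,
#'   n_bound, n_immunogenic, n_displayed` (NA `n_displayed` = not
#'   determined).
#' @return a list with `decisions`, `binding`, `responders`, `ms_overlap`,
#'   `tumor_recognized`, `displayed_samples` ready for
#'   [summarize_counts()].
#' @export
expand_counts_to_records <- function(counts) {
  stopifnot(all(counts$n_bound <= counts$n_predicted),
            all(counts$n_immunogenic <= counts$n_bound))
  dec <- list(); bnd <- list(); rsp <- list(); disp <- list()
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    ids <- sprintf("%s_%s_pep%02d", r$sample, gsub("[^A-Za-z0-9]", "",
                                                   r$allele),
                   seq_len(r$n_predicted))
    dec[[i]] <- tibble(sample = r$sample, allele = r$allele,
                       peptide_id = ids, selected = TRUE)
    bnd[[i]] <- tibble(sample = r$sample, peptide_id = ids,
                       binder = seq_along(ids) <= r$n_bound)
    if (r$n_immunogenic > 0) {
      rsp[[i]] <- tibble(sample = r$sample,
                         peptide_id = ids[seq_len(r$n_immunogenic)],
                         responder = TRUE)
    }
    if (!is.na(r$n_displayed) && r$n_displayed > 0) {
      disp[[i]] <- tibble(sample = r$sample,
                          peptide_id = ids[seq_len(r$n_displayed)])
    }
  }
  list(
    decisions = bind_rows(dec),
    binding = bind_rows(bnd),
    responders = if (length(rsp)) bind_rows(rsp) else {
      tibble(sample = character(0), peptide_id = character(0),
             responder = logical(0))
    },
    ms_overlap = NULL,
    tumor_recognized = if (length(disp)) bind_rows(disp) else NULL,
    displayed_samples = counts$sample[!is.na(counts$n_displayed)]
  )
}

#' Published TNBC candidate funnel counts
#'
#' Loads the bundled transcription of the study's per-sample candidate
#' funnel (predicted binders, cell-assay-confirmed binders, immunogenic
#' peptides and tumor-displayed peptides for four patient samples and the
#' MDA-MB-231 cell line).
#'
#' @return a tibble with columns `sample, allele, n_predicted, n_bound,
#'   n_immunogenic, n_displayed`.
#' @export
tnbc_funnel_counts <- function() {
  path <- system.file("extdata", "tnbc_candidate_funnel.tsv",
                      package = "neovax", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", colClasses = "character")
  for (col in c("n_predicted", "n_bound", "n_immunogenic", "n_displayed")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  as_tibble(df)
}
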