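#' Classify the mutated position of a candidate peptide
#'
#' MHC class I anchor positions are peptide positions 1, 2 and the
#' C-terminus; every other (interior) position faces the T-cell receptor.
#'
#' @param mut_offset 1-based position of the mutant residue in the peptide.
#' @param length peptide length.
#' @return character vector, `"anchor"` or `"tcr_facing"` (vectorized).
#' @export
#' @examples
#' classify_mutation_position(2, 9)  # "anchor"
#' classify_mutation_position(5, 9)  # "tcr_facing"
classify_mutation_position <- function(mut_offset, length) {
  stopifnot(all(mut_offset >= 1), all(mut_offset <= length))
  ifelse(mut_offset == 1 | mut_offset == 2 | mut_offset == length,
         "anchor", "tcr_facing")
}

lookup_affinity <- function(peptide, allele, affinities, what) {
  hit <- affinities$peptide == peptide & affinities$allele == allele
  if (!any(hit)) {
    stop("no ", what, " prediction for peptide '", peptide,
         "' on allele '", allele, "'", call. = FALSE)
  }
  affinities$affinity_nm[which(hit)[1]]
}

#' Select human candidate neoantigens from mutant/wild-type affinity pairs
#'
#' Applies the allele-specific, anchor-aware selection rules. With
#' `thr` = the allele's mutant affinity threshold (nM) and `wt_min` the
#' allele's wild-type minimum:
#' \itemize{
#'   \item mutant affinity at or above `thr` -> rejected
#'     (`rejected_affinity`);
#'   \item mutant below `thr` and wild-type above `wt_min` -> selected by
#'     differential binding (`anchor_differential`; this is the canonical
#'     anchor-position case, and also fires when a TCR-facing mutation
#'     destroys wild-type binding);
#'   \item mutant and wild-type both below `thr` with an affinity ratio of
#'     at most `similar_affinity_fold`: selected when the mutation is
#'     TCR-facing (`nonanchor_similar`), rejected when it sits at an anchor
#'     (`rejected_position`, since the T-cell would see an unchanged
#'     surface);
#'   \item otherwise rejected on the wild-type side (`rejected_wt`).
#' }
#' Mutant comparisons are strict (`< thr`), the wild-type differential
#' comparison strict (`> wt_min`), matching the wording of the thresholds.
#'
#' @param candidates candidate tibble (see [enumerate_mutant_windows()])
#'   with the `allele` column set.
#' @param affinities prediction tibble (see [read_affinity_table()])
#'   covering both the mutant and wild-type peptide of every candidate on
#'   its allele.
#' @param cfg a [neovax_config()] supplying `allele_thresholds`,
#'   `wt_affinity_min` and `similar_affinity_fold`.
#' @return the candidates with added columns `mutant_nm, wt_nm, position,
#'   selected, rule_path`.
#' @export
select_human_candidates <- function(candidates, affinities,
                                    cfg = neovax_config()) {
  validate_config(cfg)
  n <- nrow(candidates)
  mutant_nm <- numeric(n)
  wt_nm <- numeric(n)
  selected <- logical(n)
  rule_path <- character(n)
  position <- classify_mutation_position(candidates$mut_offset,
                                         candidates$length)
  for (i in seq_len(n)) {
    allele <- candidates$allele[i]
    if (is.na(allele) || !allele %in% names(cfg$allele_thresholds)) {
      stop("configuration error: no affinity threshold configured for ",
           "allele '", allele, "'", call. = FALSE)
    }
    thr <- cfg$allele_thresholds[[allele]]
    wt_min <- if (allele %in% names(cfg$wt_affinity_min)) {
      cfg$wt_affinity_min[[allele]]
    } else {
      thr
    }
    mutant_nm[i] <- lookup_affinity(candidates$mutant_peptide[i], allele,
                                    affinities, "mutant")
    wt_nm[i] <- lookup_affinity(candidates$wt_peptide[i], allele,
                                affinities, "wild-type")
    if (!(mutant_nm[i] < thr)) {
      rule_path[i] <- "rejected_affinity"
    } else if (wt_nm[i] > wt_min) {
      selected[i] <- TRUE
      rule_path[i] <- "anchor_differential"
    } else {
      ratio <- max(mutant_nm[i], wt_nm[i]) / min(mutant_nm[i], wt_nm[i])
      similar <- wt_nm[i] < thr && ratio <= cfg$similar_affinity_fold
      if (similar && position[i] == "tcr_facing") {
        selected[i] <- TRUE
        rule_path[i] <- "nonanchor_similar"
      } else if (similar && position[i] == "anchor") {
        rule_path[i] <- "rejected_position"
      } else {
        rule_path[i] <- "rejected_wt"
      }
    }
  }
  out <- candidates
  out$mutant_nm <- mutant_nm
  out$wt_nm <- wt_nm
  out$position <- position
  out$selected <- selected
  out$rule_path <- rule_path
  out
}

#' Select murine candidate neoantigens by percentile rank
#'
#' A candidate is selected when its best (lowest) percentile rank over the
#' H2-Db/H2-Kb predictions is within `mouse_rank_max` (inclusive boundary:
#' a rank of exactly 1.0 falls "within the 1%"). The qualifying allele and
#' rank are recorded.
#'
#' @param candidates candidate tibble.
#' @param affinities prediction tibble with per-allele `rank_pct` rows for
#'   each mutant peptide.
#' @param cfg a [neovax_config()].
#' @param alleles alleles considered (default H2-Db and H2-Kb).
#' @return the candidates with added columns `best_rank_pct, best_allele,
#'   selected, rule_path`.
#' @export
select_mouse_candidates <- function(candidates, affinities,
                                    cfg = neovax_config(),
                                    alleles = c("H2-Db", "H2-Kb")) {
  validate_config(cfg)
  n <- nrow(candidates)
  best_rank <- rep(NA_real_, n)
  best_allele <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- affinities$peptide == candidates$mutant_peptide[i] &
      affinities$allele %in% alleles
    if (!any(hit)) {
      stop("no H2-Db/H2-Kb prediction for peptide '",
           candidates$mutant_peptide[i], "'", call. = FALSE)
    }
    ranks <- affinities$rank_pct[hit]
    j <- which.min(ranks)
    best_rank[i] <- ranks[j]
    best_allele[i] <- affinities$allele[hit][j]
  }
  out <- candidates
  out$best_rank_pct <- best_rank
  out$best_allele <- best_allele
  out$selected <- best_rank <= cfg$mouse_rank_max
  out$rule_path <- ifelse(out$selected, "mouse_rank", "rejected_affinity")
  out
}

#' Deterministic mock binding-affinity predictor
#'
#' A stand-in for an external MHC-I predictor so the pipeline runs offline:
#' a pure hash of (peptide, allele, seed) mapped to a log-uniform affinity
#' in \[1, 50000\] nM, with the percentile rank a fixed strictly monotone
#' transform of the affinity (rank = 100 * log(affinity)/log(50000)). The
#' scores carry no biology; they exist to exercise downstream selection
#' logic deterministically.
#'
#' @param peptides character vector of peptides of length 8-11.
#' @param allele allele name.
#' @param seed integer seed entering the hash.
#' @return a prediction tibble (`peptide, allele, affinity_nm, rank_pct`).
#' @export
mock_affinity_predictor <- function(peptides, allele, seed = 1L) {
  bad <- nchar(peptides) < 8 | nchar(peptides) > 11
  if (any(bad)) {
    stop("mock predictor accepts peptides of length 8-11; got '",
         peptides[bad][1], "' (length ", nchar(peptides[bad][1]), ")",
         call. = FALSE)
  }
  u <- vapply(peptides, function(p) {
    codes <- utf8ToInt(paste(p, allele, seed, sep = "|"))
    h <- 0
    for (cc in codes) h <- (h * 31 + cc) %% 2147483647
    # second pass decorrelates short common prefixes
    for (cc in rev(codes)) h <- (h * 37 + cc) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
  affinity <- 10^(u * log10(50000))
  affinity <- pmin(pmax(affinity, 1), 50000)
  tibble(
    peptide = peptides,
    allele = allele,
    affinity_nm = affinity,
    rank_pct = 100 * log(affinity) / log(50000)
  )
}
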