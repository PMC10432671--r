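#' @title Synthetic input generation with known ground truth
#' @description Generators for every input the pipeline consumes — variant
#'   tables, protein FASTA, affinity predictions, binding-assay dilution
#'   series, T-cell readouts and MS ligand lists — built so that the
#'   correct downstream answer is known by construction. Every generator
#'   is a pure function of its parameters and seed (the caller's RNG state
#'   is untouched).
#' @name synthetic-data
NULL

#' Generate a somatic variant table with planted filter outcomes
#'
#' Produces `n_true` variants that pass every somatic filter rule and, for
#' each of the six rules (tumor coverage, normal coverage, normal VAF,
#' tumor VAF, strand support, population MAF), exactly `n_decoy_per_rule`
#' decoys that fail that rule alone (single-fault construction), so the
#' retained set after [apply_somatic_filters()] is predictable in closed
#' form. A protein sequence consistent with each variant's `ref_aa` at
#' `aa_pos` is generated alongside; mutations are placed well inside the
#' protein so downstream window enumeration and long-peptide design are
#' unconstrained by termini.
#'
#' @param n_true number of variants passing all filters.
#' @param n_decoy_per_rule decoys per filter rule, each failing only that
#'   rule.
#' @param seed integer seed.
#' @param cfg a [neovax_config()]; decoys are built relative to its
#'   thresholds.
#' @return a list with `variants` (tibble, see [read_variant_table()]),
#'   `proteins` (named character vector) and `truth` (list with
#'   `true_somatic_ids` and `decoy_rule`, a named map id -> failed rule).
#' @export
gen_variants <- function(n_true, n_decoy_per_rule, seed = 1L,
                         cfg = neovax_config()) {
  stopifnot(n_true >= 0, n_decoy_per_rule >= 0)
  validate_config(cfg)
  with_rng(seed, {
    rows <- list()
    proteins <- character(0)
    mk_base <- function(id) {
      len <- sample(90:160, 1)
      aa_pos <- sample(35:(len - 35), 1)
      prot <- random_protein(len)
      ref_aa <- substr(prot, aa_pos, aa_pos)
      alt_aa <- sample(setdiff(AA_STANDARD, ref_aa), 1)
      tumor_depth <- sample(40:80, 1)
      alt <- max(2, round(tumor_depth * runif(1, 0.25, 0.45)))
      fwd <- sample(seq_len(alt - 1), 1)
      list(
        row = tibble(
          id = id, gene = paste0("GENE_", id),
          protein_id = paste0("prot_", id),
          aa_pos = aa_pos, ref_aa = ref_aa, alt_aa = alt_aa,
          tumor_depth = tumor_depth, normal_depth = sample(40:80, 1),
          tumor_alt_reads = alt, normal_alt_reads = 0,
          alt_fwd = fwd, alt_rev = alt - fwd, pop_maf = 0
        ),
        protein = setNames(prot, paste0("prot_", id))
      )
    }
    for (i in seq_len(n_true)) {
      b <- mk_base(sprintf("var_true_%02d", i))
      rows[[length(rows) + 1]] <- b$row
      proteins <- c(proteins, b$protein)
    }
    for (rule in FILTER_RULES) {
      for (i in seq_len(n_decoy_per_rule)) {
        b <- mk_base(sprintf("var_%s_%02d", rule, i))
        r <- b$row
        if (rule == "tumor_coverage") {
          depth <- sample(max(4, cfg$coverage_min - 5):cfg$coverage_min, 1)
          alt <- max(2, ceiling(depth * 0.5))
          r$tumor_depth <- depth
          r$tumor_alt_reads <- alt
          r$alt_fwd <- 1
          r$alt_rev <- alt - 1
        } else if (rule == "normal_coverage") {
          r$normal_depth <- sample(max(2, cfg$coverage_min - 5):
                                     cfg$coverage_min, 1)
        } else if (rule == "normal_vaf") {
          r$normal_alt_reads <- max(1, ceiling(r$normal_depth * 5 *
                                                 cfg$normal_vaf_max))
        } else if (rule == "tumor_vaf") {
          alt <- max(2, floor(r$tumor_depth * 0.7 * cfg$tumor_vaf_min))
          r$tumor_alt_reads <- alt
          r$alt_fwd <- 1
          r$alt_rev <- alt - 1
        } else if (rule == "strand_support") {
          r$alt_fwd <- r$tumor_alt_reads
          r$alt_rev <- 0
        } else if (rule == "pop_maf") {
          r$pop_maf <- round(cfg$pop_maf_max * runif(1, 2, 10), 4)
        }
        rows[[length(rows) + 1]] <- r
        proteins <- c(proteins, b$protein)
      }
    }
    if (!length(rows)) {
      variants <- tibble(
        id = character(0), gene = character(0), protein_id = character(0),
        aa_pos = numeric(0), ref_aa = character(0), alt_aa = character(0),
        tumor_depth = numeric(0), normal_depth = numeric(0),
        tumor_alt_reads = numeric(0), normal_alt_reads = numeric(0),
        alt_fwd = numeric(0), alt_rev = numeric(0), pop_maf = numeric(0)
      )
    } else {
      variants <- bind_rows(rows)
      validate_variants(variants)
    }
    decoys <- !grepl("^var_true_", variants$id)
    list(
      variants = variants,
      proteins = proteins,
      truth = list(
        true_somatic_ids = variants$id[!decoys],
        decoy_rule = setNames(
          sub("^var_(.*)_\\d+$", "\\1", variants$id[decoys]),
          variants$id[decoys]
        )
      )
    )
  })
}

#' Generate binding-assay dilution series from true EC50/IC50 values
#'
#' Stabilization curves follow a four-parameter logistic,
#' `MFI(c) = baseline + (plateau - baseline) / (1 + (EC50/c)^h)` with Hill
#' slope `h = 1` (an EC50 defined as the half-maximal point is
#' slope-invariant), sampled at `n_dilutions` concentrations from
#' `top_concentration` down by `dilution_factor`, plus a no-peptide
#' control row at concentration 0. Competition curves report
#' `signal(c) = reference * (1 - 1 / (1 + (IC50/c)^h))`, so the signal is
#' exactly half the no-competitor reference at c = IC50. Noise is
#' multiplicative Gaussian with coefficient of variation `noise_cv`
#' (flow-cytometry MFI error scales with signal). Peptides whose true
#' value is NA are non-binders and yield flat curves at baseline (or at
#' the reference, for competition).
#'
#' @param peptides character vector of peptide ids.
#' @param true_ec50 named numeric map peptide -> true EC50 (stabilization)
#'   or IC50 (competition) in uM; NA or absent = non-binder.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param cfg a [neovax_config()].
#' @param assay_type `"stabilization"` or `"competition"`.
#' @param baseline,plateau stabilization MFI floor and ceiling.
#' @param reference FITC reference signal (competition).
#' @param hill Hill slope of the generating curve.
#' @return a long-format curve tibble (see [read_binding_curves()]).
#' @export
gen_binding_curves <- function(peptides, true_ec50, noise_cv = 0,
                               seed = 1L, cfg = neovax_config(),
                               assay_type = c("stabilization",
                                              "competition"),
                               baseline = 150, plateau = 1200,
                               reference = 1000, hill = 1) {
  assay_type <- match.arg(assay_type)
  validate_config(cfg)
  stopifnot(noise_cv >= 0)
  ok <- is.na(true_ec50) | (true_ec50 > 0.001 & true_ec50 < 1000)
  if (!all(ok)) {
    stop("true EC50/IC50 values must lie in (0.001, 1000) uM or be NA",
         call. = FALSE)
  }
  conc <- cfg$top_concentration / cfg$dilution_factor^(0:(cfg$n_dilutions - 1))
  with_rng(seed, {
    out <- lapply(peptides, function(pid) {
      e <- if (pid %in% names(true_ec50)) true_ec50[[pid]] else NA_real_
      if (assay_type == "stabilization") {
        ideal <- if (is.na(e)) rep(baseline, length(conc)) else {
          four_pl(conc, baseline, plateau, e, hill)
        }
        ctrl <- baseline
        ref <- NA_real_
      } else {
        ideal <- if (is.na(e)) rep(reference, length(conc)) else {
          reference * (1 - 1 / (1 + (e / conc)^hill))
        }
        ctrl <- reference
        ref <- reference
      }
      all_conc <- c(0, conc)
      all_sig <- c(ctrl, ideal)
      if (noise_cv > 0) {
        all_sig <- pmax(0, all_sig * (1 + rnorm(length(all_sig),
                                                0, noise_cv)))
      }
      tibble(
        peptide_id = pid, assay_type = assay_type,
        concentration_um = all_conc, signal = all_sig,
        reference_no_competitor = ref
      )
    })
    bind_rows(out)
  })
}

#' Generate T-cell assay readouts with planted responders
#'
#' Responder (subject, peptide) pairs receive a stimulated signal of at
#' least 2.5x the effective background and non-responders at most 1.5x,
#' with the unstimulated background jittered within 10%, so that
#' [call_responder()] at the 2x threshold separates the two classes
#' exactly.
#'
#' @param peptides character vector of peptide ids.
#' @param subjects character vector of subject ids.
#' @param responder_pairs tibble with columns `subject_id, peptide_id` of
#'   planted responders (may be empty).
#' @param background_pct unstimulated %IFN-gamma+ of CD8+, in (0, 5).
#' @param seed integer seed.
#' @param cfg a [neovax_config()] (supplies the zero floor used by the
#'   caller, which the responder class must clear).
#' @return a T-cell readout tibble (see [read_tcell_table()]).
#' @export
gen_tcell_assays <- function(peptides, subjects, responder_pairs,
                             background_pct = 0.4, seed = 1L,
                             cfg = neovax_config()) {
  stopifnot(background_pct > 0, background_pct < 5)
  validate_config(cfg)
  resp_key <- if (!is.null(responder_pairs) && nrow(responder_pairs)) {
    paste(responder_pairs$subject_id, responder_pairs$peptide_id)
  } else {
    character(0)
  }
  grid <- expand.grid(subject_id = subjects, peptide_id = peptides,
                      stringsAsFactors = FALSE)
  base_eff <- max(background_pct, cfg$zero_floor_pct)
  with_rng(seed, {
    unstim <- background_pct * runif(nrow(grid), 0.9, 1.1)
    is_resp <- paste(grid$subject_id, grid$peptide_id) %in% resp_key
    stim <- ifelse(
      is_resp,
      base_eff * runif(nrow(grid), 2.5, 4.0),
      background_pct * runif(nrow(grid), 0.5, 1.5)
    )
    tibble(
      subject_id = grid$subject_id, peptide_id = grid$peptide_id,
      stim_pct = pmin(100, stim), unstim_pct = pmin(100, unstim)
    )
  })
}

#' Generate an MS-eluted ligandome list
#'
#' Draws `n_background` distinct random 9-mers over the 20-residue
#' alphabet (composition realism is irrelevant because downstream matching
#' is exact-string) that never collide with the planted peptides, then
#' appends the planted set when `include_planted` is TRUE.
#'
#' @param n_background number of background ligandome peptides.
#' @param planted character vector of 8-11-mer peptides to plant.
#' @param seed integer seed.
#' @param include_planted include the planted peptides in the output.
#' @return a character vector of peptides.
#' @export
gen_ms_peptides <- function(n_background, planted = character(0),
                            seed = 1L, include_planted = TRUE) {
  stopifnot(n_background >= 0)
  if (length(planted) &&
      any(nchar(planted) < 8 | nchar(planted) > 11)) {
    stop("planted peptides must be 8-11 residues", call. = FALSE)
  }
  with_rng(seed, {
    bg <- character(0)
    while (length(bg) < n_background) {
      need <- n_background - length(bg)
      draw <- random_peptides(need + 5L)
      bg <- unique(c(bg, setdiff(draw, planted)))
    }
    bg <- bg[seq_len(n_background)]
    if (include_planted) c(bg, planted) else bg
  })
}

#' Generate an affinity table with planted selection decisions
#'
#' For every candidate, plants predicted mutant/wild-type affinities so
#' that the human selection rules reach a predetermined decision:
#' candidates in `selected_peptides` get a mutant affinity well below
#' their allele threshold with the wild-type counterpart well above it
#' (the differential-binding route), all others a mutant affinity above
#' the threshold. Ranks are the same monotone transform of affinity the
#' mock predictor uses.
#'
#' @param candidates candidate tibble with `allele` set.
#' @param selected_peptides mutant peptides that must be selected.
#' @param seed integer seed.
#' @param cfg a [neovax_config()].
#' @return a prediction tibble (see [read_affinity_table()]).
#' @export
gen_affinity_table <- function(candidates, selected_peptides,
                               seed = 1L, cfg = neovax_config()) {
  validate_config(cfg)
  with_rng(seed, {
    rows <- lapply(seq_len(nrow(candidates)), function(i) {
      allele <- candidates$allele[i]
      thr <- cfg$allele_thresholds[[allele]]
      if (is.null(thr)) {
        stop("no threshold configured for allele '", allele, "'",
             call. = FALSE)
      }
      wt_min <- if (allele %in% names(cfg$wt_affinity_min)) {
        cfg$wt_affinity_min[[allele]]
      } else {
        thr
      }
      if (candidates$mutant_peptide[i] %in% selected_peptides) {
        mut_nm <- thr * runif(1, 0.1, 0.8)
        wt_nm <- wt_min * runif(1, 1.5, 5)
      } else {
        mut_nm <- thr * runif(1, 1.5, 10)
        wt_nm <- wt_min * runif(1, 1.5, 10)
      }
      tibble(
        peptide = c(candidates$mutant_peptide[i],
                    candidates$wt_peptide[i]),
        allele = allele,
        affinity_nm = c(mut_nm, wt_nm)
      )
    })
    out <- bind_rows(rows)
    # a peptide may appear once as mutant and once (elsewhere) as WT;
    # keep the first planted value so lookups are unambiguous
    out <- out[!duplicated(out[c("peptide", "allele")]), ]
    out$rank_pct <- pmin(100, pmax(0, 100 * log(pmax(out$affinity_nm, 1)) /
                                     log(50000)))
    out
  })
}

derive_seed <- function(seed, k) {
  (as.numeric(seed) + 1000003 * k) %% 2147483647
}

#' Generate a complete synthetic study bundle with ground truth
#'
#' Builds every input for an end-to-end human-pipeline run at zero assay
#' noise: a variant table with planted filter outcomes, the matching
#' protein FASTA, an affinity table planting the selected-candidate set,
#' stabilization curves planting the binder set, T-cell readouts planting
#' the responder set, and a background-only MS ligandome (empty planted
#' overlap). Truth sets are returned alongside so a pipeline run can be
#' checked for exact recovery.
#'
#' @param seed integer master seed; stage seeds are derived from it.
#' @param n_true,n_decoy_per_rule passed to [gen_variants()].
#' @param n_selected_per_variant candidates planted as selected per true
#'   variant.
#' @param allele HLA allele of the simulated sample.
#' @param sample_id sample identifier used in summaries.
#' @param n_ms_background background ligandome size.
#' @param noise_cv binding-curve noise (default 0 for exact recovery).
#' @param cfg a [neovax_config()].
#' @return a list with `variants, proteins, affinities, curves, tcell, ms,
#'   sample_id, allele` and `truth` (list: `true_somatic_ids`,
#'   `selected_peptides`, `true_binders`, `true_ec50`,
#'   `true_responders`, `planted_ms_overlap`).
#' @export
simulate_bundle <- function(seed = 1L, n_true = 6, n_decoy_per_rule = 2,
                            n_selected_per_variant = 2,
                            allele = "HLA-A*02:01",
                            sample_id = "SIM01",
                            n_ms_background = 200,
                            noise_cv = 0,
                            cfg = neovax_config()) {
  validate_config(cfg)
  gv <- gen_variants(n_true, n_decoy_per_rule, derive_seed(seed, 1), cfg)
  true_variants <- gv$variants[gv$variants$id %in%
                                 gv$truth$true_somatic_ids, ]
  candidates <- enumerate_candidates(true_variants, gv$proteins,
                                     lengths = cfg$human_lengths)
  candidates$allele <- allele
  selected <- with_rng(derive_seed(seed, 2), {
    unlist(lapply(split(candidates$mutant_peptide,
                        candidates$source_variant), function(p) {
      sample(p, min(n_selected_per_variant, length(p)))
    }), use.names = FALSE)
  })
  affinities <- gen_affinity_table(candidates, selected,
                                   derive_seed(seed, 3), cfg)
  # binders: roughly two thirds of the selected peptides
  binders <- with_rng(derive_seed(seed, 4), {
    n_bind <- max(1, round(length(selected) * 2 / 3))
    sort(sample(selected, n_bind))
  })
  true_ec50 <- with_rng(derive_seed(seed, 5), {
    setNames(10^runif(length(binders), 0, 1.5), binders)  # 1-31.6 uM
  })
  curves <- gen_binding_curves(selected, true_ec50, noise_cv,
                               derive_seed(seed, 6), cfg)
  subjects <- paste0("donor", 1:3)
  true_responders <- with_rng(derive_seed(seed, 7), {
    resp_pep <- sample(binders, max(1, round(length(binders) / 2)))
    bind_rows(lapply(sort(resp_pep), function(p) {
      tibble(subject_id = sample(subjects,
                                 sample(1:length(subjects), 1)),
             peptide_id = p)
    }))
  })
  tcell <- gen_tcell_assays(binders, subjects, true_responders,
                            background_pct = 0.4,
                            seed = derive_seed(seed, 8), cfg = cfg)
  ms <- gen_ms_peptides(n_ms_background, planted = character(0),
                        seed = derive_seed(seed, 9))
  list(
    variants = gv$variants,
    proteins = gv$proteins,
    affinities = affinities,
    curves = curves,
    tcell = tcell,
    ms = ms,
    sample_id = sample_id,
    allele = allele,
    truth = list(
      true_somatic_ids = gv$truth$true_somatic_ids,
      decoy_rule = gv$truth$decoy_rule,
      selected_peptides = sort(selected),
      true_binders = binders,
      true_ec50 = true_ec50,
      true_responders = true_responders,
      planted_ms_overlap = character(0)
    )
  )
}
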