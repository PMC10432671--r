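#' Run the full neoantigen pipeline on a set of input files
#'
#' Orchestrates filter -> enumerate -> predict -> select -> assay ->
#' responders -> MS match -> summarize as one reproducible run. Stages
#' whose inputs are not supplied (binding curves, T-cell readouts, MS
#' list) are skipped; affinity predictions come either from a prediction
#' file produced by an external predictor or from the bundled
#' deterministic mock predictor (integration with external predictors is
#' file-based only; the pipeline never shells out). Stage outputs are
#' written to `out_dir` as they are produced, so a failing stage leaves
#' the preceding partial outputs on disk; the run manifest is written
#' last. Re-running with identical inputs, configuration and seed
#' reproduces identical outputs.
#'
#' @param variants_path somatic variant table (TSV).
#' @param proteins_path protein FASTA.
#' @param out_dir output directory (created if needed).
#' @param cfg a [neovax_config()].
#' @param affinity_path optional predicted-affinity TSV; required unless
#'   `use_mock_predictor` is TRUE.
#' @param use_mock_predictor score peptides with
#'   [mock_affinity_predictor()] instead of a prediction file.
#' @param curves_path optional binding-assay TSV.
#' @param tcell_path optional T-cell readout TSV.
#' @param ms_path optional MS peptide list TSV.
#' @param species `"human"` (affinity rules, 9-mers by default) or
#'   `"mouse"` (percentile-rank rule, 8-10-mers).
#' @param allele allele assigned to enumerated candidates (human) .
#' @param mouse_alleles alleles for the mouse rank rule.
#' @param sample_id sample label used in the summary.
#' @param seed seed for the mock predictor.
#' @return a list with `retained, audit, candidates, predictions,
#'   decisions, binding, responders, ms_match, summary, manifest`
#'   (unavailable stages are NULL).
#' @export
run_pipeline <- function(variants_path, proteins_path, out_dir,
                         cfg = neovax_config(),
                         affinity_path = NULL,
                         use_mock_predictor = FALSE,
                         curves_path = NULL, tcell_path = NULL,
                         ms_path = NULL,
                         species = c("human", "mouse"),
                         allele = "HLA-A*02:01",
                         mouse_alleles = c("H2-Db", "H2-Kb"),
                         sample_id = "sample1",
                         seed = cfg$rng_seed) {
  species <- match.arg(species)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  counts <- list()

  variants <- stage("read_inputs", read_variant_table(variants_path))
  proteins <- stage("read_inputs", read_fasta(proteins_path))
  counts$variants_in <- nrow(variants)

  flt <- stage("filter", apply_somatic_filters(variants, cfg))
  write_variant_table(flt$retained, file.path(out_dir, "retained.tsv"))
  write.table(flt$audit, file.path(out_dir, "audit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$variants_retained <- nrow(flt$retained)

  lengths <- if (species == "human") cfg$human_lengths else cfg$mouse_lengths
  candidates <- stage("enumerate", {
    cand <- enumerate_candidates(flt$retained, proteins, lengths)
    cand$allele <- allele
    cand
  })
  write.table(candidates, file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(candidates)) {
    write_fasta(setNames(candidates$mutant_peptide,
                         paste0(candidates$source_variant, "_mut_",
                                seq_len(nrow(candidates)))),
                file.path(out_dir, "mutant_peptides.fasta"))
    write_fasta(setNames(candidates$wt_peptide,
                         paste0(candidates$source_variant, "_wt_",
                                seq_len(nrow(candidates)))),
                file.path(out_dir, "wildtype_peptides.fasta"))
  }
  counts$candidates <- nrow(candidates)

  predictions <- stage("predict", {
    if (!is.null(affinity_path)) {
      read_affinity_table(affinity_path)
    } else if (use_mock_predictor) {
      peps <- unique(c(candidates$mutant_peptide, candidates$wt_peptide))
      if (species == "human") {
        mock_affinity_predictor(peps, allele, seed)
      } else {
        bind_rows(lapply(mouse_alleles, function(a) {
          mock_affinity_predictor(peps, a, seed)
        }))
      }
    } else {
      stop("affinity predictions missing: supply affinity_path or set ",
           "use_mock_predictor = TRUE")
    }
  })
  write_affinity_table(predictions, file.path(out_dir, "predictions.tsv"))

  decisions <- stage("select", {
    if (species == "human") {
      select_human_candidates(candidates, predictions, cfg)
    } else {
      select_mouse_candidates(candidates, predictions, cfg, mouse_alleles)
    }
  })
  write.table(decisions, file.path(out_dir, "decisions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts$selected <- sum(decisions$selected)

  binding <- NULL
  if (!is.null(curves_path)) {
    binding <- stage("assay", {
      fit_binding_curves(read_binding_curves(curves_path), cfg)
    })
    write.table(binding, file.path(out_dir, "binding.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts$binders <- sum(binding$binder)
  }

  responders <- NULL
  if (!is.null(tcell_path)) {
    responders <- stage("responders", {
      rec <- read_tcell_table(tcell_path)
      rec$responder <- call_responder(rec$stim_pct, rec$unstim_pct, cfg)
      rec
    })
    write_tcell_table(responders, file.path(out_dir, "responders.tsv"))
    counts$responder_pairs <- sum(responders$responder)
  }

  ms_match <- NULL
  if (!is.null(ms_path)) {
    ms_match <- stage("match_ms", {
      lig <- read_ms_peptides(ms_path)
      match_candidates(lig, decisions[decisions$selected, , drop = FALSE])
    })
    write.table(ms_match$overlap, file.path(out_dir, "ms_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$ms_overlap <- nrow(ms_match$overlap)
  }

  summary_tbl <- stage("summarize", {
    dec <- tibble(sample = sample_id, allele = decisions$allele,
                  peptide_id = decisions$mutant_peptide,
                  selected = decisions$selected)
    bnd <- if (!is.null(binding)) {
      tibble(sample = sample_id, peptide_id = binding$peptide_id,
             binder = binding$binder)
    } else {
      NULL
    }
    rsp <- if (!is.null(responders)) {
      tibble(sample = sample_id, peptide_id = responders$peptide_id,
             responder = responders$responder)
    } else {
      NULL
    }
    ms_tbl <- if (!is.null(ms_match) && nrow(ms_match$overlap)) {
      tibble(sample = sample_id,
             peptide_id = ms_match$overlap$mutant_peptide)
    } else {
      NULL
    }
    summarize_counts(dec, bnd, rsp, ms_tbl,
                     displayed_samples = if (!is.null(ms_match)) {
                       sample_id
                     } else {
                       character(0)
                     })
  })
  write.table(summary_tbl, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  inputs <- c(variants = variants_path, proteins = proteins_path,
              affinities = affinity_path, curves = curves_path,
              tcell = tcell_path, ms = ms_path)
  manifest <- list(
    tool = "neovax",
    version = as.character(utils::packageVersion("neovax")),
    seed = seed,
    species = species,
    sample_id = sample_id,
    config = unclass(cfg),
    input_digests = as.list(tools::md5sum(inputs[!vapply(inputs, is.null,
                                                         logical(1))])),
    stage_counts = counts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  list(retained = flt$retained, audit = flt$audit,
       candidates = candidates, predictions = predictions,
       decisions = decisions, binding = binding, responders = responders,
       ms_match = ms_match, summary = summary_tbl, manifest = manifest)
}

#' Write a synthetic bundle to disk
#'
#' Materializes the tables of [simulate_bundle()] as the TSV/FASTA files
#' [run_pipeline()] consumes, plus a truth TSV of planted somatic ids.
#'
#' @param bundle a list from [simulate_bundle()].
#' @param dir output directory.
#' @return named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    affinities = file.path(dir, "affinities.tsv"),
    curves = file.path(dir, "curves.tsv"),
    tcell = file.path(dir, "tcell.tsv"),
    ms = file.path(dir, "ms_peptides.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_variant_table(bundle$variants, paths["variants"])
  write_fasta(bundle$proteins, paths["proteins"])
  write_affinity_table(bundle$affinities, paths["affinities"])
  write_binding_curves(bundle$curves, paths["curves"])
  write_tcell_table(bundle$tcell, paths["tcell"])
  write_ms_peptides(bundle$ms, paths["ms"])
  write.table(
    data.frame(id = bundle$truth$true_somatic_ids),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths
}
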