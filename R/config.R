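#' Pipeline configuration
#'
#' All numeric thresholds used anywhere in the pipeline live in a single flat
#' configuration object, so no constant is hard-coded in an analysis
#' function. Defaults reflect the study design the package implements:
#' somatic calls are retained when tumor and normal coverage each exceed 10
#' reads, normal-tissue VAF is below 1%, tumor VAF is above 15%, variant
#' reads occur on both strands, and population MAF is at most 1%. Human
#' candidate epitopes are selected against allele-specific predicted-affinity
#' thresholds (HLA-A*02:01 1000 nM, HLA-A*03:01 1500 nM, HLA-A*24:02
#' 2500 nM, with the wild-type counterpart required above 1000 nM for
#' A*02:01); murine candidates against a 1% percentile-rank cutoff. Binding
#' assays titrate from 100 uM in eight serial dilution steps; T-cell
#' responders show at least twice the unstimulated background.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return an object of class `neovax_config`: a named list with fields
#'   `coverage_min` (reads, strict greater-than), `normal_vaf_max`
#'   (fraction, strict less-than), `tumor_vaf_min` (fraction, strict
#'   greater-than), `pop_maf_max` (fraction, retained when <=),
#'   `allele_thresholds` (named nM map), `wt_affinity_min` (named nM map for
#'   the wild-type side of the differential rule), `mouse_rank_max`
#'   (percent), `responder_fold`, `zero_floor_pct`, `top_concentration`
#'   (uM), `n_dilutions`, `dilution_factor`, `flank_len` (residues),
#'   `lp_len` (residues), `similar_affinity_fold`, `binder_plateau_fold`,
#'   `human_lengths`, `mouse_lengths`, `rng_seed`.
#' @export
#' @examples
#' cfg <- neovax_config()
#' cfg$allele_thresholds[["HLA-A*02:01"]]
#' neovax_config(dilution_factor = 2)$dilution_factor
neovax_config <- function(...) {
  cfg <- list(
    coverage_min = 10,
    normal_vaf_max = 0.01,
    tumor_vaf_min = 0.15,
    pop_maf_max = 0.01,
    allele_thresholds = c(
      "HLA-A*02:01" = 1000,
      "HLA-A*03:01" = 1500,
      "HLA-A*24:02" = 2500
    ),
    # WT side of the anchor differential rule: A*02:01 is stated explicitly
    # (WT above 1000 nM); the other alleles mirror their own mutant
    # threshold to preserve the differential-binding intent.
    wt_affinity_min = c(
      "HLA-A*02:01" = 1000,
      "HLA-A*03:01" = 1500,
      "HLA-A*24:02" = 2500
    ),
    mouse_rank_max = 1.0,
    responder_fold = 2.0,
    zero_floor_pct = 0.1,
    top_concentration = 100,
    n_dilutions = 8,
    dilution_factor = 3,
    flank_len = 10,
    lp_len = 31,
    similar_affinity_fold = 3,
    binder_plateau_fold = 1.5,
    human_lengths = 9L,
    mouse_lengths = c(8L, 9L, 10L),
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  class(cfg) <- "neovax_config"
  validate_config(cfg)
  cfg
}

#' @rdname neovax_config
#' @param cfg a `neovax_config` object.
#' @export
validate_config <- function(cfg) {
  scalar_pos <- c(
    "coverage_min", "normal_vaf_max", "tumor_vaf_min", "pop_maf_max",
    "mouse_rank_max", "responder_fold", "zero_floor_pct",
    "top_concentration", "n_dilutions", "dilution_factor", "flank_len",
    "lp_len", "similar_affinity_fold", "binder_plateau_fold"
  )
  for (key in scalar_pos) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("configuration key '", key, "' must be a positive number",
           call. = FALSE)
    }
  }
  if (cfg$n_dilutions < 2) {
    stop("n_dilutions must be at least 2", call. = FALSE)
  }
  thr <- cfg$allele_thresholds
  if (is.null(names(thr)) || any(!nzchar(names(thr))) || any(thr <= 0)) {
    stop("allele_thresholds must be a named map of positive nM values",
         call. = FALSE)
  }
  ok_allele <- grepl("^(HLA-[A-C]\\*\\d{2}:\\d{2}|H2-[DK]b)$", names(thr))
  if (any(!ok_allele)) {
    stop("invalid allele name(s) in allele_thresholds: ",
         paste(names(thr)[!ok_allele], collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read/write a configuration as a flat YAML document
#'
#' Every threshold of [neovax_config()] serializes to a `key: value` text
#' file so a run's configuration can be archived alongside its outputs.
#'
#' @param path file path.
#' @return `read_config()` returns a `neovax_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("allele_thresholds", "wt_affinity_min")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  for (key in c("human_lengths", "mouse_lengths")) {
    if (!is.null(raw[[key]])) raw[[key]] <- as.integer(unlist(raw[[key]]))
  }
  do.call(neovax_config, raw)
}

#' @rdname read_config
#' @param cfg a `neovax_config` object.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  # named atomic vectors must become lists to serialize as YAML maps
  for (key in c("allele_thresholds", "wt_affinity_min")) {
    out[[key]] <- as.list(out[[key]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
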