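cfg <- neovax_config()

aff_for <- function(cand, mut_nm, wt_nm) {
  tibble::tibble(
    peptide = c(cand$mutant_peptide, cand$wt_peptide),
    allele = cand$allele,
    affinity_nm = c(mut_nm, wt_nm),
    rank_pct = c(1, 1)
  )
}

test_that("anchor and TCR-facing positions are classified as 1/2/C-terminus", {
  expect_equal(classify_mutation_position(c(1, 2, 9, 5, 3, 8),
                                          rep(9, 6)),
               c("anchor", "anchor", "anchor", "tcr_facing", "tcr_facing",
                 "tcr_facing"))
  expect_equal(classify_mutation_position(8, 8), "anchor")
  expect_equal(classify_mutation_position(10, 10), "anchor")
})

test_that("human selection reproduces the published rule cases", {
  # anchor mutation, mutant 800 nM / WT 1500 nM on A*02:01: selected
  c1 <- make_candidate("YLFPNAPYL", "YIFPNAPYL", 2)
  d1 <- select_human_candidates(c1, aff_for(c1, 800, 1500), cfg)
  expect_true(d1$selected)
  expect_equal(d1$rule_path, "anchor_differential")
  # mutant above 1000 nM: rejected on affinity
  d2 <- select_human_candidates(c1, aff_for(c1, 1200, 1500), cfg)
  expect_false(d2$selected)
  expect_equal(d2$rule_path, "rejected_affinity")
  # TCR-facing mutation with similar strong binding of both: selected
  c3 <- make_candidate("NLAPWIKSV", "NLAPYIKSV", 5)
  d3 <- select_human_candidates(c3, aff_for(c3, 300, 350), cfg)
  expect_true(d3$selected)
  expect_equal(d3$rule_path, "nonanchor_similar")
  # same affinities at an anchor position: rejected for position
  c4 <- make_candidate("WLAPYIKSV", "NLAPYIKSV", 1)
  d4 <- select_human_candidates(c4, aff_for(c4, 300, 350), cfg)
  expect_false(d4$selected)
  expect_equal(d4$rule_path, "rejected_position")
  # unknown allele: configuration error
  c5 <- make_candidate("WLAPYIKSV", "NLAPYIKSV", 1, allele = "HLA-B*07:02")
  expect_error(select_human_candidates(c5, aff_for(c5, 300, 350), cfg),
               "threshold")
})

test_that("human selection agrees with the straight-line oracle on an exhaustive grid", {
  for (allele in names(cfg$allele_thresholds)) {
    thr <- cfg$allele_thresholds[[allele]]
    wt_min <- cfg$wt_affinity_min[[allele]]
    for (mut_nm in c(thr / 2, thr / 4, thr * 2)) {
      for (wt_nm in c(thr / 2, thr / 4, thr * 2)) {
        for (off in c(1, 2, 5, 9)) {
          cand <- make_candidate("AAAAKAAAA", "AAAAAAAAA", off,
                                 allele = allele)
          got <- select_human_candidates(cand, aff_for(cand, mut_nm, wt_nm),
                                         cfg)
          exp <- oracle_select_human(mut_nm, wt_nm, off, 9, thr, wt_min,
                                     cfg$similar_affinity_fold)
          info <- sprintf("%s mut=%g wt=%g off=%d", allele, mut_nm,
                          wt_nm, off)
          expect_equal(got$selected, exp$selected, info = info)
          expect_equal(got$rule_path, exp$rule_path, info = info)
        }
      }
    }
  }
})

test_that("loosening the affinity threshold never shrinks the selected set", {
  set.seed(42)
  cands <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_candidate(neovax:::random_peptides(1, 9),
                   neovax:::random_peptides(1, 9),
                   sample(1:9, 1), variant = paste0("v", i))
  }))
  aff <- tibble::tibble(
    peptide = c(cands$mutant_peptide, cands$wt_peptide),
    allele = "HLA-A*02:01",
    affinity_nm = 10^runif(80, 1, 4.3),
    rank_pct = 1
  )
  n_base <- sum(select_human_candidates(cands, aff, cfg)$selected)
  looser <- neovax_config(
    allele_thresholds = c("HLA-A*02:01" = 2000,
                          "HLA-A*03:01" = 1500, "HLA-A*24:02" = 2500)
  )
  expect_gte(sum(select_human_candidates(cands, aff, looser)$selected),
             n_base)
})

test_that("mouse selection honors the inclusive 1% rank boundary", {
  cand <- make_candidate("SIINFEKL", "SIINFEKI", 8, allele = NA)
  aff <- function(db, kb) tibble::tibble(
    peptide = "SIINFEKL", allele = c("H2-Db", "H2-Kb"),
    affinity_nm = c(100, 100), rank_pct = c(db, kb)
  )
  d1 <- select_mouse_candidates(cand, aff(3, 0.5), cfg)
  expect_true(d1$selected)
  expect_equal(d1$best_allele, "H2-Kb")
  expect_equal(d1$rule_path, "mouse_rank")
  d2 <- select_mouse_candidates(cand, aff(1.5, 1.5), cfg)
  expect_false(d2$selected)
  # exactly 1.0 falls within the 1% rank
  d3 <- select_mouse_candidates(cand, aff(1.0, 4), cfg)
  expect_true(d3$selected)
  expect_equal(d3$best_allele, "H2-Db")
})

test_that("mock predictor is deterministic, bounded and rank-monotone", {
  a <- mock_affinity_predictor(c("SIINFEKL", "NLAPYIKSV"), "H2-Kb", 7)
  b <- mock_affinity_predictor(c("SIINFEKL", "NLAPYIKSV"), "H2-Kb", 7)
  expect_identical(a, b)
  expect_false(identical(
    a$affinity_nm,
    mock_affinity_predictor(c("SIINFEKL", "NLAPYIKSV"), "H2-Kb", 8)$affinity_nm
  ))
  set.seed(1)
  peps <- unique(neovax:::random_peptides(1000, 9))
  pr <- mock_affinity_predictor(peps, "HLA-A*02:01", 3)
  expect_true(all(pr$affinity_nm >= 1 & pr$affinity_nm <= 50000))
  ord <- order(pr$affinity_nm)
  expect_false(is.unsorted(pr$rank_pct[ord]))
  expect_error(mock_affinity_predictor("AAAAAAAAAAAA", "H2-Kb", 1),
               "8-11")
})
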