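test_that("apply_mutation substitutes, checks the reference and reverts", {
  ctx <- apply_mutation("ACDEF", 3, "D", "Y")
  expect_equal(ctx$sequence, "ACYEF")
  expect_equal(ctx$wt_sequence, "ACDEF")
  expect_error(apply_mutation("ACDEF", 4, "D", "Y"), "reference mismatch")
  expect_error(apply_mutation("ACDEF", 4, "E", "E"), "missense")
  # involution: applying the reverse change restores the original
  back <- apply_mutation(ctx$sequence, 3, "Y", "D")
  expect_equal(back$sequence, "ACDEF")
})

test_that("mutation context is a 21-mer for interior sites, truncated at termini", {
  set.seed(21)
  prot <- neovax:::random_protein(500)
  ctx <- apply_mutation(prot, 100, substr(prot, 100, 100),
                        setdiff(neovax:::AA_STANDARD,
                                substr(prot, 100, 100))[1])
  win <- build_context_21mer(ctx)
  expect_equal(nchar(win$peptide), 21)
  expect_equal(win$mut_offset, 11)
  expect_equal(substr(win$peptide, 11, 11), ctx$alt_aa)
  # mutation at position 3 of the protein: 13-mer with offset 3
  ctx2 <- apply_mutation(prot, 3, substr(prot, 3, 3),
                         setdiff(neovax:::AA_STANDARD,
                                 substr(prot, 3, 3))[1])
  win2 <- build_context_21mer(ctx2)
  expect_equal(nchar(win2$peptide), 13)
  expect_equal(win2$mut_offset, 3)
  # the context is an exact substring of the mutated protein
  expect_equal(win$peptide, substr(ctx$sequence, win$start,
                                   win$start + 20))
})

test_that("window counts follow the containment combinatorics", {
  set.seed(8)
  prot <- neovax:::random_protein(60)
  mk <- function(pos) {
    ref <- substr(prot, pos, pos)
    apply_mutation(prot, pos, ref,
                   setdiff(neovax:::AA_STANDARD, ref)[1], variant_id = "v")
  }
  # interior: exactly L windows per length, offsets covering 1..L
  cand9 <- enumerate_mutant_windows(mk(30), 9)
  expect_equal(nrow(cand9), 9)
  expect_setequal(cand9$mut_offset, 1:9)
  expect_equal(nrow(enumerate_mutant_windows(mk(30), c(8, 9, 10))), 27)
  # boundary: mutation at position 1 gives a single window, offset 1
  cand1 <- enumerate_mutant_windows(mk(1), 9)
  expect_equal(nrow(cand1), 1)
  expect_equal(cand1$mut_offset, 1)
  # closed-form counts vs exhaustive-scan oracle at every position
  for (pos in c(1:12, 50:60)) {
    for (L in c(8, 9, 10)) {
      got <- nrow(enumerate_mutant_windows(mk(pos), L))
      expect_equal(got, oracle_window_count(pos, L, 60),
                   info = sprintf("pos=%d L=%d", pos, L))
    }
  }
})

test_that("mutant/wild-type pairs differ exactly at the mutant offset", {
  set.seed(99)
  for (rep in 1:20) {
    len <- sample(40:120, 1)
    prot <- neovax:::random_protein(len)
    pos <- sample(seq_len(len), 1)
    ref <- substr(prot, pos, pos)
    alt <- sample(setdiff(neovax:::AA_STANDARD, ref), 1)
    cand <- enumerate_mutant_windows(
      apply_mutation(prot, pos, ref, alt), c(8, 9, 10)
    )
    for (i in seq_len(nrow(cand))) {
      m <- strsplit(cand$mutant_peptide[i], "")[[1]]
      w <- strsplit(cand$wt_peptide[i], "")[[1]]
      diffs <- which(m != w)
      expect_identical(diffs, as.integer(cand$mut_offset[i]))
      expect_equal(m[diffs], alt)
      expect_equal(w[diffs], ref)
    }
  }
})

test_that("enumerating from the 21-mer context matches the full protein", {
  set.seed(5)
  prot <- neovax:::random_protein(200)
  pos <- 90
  ref <- substr(prot, pos, pos)
  alt <- sample(setdiff(neovax:::AA_STANDARD, ref), 1)
  ctx_full <- apply_mutation(prot, pos, ref, alt)
  win <- build_context_21mer(ctx_full)
  ctx_sub <- apply_mutation(win$wt_peptide, win$mut_offset, ref, alt)
  from_full <- enumerate_mutant_windows(ctx_full, c(8, 9, 10))
  from_ctx <- enumerate_mutant_windows(ctx_sub, c(8, 9, 10))
  expect_setequal(from_ctx$mutant_peptide, from_full$mutant_peptide)
  expect_setequal(from_ctx$wt_peptide, from_full$wt_peptide)
})

test_that("windows containing X are excluded", {
  prot <- paste0(strrep("A", 10), "X", strrep("G", 30))
  # mutate position 25, far enough that 8-mers avoid the X at 11
  ctx <- apply_mutation(prot, 25, "G", "W")
  cand <- enumerate_mutant_windows(ctx, c(8, 9, 10))
  expect_false(any(grepl("X", cand$mutant_peptide)))
  # mutate position 15: some windows would span the X and must be dropped
  ctx2 <- apply_mutation(prot, 15, "G", "W")
  cand2 <- enumerate_mutant_windows(ctx2, 9)
  expect_true(nrow(cand2) < 9)
  expect_false(any(grepl("X", cand2$mutant_peptide)))
})
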