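random_records <- function(seed) {
  set.seed(seed)
  samples <- c("s1", "s2", "s3")
  alleles <- c("HLA-A*02:01", "HLA-A*24:02")
  n <- 40
  decisions <- tibble::tibble(
    sample = sample(samples, n, replace = TRUE),
    allele = sample(alleles, n, replace = TRUE),
    peptide_id = sprintf("pep%02d", 1:n),
    selected = runif(n) < 0.8
  )
  sel <- decisions[decisions$selected, ]
  binding <- tibble::tibble(
    sample = sel$sample, peptide_id = sel$peptide_id,
    binder = runif(nrow(sel)) < 0.6
  )
  bnd <- binding[binding$binder, ]
  responders <- dplyr::bind_rows(lapply(seq_len(nrow(bnd)), function(i) {
    tibble::tibble(sample = bnd$sample[i], peptide_id = bnd$peptide_id[i],
                   subject_id = paste0("d", 1:3),
                   responder = runif(3) < 0.4)
  }))
  ms <- sel[runif(nrow(sel)) < 0.2, c("sample", "peptide_id")]
  list(decisions = decisions, binding = binding, responders = responders,
       ms = ms)
}

test_that("funnel counts match a direct counting oracle on random tables", {
  for (seed in 1:25) {
    r <- random_records(seed)
    out <- summarize_counts(r$decisions, r$binding, r$responders,
                            ms_overlap = r$ms,
                            displayed_samples = c("s1", "s2", "s3"))
    per <- out[out$sample != "Total", ]
    for (i in seq_len(nrow(per))) {
      sel <- r$decisions[r$decisions$selected &
                           r$decisions$sample == per$sample[i] &
                           r$decisions$allele == per$allele[i], ]
      key <- paste(sel$sample, sel$peptide_id)
      bkey <- with(r$binding[r$binding$binder, ], paste(sample, peptide_id))
      rkey <- with(r$responders[r$responders$responder, ],
                   paste(sample, peptide_id))
      mkey <- with(r$ms, paste(sample, peptide_id))
      expect_equal(per$n_predicted[i], nrow(sel))
      expect_equal(per$n_bound[i], sum(key %in% bkey))
      expect_equal(per$n_immunogenic[i],
                   sum(key %in% bkey & key %in% rkey))
      expect_equal(per$n_displayed[i], sum(key %in% mkey))
    }
    tot <- out[out$sample == "Total", ]
    expect_equal(tot$n_predicted, sum(per$n_predicted))
    expect_equal(tot$n_bound, sum(per$n_bound))
    expect_equal(tot$n_immunogenic, sum(per$n_immunogenic))
    # funnel invariants
    expect_true(all(out$n_bound <= out$n_predicted))
    expect_true(all(out$n_immunogenic <= out$n_bound))
  }
})

test_that("rates are percentages truncated to one decimal", {
  expect_equal(neovax:::rate_pct(44, 66), 66.6)
  expect_equal(neovax:::rate_pct(2, 3), 66.6)
  expect_equal(neovax:::rate_pct(1, 2), 50)
  expect_equal(neovax:::rate_pct(999, 1000), 99.9)
  expect_true(is.na(neovax:::rate_pct(0, 0)))
})

test_that("samples without display assays report n_displayed as NA", {
  dec <- tibble::tibble(sample = c("a", "b"), allele = "HLA-A*02:01",
                        peptide_id = c("p1", "p2"), selected = TRUE)
  bnd <- tibble::tibble(sample = c("a", "b"), peptide_id = c("p1", "p2"),
                        binder = TRUE)
  rsp <- tibble::tibble(sample = "a", peptide_id = "p1", responder = TRUE)
  ms <- tibble::tibble(sample = "b", peptide_id = "p2")
  out <- summarize_counts(dec, bnd, rsp, ms_overlap = ms,
                          displayed_samples = "b")
  expect_true(is.na(out$n_displayed[out$sample == "a"]))
  expect_equal(out$n_displayed[out$sample == "b"], 1)
  expect_equal(out$n_displayed[out$sample == "Total"], 1)
})

test_that("empty inputs produce a zero Total row", {
  dec <- tibble::tibble(sample = character(0), allele = character(0),
                        peptide_id = character(0), selected = logical(0))
  out <- summarize_counts(dec, dec[0, c("sample", "peptide_id")] |>
                            dplyr::mutate(binder = logical(0)),
                          tibble::tibble(sample = character(0),
                                         peptide_id = character(0),
                                         responder = logical(0)))
  expect_equal(nrow(out), 1)
  expect_equal(out$sample, "Total")
  expect_equal(out$n_predicted, 0)
})

test_that("downstream records for unknown peptides are a consistency error", {
  dec <- tibble::tibble(sample = "a", allele = "HLA-A*02:01",
                        peptide_id = "p1", selected = TRUE)
  bad <- tibble::tibble(sample = "a", peptide_id = "ghost", binder = TRUE)
  expect_error(summarize_counts(dec, bad, NULL), "consistency error")
})

test_that("expanding a count table and re-tallying is the identity", {
  counts <- tibble::tibble(
    sample = c("s1", "s1", "s2"),
    allele = c("HLA-A*02:01", "HLA-A*24:02", "HLA-A*02:01"),
    n_predicted = c(10L, 5L, 7L),
    n_bound = c(8L, 2L, 7L),
    n_immunogenic = c(3L, 0L, 5L),
    n_displayed = c(NA_integer_, NA_integer_, 2L)
  )
  rec <- expand_counts_to_records(counts)
  out <- summarize_counts(rec$decisions, rec$binding, rec$responders,
                          tumor_recognized = rec$tumor_recognized,
                          displayed_samples = rec$displayed_samples)
  per <- out[out$sample != "Total", names(counts)]
  expect_equal(as.data.frame(per), as.data.frame(counts))
})
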