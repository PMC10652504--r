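# Gene gating and transcript prioritisation.

test_that("gene gating is total over the validity levels", {
  outcomes <- vapply(
    c("definitive", "strong", "moderate", "limited", "disputed", "refuted",
      "none"),
    function(v) gate_gene(t_gene(clinical_validity = v)),
    character(1))
  expect_equal(unname(outcomes[c("definitive", "strong", "moderate",
                                 "limited")]),
               rep("classifiable", 4))
  expect_equal(unname(outcomes[c("disputed", "refuted", "none")]),
               rep("not_classifiable", 3))
})

test_that("expert-panel genes are delegated regardless of validity", {
  expect_equal(gate_gene(t_gene(vcep_curated = TRUE)), "vcep_delegate")
  expect_equal(gate_gene(t_gene(vcep_curated = TRUE,
                                clinical_validity = "disputed")),
               "vcep_delegate")
})

test_that("a missing validity field is a named validation error", {
  expect_error(gene_context("G1", "AD", clinical_validity = NA),
               "clinical_validity")
})

test_that("transcript priority follows the reference order", {
  tx <- list(transcript_record("NM_1", "refseq", 3000),
             transcript_record("NM_2", "mane_select", 2000))
  expect_equal(select_primary_transcript(tx)$id, "NM_2")
  tx2 <- list(transcript_record("NM_3", "refseq", 1000),
              transcript_record("NM_4", "mane_clinical_plus", 500),
              transcript_record("NM_5", "refseq_select", 800))
  expect_equal(select_primary_transcript(tx2)$id, "NM_5")
})

test_that("among plain RefSeq transcripts the largest wins", {
  tx <- list(transcript_record("NM_1", "refseq", 1000),
             transcript_record("NM_2", "refseq", 4000))
  expect_equal(select_primary_transcript(tx)$id, "NM_2")
  single <- list(transcript_record("NM_9", "refseq", 500))
  expect_equal(select_primary_transcript(single)$id, "NM_9")
})

test_that("transcript selection is permutation invariant with deterministic ties", {
  tx <- list(transcript_record("NM_b", "refseq", 2000),
             transcript_record("NM_a", "refseq", 2000),
             transcript_record("NM_c", c("refseq", "mane_clinical_plus"), 900))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(select_primary_transcript(tx[perm])$id, "NM_c")
  }
  refseq_only <- tx[1:2]
  expect_equal(select_primary_transcript(refseq_only)$id, "NM_a")
  expect_equal(select_primary_transcript(rev(refseq_only))$id, "NM_a")
  expect_error(select_primary_transcript(list()), "non-empty")
})

test_that("criterion calls validate their strength modulation", {
  expect_error(criterion_call("BA1", "S"), "not an allowed")
  expect_error(criterion_call("PS1", "VS"), "not an allowed")
  expect_silent(criterion_call("PM2", "M"))
  expect_error(criterion_call("XYZ", "P"), "unknown criterion")
  expect_error(criterion_call("PP5", "P"), "never applied")
})
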