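test_that("EF outcome rule implements the SHIM thresholds", {
  expect_identical(classify_ef_outcome(17, 2), 1L)
  expect_identical(classify_ef_outcome(16, 4), 1L)
  expect_identical(classify_ef_outcome(16, 3), 0L)
  expect_identical(classify_ef_outcome(25, 0), 1L)
  expect_identical(classify_ef_outcome(1, 5), 1L)
})

test_that("EF outcome rule is monotone non-decreasing in both arguments", {
  grid <- expand.grid(total = 1:25, q2 = 0:5)
  out <- classify_ef_outcome(grid$total, grid$q2)
  m <- matrix(out, nrow = 25, ncol = 6)
  # increasing either argument never flips 1 -> 0
  expect_true(all(diff(m) >= 0))
  expect_true(all(t(diff(t(m))) >= 0))
})

test_that("outcome rule validates its inputs by name", {
  expect_error(classify_ef_outcome(0, 3), "shim_total")
  expect_error(classify_ef_outcome(26, 3), "shim_total")
  expect_error(classify_ef_outcome(10, -1), "shim_q2")
  expect_error(classify_ef_outcome(10, 6), "shim_q2")
})

test_that("token normalization lowercases, trims and collapses whitespace", {
  expect_identical(normalize_token("  Cold   Cut "), "cold cut")
  expect_identical(normalize_token("Peel/Push"), "peel/push")
  expect_identical(normalize_token(c("A", "b  c")), c("a", "b c"))
})

test_that("vocabularies are deterministic bijections with reserved ids", {
  v <- vocabulary(c("spread", "cold cut", "spread"), "gesture")
  expect_s3_class(v, "cg_vocabulary")
  expect_identical(v$tokens, c("cold cut", "spread"))
  expect_identical(unname(v$index), c(2L, 3L))   # content starts after PAD, CLS
  expect_identical(v$pad_id, 0L)
  expect_identical(v$cls_id, 1L)
  # bijection round trip
  expect_identical(gestureEF:::id_token(v, gestureEF:::token_id(v, v$tokens)),
                   v$tokens)
})

test_that("vocabulary construction is order-independent over records", {
  ds <- fixture_cohort(n = 8)
  recs <- ds$records
  v1 <- build_vocabulary(recs)
  v2 <- build_vocabulary(rev(recs))
  expect_identical(v1, v2)
  # distinct-token count matches a direct scan
  toks <- unique(unlist(lapply(recs, function(r) r$sequence$gesture)))
  expect_identical(length(v1$gesture), length(toks))
  expect_error(build_vocabulary(list()), "empty")
})

test_that("case records validate ordinals and derive the outcome", {
  r <- fixture_record()
  expect_identical(r$sequence$ordinal, 0:2)
  expect_identical(r$ef_outcome, 1L)
  bad <- data.frame(gesture = "spread", anatomy = "lateral fascia",
                    `function` = "exposure", ordinal = 3L,
                    check.names = FALSE)
  expect_error(
    case_record("x", bad, fixture_clinical(), 10, 1),
    "ordinal"
  )
})

test_that("clinical features must be finite and positive", {
  expect_error(clinical_features(-1, 60, 25, 7, 5, 100), "prostate_volume")
  expect_error(clinical_features(40, 60, 25, 7, Inf, 100), "psa")
})

test_that("encoding produces the documented id matrix shapes", {
  vocabs <- default_vocabularies()
  r1 <- fixture_record(gestures = "spread")
  e1 <- encode_sequence(r1, vocabs, channels = "gesture")
  expect_identical(dim(e1$ids), c(2L, 1L))
  expect_identical(unname(e1$ids[1, 1]), 1L)  # CLS
  r3 <- fixture_record()
  e3 <- encode_sequence(r3, vocabs)
  expect_identical(dim(e3$ids), c(4L, 3L))
  expect_true(all(e3$ids[-1, ] >= 2L))        # content ids after reserved
})

test_that("decode(encode(record)) reproduces the token strings", {
  vocabs <- default_vocabularies()
  ds <- fixture_cohort(n = 6)
  for (r in ds$records) {
    enc <- encode_sequence(r, vocabs)
    dec <- decode_sequence(enc, vocabs)
    expect_identical(dec$gesture, r$sequence$gesture)
    expect_identical(dec$anatomy, r$sequence$anatomy)
    expect_identical(dec[["function"]], r$sequence[["function"]])
  }
})

test_that("unknown tokens are reported with token, channel and position", {
  vocabs <- default_vocabularies()
  r <- fixture_record(gestures = c("peel/push", "laser blast"))
  expect_error(encode_sequence(r, vocabs),
               "laser blast.*gesture.*position 1")
})

test_that("padding extends the mask and is reversible on decode", {
  vocabs <- default_vocabularies()
  enc <- encode_sequence(fixture_record(), vocabs)
  p <- pad_sequence(enc, 10L)
  expect_identical(nrow(p$ids), 10L)
  expect_identical(sum(p$attention_mask), 4L)
  expect_identical(decode_sequence(p, vocabs), decode_sequence(enc, vocabs))
  expect_error(pad_sequence(enc, 2L), "shorter")
})

test_that("annotation IO round-trips a cohort field-for-field", {
  ds <- fixture_cohort(n = 5)
  dir <- withr::local_tempdir()
  write_annotations(ds, dir)
  ds2 <- read_annotations(dir)
  expect_identical(names(ds2$records), names(ds$records))
  for (id in names(ds$records)) {
    expect_identical(ds2$records[[id]]$sequence, ds$records[[id]]$sequence)
    expect_equal(as.numeric(ds2$records[[id]]$clinical),
                 as.numeric(ds$records[[id]]$clinical))
    expect_identical(ds2$records[[id]]$ef_outcome, ds$records[[id]]$ef_outcome)
  }
  expect_identical(ds2$vocabularies, ds$vocabularies)
})

test_that("canonical re-serialization is byte-identical", {
  ds <- fixture_cohort(n = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_annotations(ds, d1)
  write_annotations(read_annotations(d1), d2)
  for (f in c("annotations.csv", "cases.csv", "vocabularies.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("an empty cohort file round-trips without error", {
  dir <- withr::local_tempdir()
  write_annotations(cohort_dataset(list()), dir)
  ds <- read_annotations(dir)
  expect_identical(length(ds$records), 0L)
})

test_that("malformed annotation files fail with informative parse errors", {
  ds <- fixture_cohort(n = 3)
  dir <- withr::local_tempdir()
  write_annotations(ds, dir)
  ann <- read.csv(file.path(dir, "annotations.csv"), check.names = FALSE)

  dup <- rbind(ann, ann[1, ])
  write.csv(dup, file.path(dir, "annotations.csv"), row.names = FALSE)
  expect_error(read_annotations(dir), "duplicate \\(case_id, ordinal\\)")

  gap <- ann[ann$ordinal != 1 | ann$case_id != "case01", ]
  write.csv(gap, file.path(dir, "annotations.csv"), row.names = FALSE)
  expect_error(read_annotations(dir), "non-contiguous ordinals.*case01")

  write.csv(ann[setdiff(names(ann), "gesture")],
            file.path(dir, "annotations.csv"), row.names = FALSE)
  expect_error(read_annotations(dir), "missing required column.*gesture")
})
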