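make_store <- function(n = 3, config = trio_config()) {
  svs <- sv_calls(tibble::tibble(
    chrom = "chrS", start = seq(1000, by = 4000, length.out = n),
    end = seq(3000, by = 4000, length.out = n), svtype = "DEL"))
  curation_project(config, dplyr::rename(svs, image_id = id))
}

test_that("config validation enforces uniqueness and arity", {
  expect_s3_class(trio_config(), "curation_config")
  expect_s3_class(cancer_config(), "curation_config")
  expect_error(curation_config("p", "q?", c("YES")), ">= 2 answers")
  expect_error(curation_config("p", "q?", c("A", "A")), "duplicate answers")
  expect_error(curation_config("p", "q?", c("A", "B"), keys = c("a", "a")),
               "duplicate keys")
  expect_error(curation_config("p", "q?", c("A", "B"), keys = c("ab", "c")),
               "single characters")
})

test_that("JSON configs round-trip and report missing fields by name", {
  path <- tempfile(fileext = ".json")
  write_curation_config(trio_config(), path)
  cfg <- load_curation_config(path)
  expect_equal(cfg$answers, c("GOOD", "BAD", "DE NOVO"))
  expect_equal(cfg$question, trio_config()$question)

  writeLines('{"project": "x"}', path)
  expect_error(load_curation_config(path), "curationQandA")
  writeLines('{"project":"x","curationQandA":{"answers":["A","B"]}}', path)
  expect_error(load_curation_config(path), "question")
})

test_that("responses append, validate, and supersede per reviewer", {
  store <- make_store(2)
  id1 <- store$images$image_id[1]
  store <- record_response(store, id1, "r1", "GOOD")
  expect_equal(curation_scores(store)$n_responses[1], 1L)
  # same reviewer re-scores: latest wins, count stays 1
  store <- record_response(store, id1, "r1", "BAD")
  sc <- curation_scores(store)
  expect_equal(sc$n_responses[1], 1L)
  expect_equal(sc$count_BAD[1], 1L)
  expect_equal(sc$count_GOOD[1], 0L)

  expect_error(record_response(store, id1, "r1", "MAYBE"), "invalid answer")
  expect_error(record_response(store, "nope", "r1", "GOOD"),
               "unknown image_id")
})

test_that("batch import rejects invalid rows and keeps the rest", {
  store <- make_store(2)
  ids <- store$images$image_id
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    image_id = c(ids[1], ids[2], "ghost", ids[1]),
    reviewer = c("r1", "r1", "r1", "r2"),
    answer = c("GOOD", "BAD", "GOOD", "MAYBE")), tsv)
  expect_warning(store <- import_responses(store, tsv), "2 response row")
  expect_equal(nrow(attr(store, "rejected")), 2)
  expect_equal(nrow(latest_responses(store)), 2)
})

test_that("stores survive a save/load round trip", {
  store <- make_store(2)
  store <- record_response(store, store$images$image_id[1], "r1", "GOOD",
                           timestamp = "2026-01-01T00:00:00Z",
                           elapsed_seconds = 2.5)
  path <- tempfile(fileext = ".json")
  save_curation_store(store, path)
  back <- load_curation_store(path)
  expect_equal(back$config$answers, store$config$answers)
  expect_equal(back$images, store$images)
  expect_equal(back$responses, store$responses)
})

test_that("score aggregation matches arithmetic on the mapped values", {
  m <- score_mapping()
  expect_equal(aggregate_curation_score(rep("GOOD", 9), m), 1.0)
  expect_equal(aggregate_curation_score(c(rep("GOOD", 5), rep("BAD", 4)),
                                        m), 5 / 9)
  expect_equal(aggregate_curation_score(c("GOOD", "DE NOVO", "BAD"), m),
               2 / 3)
  cm <- score_mapping(c(TUMOR = 3, BOTH = 2, NORMAL = 1, NEITHER = 0),
                      "mode")
  expect_equal(aggregate_curation_score(c("TUMOR", "TUMOR", "BOTH"), cm), 3)
  # mode ties break toward the larger value
  expect_equal(aggregate_curation_score(c("TUMOR", "BOTH"), cm), 3)
  sdm <- score_mapping(c(GOOD = 1, "DE NOVO" = 1, BAD = 0), "sd")
  expect_equal(aggregate_curation_score(c("GOOD", "BAD"), sdm), 0.5)
  expect_error(aggregate_curation_score(character(0), m), "empty")
  expect_error(aggregate_curation_score("HMM", m), "unmapped")
})

test_that("aggregation is permutation invariant and bounded", {
  m <- score_mapping()
  answers <- c("GOOD", "BAD", "DE NOVO")
  withr::with_seed(17, {
    for (agg in c("mean", "median", "mode", "min", "max")) {
      mm <- score_mapping(m$values, agg)
      for (rep in 1:20) {
        a <- sample(answers, sample(1:15, 1), replace = TRUE)
        s <- aggregate_curation_score(a, mm)
        expect_equal(s, aggregate_curation_score(sample(a), mm))
        expect_gte(s, 0); expect_lte(s, 1)
      }
    }
  })
})

test_that("score classes partition [0, 1]", {
  expect_equal(classify_curation_score(1), "UNANIMOUS_HIGH")
  expect_equal(classify_curation_score(0), "UNANIMOUS_LOW")
  expect_equal(classify_curation_score(8 / 9), "UNAMBIGUOUS_HIGH")
  expect_equal(classify_curation_score(1 / 9), "UNAMBIGUOUS_LOW")
  expect_equal(classify_curation_score(0.5), "AMBIGUOUS")
  expect_equal(classify_curation_score(0.2), "AMBIGUOUS")  # inclusive
  expect_equal(classify_curation_score(0.8), "AMBIGUOUS")  # inclusive
  # every score in a fine grid gets exactly one class
  grid <- seq(0, 1, by = 0.001)
  cls <- classify_curation_score(grid)
  expect_false(anyNA(cls))
  expect_setequal(unique(cls), c("UNANIMOUS_HIGH", "UNANIMOUS_LOW",
                                 "UNAMBIGUOUS_HIGH", "UNAMBIGUOUS_LOW",
                                 "AMBIGUOUS"))
  expect_error(classify_curation_score(1.2), "0, 1")
})

test_that("reports cover every image and conserve response counts", {
  store <- make_store(3)
  ids <- store$images$image_id
  store <- record_response(store, ids[1], "r1", "GOOD")
  store <- record_response(store, ids[1], "r2", "GOOD")
  store <- record_response(store, ids[1], "r3", "GOOD")
  store <- record_response(store, ids[2], "r1", "BAD")
  report <- generate_report(store)
  expect_equal(nrow(report), 3)
  expect_equal(report$score[report$image_id == ids[1]], 1.0)
  expect_equal(report$n_responses[report$image_id == ids[3]], 0L)
  expect_true(is.na(report$score[report$image_id == ids[3]]))
  # conservation: total counts equal distinct latest responses
  cnt_cols <- grep("^count_", names(report), value = TRUE)
  expect_equal(sum(as.matrix(report[cnt_cols])),
               nrow(latest_responses(store)))
  # rows ordered by (chrom, start)
  expect_equal(report$start, sort(report$start))
  # written TSV has an empty score for unscored images
  tsv <- tempfile(fileext = ".tsv")
  generate_report(store, path = tsv)
  raw <- readLines(tsv)
  expect_equal(length(raw), 4)
})

test_that("VCF annotation adds SVP tags and round-trips exactly", {
  store <- make_store(2)
  ids <- store$images$image_id
  for (r in paste0("r", 1:9)) {
    store <- record_response(store, ids[1], r, "GOOD")
  }
  store <- record_response(store, ids[2], "r1", "GOOD")
  store <- record_response(store, ids[2], "r2", "BAD")
  scores <- curation_scores(store)

  vcf <- tempfile(fileext = ".vcf")
  write_sv_vcf(store$images |>
                 dplyr::rename(id = image_id), vcf,
               contig_lengths = c(chrS = 100000))
  ann <- tempfile(fileext = ".vcf")
  annotate_vcf_with_scores(vcf, scores, ann)
  lines <- readLines(ann)
  expect_true(any(grepl("^##INFO=<ID=SVP,Number=1,Type=Float", lines)))
  expect_true(any(grepl("SVP=1\\.0000", lines)))
  expect_true(any(grepl("SVP=0\\.5000", lines)))
  # annotate-then-strip is the identity
  stripped <- tempfile(fileext = ".vcf")
  strip_vcf_scores(ann, stripped)
  expect_identical(readLines(stripped), readLines(vcf))
  # unscored records stay untouched
  scores2 <- scores; scores2$score[2] <- NA
  ann2 <- tempfile(fileext = ".vcf")
  annotate_vcf_with_scores(vcf, scores2, ann2)
  body <- grep("^#", readLines(ann2), invert = TRUE, value = TRUE)
  expect_equal(sum(grepl("SVP=", body)), 1)
})

test_that("curation summaries match hand-tallied fractions", {
  scores <- tibble::tibble(
    image_id = paste0("i", 1:10), chrom = "chrS",
    start = seq(0, 9000, by = 1000),
    end = seq(0, 9000, by = 1000) + c(rep(500, 5), rep(2000, 5)),
    svtype = "DEL",
    score = c(rep(1, 7), 0, 0.5, 0.5))
  sm <- summarize_curation(scores)
  expect_equal(sm$frac_unanimous, 0.8)
  expect_equal(sm$frac_unanimous_high, 0.7)
  expect_equal(sm$frac_unanimous_low, 0.1)
  expect_equal(sm$frac_unambiguous, 0.8)
  expect_equal(sm$frac_ambiguous, 0.2)
  expect_equal(sm$median_size_all,
               median(scores$end - scores$start))
  td <- tidy(sm)
  expect_equal(nrow(td), 4)

  # excluded images leave the denominators
  sm2 <- summarize_curation(scores, exclusions = c("i9", "i10"))
  expect_equal(sm2$frac_unanimous, 1.0)
  expect_true(is.na(sm2$median_size_ambiguous))
  expect_error(summarize_curation(scores, exclusions = scores$image_id),
               "no scored images")
})

test_that("concordance against orthogonal calls matches a hand tally", {
  scores <- tibble::tibble(
    image_id = paste0("i", 1:12), chrom = "chrS", start = 0, end = 1000,
    svtype = c(rep("DEL", 11), "INV"),
    score = c(1, 1, 1, 1, 0.9, 0, 0, 0.1, 1, 0.5, 1, 1))
  calls <- tibble::tibble(
    image_id = paste0("i", 1:12),
    genotype = c("het", "hom_alt", "hom_ref", "het", "het", "hom_ref",
                 "het", "hom_ref", "missing", "het", "het", "het"),
    copy_number = c(1.0, 0.5, 2.0, 1.2, 1.0, 2.0, 2.2, 1.0, 1.5, 2,
                    NA, 1))
  cc <- concordance_with_orthogonal(scores, calls)
  # eligible: unambiguous deletions i1-i9 and i11 (i10 ambiguous, i12 INV)
  # genotype denominators drop i9 (missing) and i11 stays: n = 9;
  # hand tally: agree i1 i2 i4 i5 (high, non-ref), i6 i8 (low, hom_ref),
  # i11; disagree i3 (high, hom_ref), i7 (low, het) -> 7/9
  expect_equal(cc$n_genotype, 9)
  expect_equal(cc$genotype_agreement, 7 / 9)
  # copy number drops i11 (NA): n = 9; agree i1 i2 i4 i5 (high, cn < 1.4),
  # i6 i7 (low, copy-neutral); disagree i3 i9 (high, neutral) and i8
  # (low, cn 1.0: orthogonal false positive) -> 6/9
  expect_equal(cc$n_copy_number, 9)
  expect_equal(cc$cn_agreement, 6 / 9)
  expect_s3_class(tidy(cc), "tbl_df")
  expect_error(concordance_with_orthogonal(scores[c(10, 12), ], calls),
               "no unambiguous deletions")
})

test_that("orthogonal call TSVs validate genotype labels", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(image_id = "a", genotype = "weird",
                                  copy_number = 2), tsv)
  expect_error(read_orthogonal_calls(tsv), "unknown genotype")
  readr::write_tsv(tibble::tibble(image_id = "a", genotype = "het",
                                  copy_number = 1.1), tsv)
  expect_equal(nrow(read_orthogonal_calls(tsv)), 1)
})
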