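test_that("insert stats recover constant and closed-form span sets", {
  lines <- as_sorted_sam(c(
    proper_pair_lines("q1", "chrT", 101, 300),
    proper_pair_lines("q2", "chrT", 201, 300),
    proper_pair_lines("q3", "chrT", 301, 300)))
  bam <- make_bam(lines, "const")
  st <- estimate_insert_stats(bam)
  expect_equal(st$mean, 300)
  expect_equal(st$sd, 0)
  expect_equal(st$n, 3)

  lines <- as_sorted_sam(c(
    proper_pair_lines("q1", "chrT", 101, 200),
    proper_pair_lines("q2", "chrT", 201, 300),
    proper_pair_lines("q3", "chrT", 301, 400)))
  st <- estimate_insert_stats(make_bam(lines, "three"))
  expect_equal(st$mean, 300)
  expect_equal(st$sd, sqrt(20000 / 3), tolerance = 1e-10)  # population sd
})

test_that("insert stats match a brute-force pass over the raw records", {
  fix <- small_del_fixture(seed = 7)
  st <- estimate_insert_stats(fix$bam)
  rec <- scan_all_records(fix$bam)
  primary <- bitwAnd(rec$flag, 256L + 2048L + 1024L + 512L + 4L) == 0L
  lead <- primary & bitwAnd(rec$flag, 2L) > 0L &
    rec$strand == "+" & bitwAnd(rec$flag, 32L) > 0L &
    rec$mrnm == rec$rname & (rec$pos - 1) <= (rec$mpos - 1)
  g <- rec[lead, ]
  mates <- rec[primary, ]
  key <- paste(mates$qname, mates$pos)
  spans <- vapply(seq_len(nrow(g)), function(i) {
    m <- mates[mates$qname == g$qname[i] & mates$pos == g$mpos[i], ][1, ]
    (m$pos - 1 + oracle_cigar_ref_width(m$cigar)) - (g$pos[i] - 1)
  }, numeric(1))
  expect_equal(st$n, length(spans))
  expect_equal(st$mean, mean(spans))
  expect_equal(st$sd, sqrt(mean((spans - mean(spans))^2)))
})

test_that("insert stats estimation fails cleanly without qualifying pairs", {
  lines <- as_sorted_sam(
    sam_line("solo", 0, "chrT", 500, "50M"))  # unpaired read
  expect_error(estimate_insert_stats(make_bam(lines, "nopairs")),
               "no qualifying")
})

test_that("pair extraction matches the brute-force oracle exactly", {
  fix <- small_del_fixture(seed = 5)
  st <- estimate_insert_stats(fix$bam)
  win <- genomic_window("chrS", 4000, 8000)  # <= 10 kb window
  got <- norm_df(as.data.frame(extract_pair_evidence(fix$bam, win, st)))
  want <- norm_df(oracle_pair_evidence(fix$bam, win, st))
  expect_equal(got, want)
  expect_gt(sum(got$evclass == "DELETION"), 0)
})

test_that("pair extraction honors window and pairing contracts", {
  # a pair with only one mate inside the window is still returned
  lines <- as_sorted_sam(proper_pair_lines("far", "chrT", 101, 800))
  bam <- make_bam(lines, "onemate")
  got <- extract_pair_evidence(bam, genomic_window("chrT", 50, 200),
                               insert_stats(300, 50))
  expect_equal(nrow(got), 1)
  expect_equal(got$evclass, "DELETION")  # span 800 > 300 + 4 * 50
  expect_equal(got$left_start, 100)
  expect_equal(got$right_end, 900)

  # both mates inside the window: the pair is emitted once
  got2 <- extract_pair_evidence(bam, genomic_window("chrT", 50, 950),
                                insert_stats(300, 50))
  expect_equal(nrow(got2), 1)

  # window with no alignments: empty list, not an error
  empty <- extract_pair_evidence(bam, genomic_window("chrT", 5000, 6000),
                                 insert_stats(300, 50))
  expect_equal(nrow(empty), 0)
})

test_that("split extraction matches the brute-force oracle exactly", {
  fix <- small_del_fixture(seed = 5)
  win <- genomic_window("chrS", 4000, 8000)
  got <- norm_df(as.data.frame(extract_split_evidence(fix$bam, win)))
  want <- norm_df(oracle_split_evidence(fix$bam, win))
  expect_equal(got, want)
  expect_true(all(got$evclass == "DELETION"))
  expect_gt(nrow(got), 0)
})

test_that("split extraction emits planted breakpoints once per read", {
  fix <- small_del_fixture(seed = 5)
  sp <- extract_split_evidence(fix$bam, fix$window)
  expect_equal(nrow(sp), fix$truth$n_support_splits)
  expect_false(anyDuplicated(sp$qname) > 0)
  # split segments pinpoint the planted breakpoints
  expect_true(all(sp$seg1_end == fix$sv$start))
  expect_true(all(sp$seg2_start == fix$sv$end))
})

test_that("three-segment reads emit adjacent pairs only", {
  # one read split into three same-strand segments, read order preserved
  tags <- function(excl) {
    ents <- c("chrT,101,+,30M70S,60,0;", "chrT,1001,+,30S30M40S,60,0;",
              "chrT,2001,+,60S40M,60,0;")
    paste0("SA:Z:", paste0(ents[-excl], collapse = ""))
  }
  lines <- as_sorted_sam(c(
    sam_line("r3", 0, "chrT", 101, "30M70S", tags = tags(1)),
    sam_line("r3", 2048, "chrT", 1001, "30S30M40S", tags = tags(2)),
    sam_line("r3", 2048, "chrT", 2001, "60S40M", tags = tags(3))))
  sp <- extract_split_evidence(make_bam(lines, "triple"),
                               genomic_window("chrT", 0, 5000))
  expect_equal(nrow(sp), 2)
  expect_equal(sp$seg1_start, c(100, 1000))
  expect_equal(sp$seg2_start, c(1000, 2000))
  expect_true(all(sp$evclass == "DELETION"))
})

test_that("malformed SA entries are skipped with a warning", {
  lines <- as_sorted_sam(c(
    sam_line("bad", 0, "chrT", 101, "30M70S", tags = "SA:Z:chrT,oops;")))
  expect_warning(
    sp <- extract_split_evidence(make_bam(lines, "badsa"),
                                 genomic_window("chrT", 0, 5000)),
    "malformed")
  expect_equal(nrow(sp), 0)
})

test_that("coverage matches a brute-force per-base tally exactly", {
  fix <- small_del_fixture(seed = 5)
  win <- genomic_window("chrS", 4000, 8000)
  got <- compute_coverage(fix$bam, win)
  expect_equal(got$depth, oracle_coverage(fix$bam, win))
  expect_equal(nrow(got), 4000)
})

test_that("coverage counts aligned bases only", {
  lines <- as_sorted_sam(c(
    sam_line("r1", 0, "chrT", 101, "100M"),
    sam_line("r2", 0, "chrT", 301, "20S60M20S"),
    sam_line("r3", 0, "chrT", 501, "40M20D40M")))
  bam <- make_bam(lines, "covops")
  cov <- compute_coverage(bam, genomic_window("chrT", 0, 1000))
  d <- cov$depth
  expect_equal(sum(d[101:200]), 100)       # plain read: 100 bases at depth 1
  expect_equal(sum(d[301:400]), 60)        # soft clips don't count
  expect_equal(d[541:560], rep(0L, 20))    # deletion gap doesn't count
  expect_equal(sum(d[501:600]), 80)
  # empty window: all-zero track of the right length
  cov0 <- compute_coverage(bam, genomic_window("chrT", 5000, 6000))
  expect_equal(cov0$depth, rep(0L, 1000))
})

test_that("downsampling preserves discordant pairs and caps normals", {
  fix <- small_del_fixture(seed = 5)
  st <- estimate_insert_stats(fix$bam)
  pairs <- extract_pair_evidence(fix$bam, fix$window, st)
  n_disc <- sum(pairs$evclass != "NORMAL")
  expect_gt(n_disc, 0)

  ds <- downsample_normal_pairs(pairs, max_normals = 50, seed = 3)
  expect_equal(sum(ds$evclass != "NORMAL"), n_disc)
  expect_equal(sum(ds$evclass == "NORMAL"),
               min(sum(pairs$evclass == "NORMAL"), 50))
  # relative order preserved: output is a subsequence of the input
  expect_equal(ds$qname, pairs$qname[pairs$qname %in% ds$qname])
  # reproducible for a fixed seed
  expect_identical(ds, downsample_normal_pairs(pairs, 50, seed = 3))
  # no-op cases
  expect_identical(downsample_normal_pairs(pairs, nrow(pairs), seed = 1),
                   pairs)
  only_disc <- pairs[pairs$evclass != "NORMAL", ]
  expect_identical(downsample_normal_pairs(only_disc, 0, seed = 1),
                   only_disc)
  expect_error(downsample_normal_pairs(pairs, -1), "max_normals")
})

test_that("gather_sample_evidence composes tracks deterministically", {
  fix <- small_del_fixture(seed = 5)
  tr1 <- gather_sample_evidence(fix$bam, fix$window, seed = 2,
                                sample_name = "s1")
  tr2 <- gather_sample_evidence(fix$bam, fix$window, seed = 2,
                                sample_name = "s1")
  expect_identical(tr1, tr2)
  expect_s3_class(tr1, "sample_tracks")
  expect_gt(sum(tr1$pairs$evclass == "DELETION"), 0)
  expect_gt(nrow(tr1$splits), 0)
  # coverage dips over the het deletion
  inside <- with(tr1$coverage, mean(depth[pos >= 5200 & pos < 6800]))
  flank <- with(tr1$coverage, mean(depth[pos < 4800]))
  expect_lt(inside / flank, 0.65)
  expect_gt(inside / flank, 0.35)

  # empty region: empty evidence, zero coverage
  bam1 <- make_bam(as_sorted_sam(proper_pair_lines("p", "chrT", 101, 300)),
                   "sparse")
  tr0 <- gather_sample_evidence(bam1, genomic_window("chrT", 5000, 6000),
                                sample_name = "s1")
  expect_equal(nrow(tr0$pairs) + nrow(tr0$splits), 0)
  expect_true(all(tr0$coverage$depth == 0))
})

test_that("tidy and glance summarize sample tracks", {
  fix <- small_del_fixture(seed = 5)
  tr <- gather_sample_evidence(fix$bam, fix$window, sample_name = "s1")
  td <- tidy(tr)
  expect_equal(nrow(td), nrow(tr$pairs) + nrow(tr$splits))
  expect_named(td, c("sample", "kind", "class", "left_start", "left_end",
                     "right_start", "right_end", "strands", "span"))
  gl <- glance(tr)
  expect_equal(gl$modal_discordant_class, "DELETION")
  tsv <- tempfile(fileext = ".tsv")
  write_evidence_tsv(tr, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)),
               nrow(td))
})

test_that("missing index and invalid windows raise clear errors", {
  fix <- small_del_fixture(seed = 5)
  nobai <- tempfile(fileext = ".bam")
  file.copy(fix$bam, nobai)
  expect_error(compute_coverage(nobai, fix$window), "index")
  expect_error(genomic_window("chrS", -5, 100), "start")
  expect_error(genomic_window("chrS", 100, 100), "end")
})
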