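# Shared fixtures: hand-written SAM records for exact-value tests and
# cached synthetic BAMs for pipeline tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# one SAM alignment line; seq/qual sized from the cigar
sam_line <- function(qname, flag, rname, pos, cigar, mrnm = "=", mpos = 1,
                     tlen = 0, mapq = 60, tags = character()) {
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = FALSE)
  paste(c(qname, flag, rname, pos, mapq, cigar, mrnm, mpos, tlen,
          strrep("A", qlen), strrep("I", qlen), tags), collapse = "\t")
}

sam_header <- function(contigs = c(chrT = 10000)) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
}

# write SAM lines to an indexed BAM in a temp dir; records must be sorted
make_bam <- function(lines, name = "fix") {
  dir <- tempfile("svcfix")
  dir.create(dir)
  sam <- file.path(dir, paste0(name, ".sam"))
  writeLines(lines, sam)
  Rsamtools::asBam(sam, destination = file.path(dir, name),
                   overwrite = TRUE, indexDestination = TRUE)
}

# a proper +/- pair with the given outer span (read length 50)
proper_pair_lines <- function(qname, rname, pos, span, rl = 50) {
  mpos <- pos + span - rl
  c(sam_line(qname, 99, rname, pos, paste0(rl, "M"), mpos = mpos,
             tlen = span, tags = paste0("MC:Z:", rl, "M")),
    sam_line(qname, 147, rname, mpos, paste0(rl, "M"), mpos = pos,
             tlen = -span, tags = paste0("MC:Z:", rl, "M")))
}

# sort raw body lines by (rname, pos) and prepend a header
as_sorted_sam <- function(body, contigs = c(chrT = 10000)) {
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 4))
  rn <- vapply(strsplit(body, "\t"), `[[`, "", 3)
  c(sam_header(contigs), body[order(match(rn, names(contigs)), pos)])
}

# standard het-DEL trio fixture used across tests
trio_fixture <- function() {
  cached_fixture("trio_del", function() {
    dir <- file.path(tempdir(), "svcurate_trio_fix")
    sv <- sv_call("chrS", 40000, 42000, "DEL")
    spec <- simulation_spec(sv, depth = 30, seed = 11)
    tr <- simulate_trio(spec, dir, inheritance = "denovo")
    list(sv = sv, spec = spec, bams = tr$bams, truth = tr$truth,
         window = compute_window(sv), dir = dir)
  })
}

# small single-sample het-DEL fixture on a 12 kb contig
small_del_fixture <- function(seed = 5) {
  cached_fixture(paste0("small_del_", seed), function() {
    dir <- file.path(tempdir(), paste0("svcurate_small_", seed))
    dir.create(dir, showWarnings = FALSE)
    sv <- sv_call("chrS", 5000, 7000, "DEL")
    spec <- simulation_spec(sv, reference_length = 12000, depth = 30,
                            seed = seed)
    res <- simulate_sv_alignments(spec, file.path(dir, "s.bam"))
    list(sv = sv, spec = spec, bam = res$bam, truth = res$truth,
         window = genomic_window("chrS", 3500, 8500))
  })
}

# coerce all numeric-ish columns to double so implementation and oracle
# frames compare on values, not storage mode
norm_df <- function(d) {
  d[] <- lapply(d, function(col) if (is.numeric(col)) as.numeric(col)
                else col)
  rownames(d) <- NULL
  d
}

# ---- independent brute-force oracles -------------------------------------

# full-file scan (no window query) into a plain data frame
scan_all_records <- function(bam) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar",
             "mrnm", "mpos", "qwidth"),
    tag = c("SA", "MC"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  data.frame(qname = as.character(res$qname), flag = as.integer(res$flag),
             rname = as.character(res$rname),
             strand = as.character(res$strand),
             pos = as.integer(res$pos), cigar = as.character(res$cigar),
             mrnm = as.character(res$mrnm), mpos = as.integer(res$mpos),
             qwidth = as.integer(res$qwidth),
             SA = if (is.null(res$tag$SA)) NA_character_ else
               as.character(res$tag$SA),
             stringsAsFactors = FALSE)
}

# cigar reference width by direct token parsing (independent of the
# GenomicAlignments-based implementation path)
oracle_cigar_ref_width <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

oracle_lead_clip <- function(cigar, strand) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  if (strand == "-") { n <- rev(n); op <- rev(op) }
  k <- 0L
  for (j in seq_along(op)) {
    if (op[j] %in% c("S", "H")) k <- k + n[j] else break
  }
  k
}

# brute-force pair evidence: pair mates by qname from the full file scan
oracle_pair_evidence <- function(bam, window, stats) {
  rec <- scan_all_records(bam)
  primary <- bitwAnd(rec$flag, 256L + 2048L + 1024L + 512L + 4L) == 0L
  rec <- rec[primary & bitwAnd(rec$flag, 1L) > 0L &
               bitwAnd(rec$flag, 8L) == 0L, ]
  out <- list()
  for (qn in unique(rec$qname)) {
    mates <- rec[rec$qname == qn, ]
    if (nrow(mates) != 2) next
    if (any(mates$rname != window$chrom)) next
    st <- mates$pos - 1
    en <- st + vapply(mates$cigar, oracle_cigar_ref_width, integer(1))
    overlaps <- any(st < window$end & en > window$start)
    if (!overlaps) next
    o <- order(st, !bitwAnd(mates$flag, 64L) > 0L)
    span <- max(en) - st[o[1]]
    ls <- mates$strand[o[1]]; rs <- mates$strand[o[2]]
    cutoff <- stats$mean + stats$z * stats$sd
    cls <- if (ls == "+" && rs == "-") {
      if (span <= cutoff) "NORMAL" else "DELETION"
    } else if (ls == "-" && rs == "+") "DUPLICATION"
    else if (ls == "+") "INVERSION_FF" else "INVERSION_RR"
    out[[qn]] <- data.frame(qname = qn, left_start = st[o[1]],
                            left_end = en[o[1]], right_start = st[o[2]],
                            right_end = en[o[2]], left_strand = ls,
                            right_strand = rs, span = span, evclass = cls)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$left_start, res$qname), ]
  rownames(res) <- NULL
  res
}

# brute-force coverage: per-base tally over every record
oracle_coverage <- function(bam, window) {
  rec <- scan_all_records(bam)
  primary <- bitwAnd(rec$flag, 256L + 2048L + 1024L + 512L + 4L) == 0L
  rec <- rec[primary, ]
  w <- as.integer(window$end - window$start)
  depth <- integer(w)
  for (i in seq_len(nrow(rec))) {
    if (rec$rname[i] != window$chrom) next
    toks <- regmatches(rec$cigar[i],
                       gregexpr("[0-9]+[MIDNSHP=X]", rec$cigar[i]))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    ref <- rec$pos[i] - 1L  # 0-based cursor
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X")) {
        lo <- max(ref, window$start); hi <- min(ref + n[j], window$end)
        if (hi > lo) {
          idx <- (lo - window$start + 1L):(hi - window$start)
          depth[idx] <- depth[idx] + 1L
        }
        ref <- ref + n[j]
      } else if (op[j] %in% c("D", "N")) {
        ref <- ref + n[j]
      }
    }
  }
  depth
}

# brute-force split evidence from the full scan, parsing SA tags directly
oracle_split_evidence <- function(bam, window) {
  rec <- scan_all_records(bam)
  usable <- bitwAnd(rec$flag, 256L + 1024L + 512L + 4L) == 0L
  rec <- rec[usable & !is.na(rec$SA), ]
  keys <- unique(paste(rec$qname, bitwAnd(rec$flag, 64L)))
  out <- list()
  for (key in keys) {
    g <- rec[paste(rec$qname, bitwAnd(rec$flag, 64L)) == key, ]
    segs <- data.frame(rname = g$rname, pos = g$pos, strand = g$strand,
                       cigar = g$cigar, stringsAsFactors = FALSE)
    for (sa in g$SA) {
      for (ent in strsplit(sa, ";")[[1]]) {
        p <- strsplit(ent, ",")[[1]]
        if (length(p) == 6) {
          segs <- rbind(segs, data.frame(rname = p[1],
                                         pos = as.integer(p[2]),
                                         strand = p[3], cigar = p[4]))
        }
      }
    }
    segs <- segs[segs$rname == window$chrom, ]
    segs <- segs[!duplicated(paste(segs$pos, segs$strand, segs$cigar)), ]
    if (nrow(segs) < 2) next
    segs$start <- segs$pos - 1L
    segs$end <- segs$start +
      vapply(segs$cigar, oracle_cigar_ref_width, integer(1))
    segs$off <- mapply(oracle_lead_clip, segs$cigar, segs$strand)
    segs <- segs[order(segs$off, segs$start), ]
    for (k in seq_len(nrow(segs) - 1)) {
      a <- segs[k, ]; b <- segs[k + 1, ]
      left_first <- a$start <= b$start
      s1 <- if (left_first) a else b
      s2 <- if (left_first) b else a
      if (!(s1$start < window$end && max(s1$end, s2$end) > window$start)) {
        if (!(s2$start < window$end && s2$end > window$start)) next
      }
      flipped <- if (s1$strand == s2$strand) {
        xor(!left_first, s1$strand == "-")
      } else !left_first
      cls <- if (s1$strand != s2$strand) {
        if (s1$strand == "+") "INVERSION_FF" else "INVERSION_RR"
      } else if (flipped) "DUPLICATION" else "DELETION"
      out[[paste(key, k)]] <- data.frame(
        qname = g$qname[1], seg1_start = s1$start, seg1_end = s1$end,
        seg2_start = s2$start, seg2_end = s2$end,
        seg1_strand = s1$strand, seg2_strand = s2$strand,
        read_order_flipped = flipped,
        span = max(s1$end, s2$end) - s1$start, evclass = cls)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$seg1_start, res$qname), ]
  rownames(res) <- NULL
  res
}
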