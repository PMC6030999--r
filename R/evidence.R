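#' Structural variant calls and genomic windows
#'
#' `sv_call()` builds a one-row tibble describing a candidate structural
#' variant; `sv_calls()` validates a tibble of them. Coordinates are 0-based
#' half-open throughout the package (VCF positions are converted on read).
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval of the variant. For insertions
#'   `end` may equal `start + 1`.
#' @param svtype One of `"DEL"`, `"DUP"`, `"INV"`, `"INS"`.
#' @param id Record identifier; defaults to `"chrom_start_end_svtype"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `svtype`, `id`.
#' @export
#' @examples
#' sv_call("chrS", 40000, 42000, "DEL")
sv_call <- function(chrom, start, end, svtype, id = NULL) {
  svtype <- match.arg(svtype, SVTYPES)
  if (!nzchar(chrom)) abort("`chrom` must be non-empty")
  if (svtype == "INS") {
    if (end < start) abort("for INS, `end` must be >= `start`")
  } else if (start >= end) {
    abort("`start` must be < `end` for DEL/DUP/INV")
  }
  if (is.null(id)) id <- paste(chrom, start, end, svtype, sep = "_")
  tibble(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         svtype = svtype, id = id)
}

#' @rdname sv_call
#' @param x A data frame with at least `chrom`, `start`, `end`, `svtype`.
#' @export
sv_calls <- function(x) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end", "svtype")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$svtype %in% SVTYPES)) abort("unknown svtype")
  if (!"id" %in% names(x) || anyNA(x$id)) {
    x$id <- paste(x$chrom, x$start, x$end, x$svtype, sep = "_")
  }
  x
}

#' Genomic window around a position
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds; `start >= 0`, `end > start`.
#' @return A list of class `genomic_window`.
#' @export
genomic_window <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 0) abort("window start must be >= 0")
  if (end <= start) abort("window end must be > start")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_window")
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("<genomic_window> %s:%s-%s (%d bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              as.integer(x$end - x$start)))
  invisible(x)
}

width.genomic_window <- function(x) as.integer(x$end - x$start)

# ---- low-level BAM access ------------------------------------------------

bam_flags <- function(include_supplementary = FALSE) {
  # skip unmapped, secondary, duplicate and QC-fail records everywhere
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE
  )
  if (!include_supplementary) {
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isDuplicate = FALSE,
      isNotPassingQualityControls = FALSE
    )
  }
  flag
}

check_bam_indexed <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path)
  if (!file.exists(bai) && !file.exists(bai2)) {
    abort(paste0("missing index (.bai) for: ", path))
  }
  invisible(path)
}

# scan one window into a tibble of alignment records (0-based half-open)
scan_window <- function(path, window, include_supplementary = FALSE,
                        tags = c("SA", "MC")) {
  check_bam_indexed(path)
  gr <- GenomicRanges::GRanges(window$chrom,
                               IRanges::IRanges(window$start + 1, window$end))
  param <- Rsamtools::ScanBamParam(
    flag = bam_flags(include_supplementary),
    what = c("qname", "flag", "rname", "strand", "pos", "cigar",
             "mrnm", "mpos", "isize", "qwidth"),
    tag = tags,
    which = gr
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  records_to_tibble(res, tags)
}

records_to_tibble <- function(res, tags = character()) {
  n <- length(res$qname)
  out <- tibble(
    qname = as.character(res$qname),
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    strand = as.character(res$strand),
    pos = as.integer(res$pos),
    cigar = as.character(res$cigar),
    mrnm = as.character(res$mrnm),
    mpos = as.integer(res$mpos),
    isize = as.integer(res$isize),
    qwidth = as.integer(res$qwidth)
  )
  for (tg in tags) {
    v <- res$tag[[tg]]
    out[[tg]] <- if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  if (n > 0) {
    out$start <- out$pos - 1
    out$end <- out$start +
      GenomicAlignments::cigarWidthAlongReferenceSpace(out$cigar)
    out$mate_strand <- if_else(bitwAnd(out$flag, 32L) > 0L, "-", "+")
    out$supplementary <- bitwAnd(out$flag, 2048L) > 0L
    out$first_in_pair <- bitwAnd(out$flag, 64L) > 0L
    out$paired <- bitwAnd(out$flag, 1L) > 0L
    out$mate_unmapped <- bitwAnd(out$flag, 8L) > 0L
    out$proper <- bitwAnd(out$flag, 2L) > 0L
  } else {
    out$start <- numeric(0); out$end <- numeric(0)
    out$mate_strand <- character(0); out$supplementary <- logical(0)
    out$first_in_pair <- logical(0); out$paired <- logical(0)
    out$mate_unmapped <- logical(0); out$proper <- logical(0)
  }
  out
}

# ---- insert-size statistics ----------------------------------------------

#' Estimate the insert-size distribution of a library
#'
#' Samples up to `max_sampled` properly paired, primary, non-duplicate read
#' pairs in +/- orientation from the start of the file and returns the mean
#' and population standard deviation of the outer span (rightmost mapped end
#' minus leftmost mapped start). The outer span, rather than the TLEN field,
#' is used so paired and split observations share one y-axis when plotted.
#'
#' @param path Path to a coordinate-sorted BAM file.
#' @param max_sampled Maximum number of pairs to sample (default 10,000).
#' @param z Threshold multiplier stored with the stats (default 4): pairs in
#'   +/- orientation whose span exceeds `mean + z * sd` are treated as
#'   deletion-supporting.
#' @return A list of class `insert_stats` with elements `mean`, `sd`, `z`,
#'   `n`.
#' @export
estimate_insert_stats <- function(path, max_sampled = 10000, z = 4) {
  if (max_sampled < 1) abort("`max_sampled` must be >= 1")
  if (z <= 0) abort("`z` must be > 0")
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bf <- Rsamtools::BamFile(path, yieldSize = 50000L)
  open(bf)
  on.exit(close(bf))
  param <- Rsamtools::ScanBamParam(
    flag = bam_flags(include_supplementary = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "cigar",
             "mrnm", "mpos", "isize", "qwidth"),
    tag = "MC"
  )
  spans <- numeric(0)
  repeat {
    res <- Rsamtools::scanBam(bf, param = param)[[1]]
    if (length(res$qname) == 0) break
    rec <- records_to_tibble(res, tags = "MC")
    # leftmost mate of a +/- proper pair counts the pair exactly once
    rec <- filter(rec,
                  .data$proper, .data$paired, !.data$mate_unmapped,
                  .data$strand == "+", .data$mate_strand == "-",
                  !is.na(.data$mrnm), .data$mrnm == .data$rname,
                  .data$start <= .data$mpos - 1)
    if (nrow(rec) > 0) {
      mate_end <- mate_ref_end(rec)
      spans <- c(spans, mate_end - rec$start)
    }
    if (length(spans) >= max_sampled) break
  }
  if (length(spans) == 0) {
    abort("no qualifying proper +/- pairs found; cannot estimate insert stats")
  }
  spans <- head(spans, max_sampled)
  insert_stats(mean = mean(spans), sd = pop_sd(spans), z = z,
               n = length(spans))
}

#' @rdname estimate_insert_stats
#' @param mean,sd Outer-span mean and (population) standard deviation in bp.
#' @param n Number of pairs the estimate is based on.
#' @export
insert_stats <- function(mean, sd, z = 4, n = 1) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (z <= 0) abort("`z` must be > 0")
  if (n < 1) abort("`n` must be >= 1")
  structure(list(mean = mean, sd = sd, z = z, n = as.integer(n)),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf("<insert_stats> mean %.1f bp, sd %.2f bp (z = %g, n = %d)\n",
              x$mean, x$sd, x$z, x$n))
  invisible(x)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# mate reference end from the MC (mate CIGAR) tag; falls back to
# mate_pos + this read's query width when MC is absent
mate_ref_end <- function(rec) {
  mstart <- rec$mpos - 1
  has_mc <- !is.na(rec$MC)
  w <- rec$qwidth
  if (any(has_mc)) {
    w[has_mc] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$MC[has_mc])
  }
  mstart + w
}

# ---- classification ------------------------------------------------------

#' Classify paired-end observations by the SV type they support
#'
#' Orientation is considered first (strands in genomic order), then the span
#' threshold: `(+,-)` pairs with span at most `mean + z * sd` are `NORMAL`
#' and beyond it `DELETION`; everted `(-,+)` pairs are `DUPLICATION`;
#' `(+,+)` pairs are `INVERSION_FF` and `(-,-)` pairs `INVERSION_RR`. The
#' mapping is total: every strand/span combination receives exactly one
#' class. These are the standard discordant-pair conventions for Illumina
#' forward/reverse libraries.
#'
#' @param left_strand,right_strand Strands (`"+"`/`"-"`) of the genomically
#'   left and right mates.
#' @param span Outer distance between the mates' outermost mapped ends, bp.
#' @param stats An [insert_stats()] object.
#' @return Character vector of evidence classes.
#' @export
#' @examples
#' classify_pair("+", "-", 300, insert_stats(300, 50))   # NORMAL
#' classify_pair("+", "-", 5000, insert_stats(300, 50))  # DELETION
classify_pair <- function(left_strand, right_strand, span, stats) {
  cutoff <- stats$mean + stats$z * stats$sd
  dplyr::case_when(
    left_strand == "+" & right_strand == "-" & span <= cutoff ~ "NORMAL",
    left_strand == "+" & right_strand == "-" ~ "DELETION",
    left_strand == "-" & right_strand == "+" ~ "DUPLICATION",
    left_strand == "+" & right_strand == "+" ~ "INVERSION_FF",
    TRUE ~ "INVERSION_RR"
  )
}

#' Classify split-read observations by the SV type they support
#'
#' Segments are taken in genomic order. Opposite segment strands indicate an
#' inversion, sub-typed by the strand of the left segment (`+` to
#' `INVERSION_FF`, `-` to `INVERSION_RR`). Same-strand segments whose read
#' order is flipped (the genomically left segment comes later in the read)
#' indicate a tandem duplication; same-strand segments in read order
#' indicate a deletion.
#'
#' @param seg1_strand,seg2_strand Strands of the genomically left and right
#'   segments.
#' @param read_order_flipped Logical; `TRUE` when the genomically left
#'   segment comes later in the read.
#' @return Character vector of evidence classes.
#' @export
classify_split <- function(seg1_strand, seg2_strand, read_order_flipped) {
  dplyr::case_when(
    seg1_strand != seg2_strand & seg1_strand == "+" ~ "INVERSION_FF",
    seg1_strand != seg2_strand ~ "INVERSION_RR",
    read_order_flipped ~ "DUPLICATION",
    TRUE ~ "DELETION"
  )
}

# ---- pair evidence -------------------------------------------------------

#' Extract classified paired-end evidence for a window
#'
#' Returns one row per read pair with at least one primary alignment
#' overlapping the window and both mates mapped to the window's chromosome.
#' Mates are stored in genomic order; the span is the outer distance
#' (rightmost end minus leftmost start). Unpaired reads, mate-unmapped reads
#' and inter-chromosomal pairs are skipped. Each pair is classified with
#' [classify_pair()].
#'
#' @param path Indexed BAM file.
#' @param window A [genomic_window()].
#' @param stats An [insert_stats()] object.
#' @return A tibble with columns `qname`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `left_strand`, `right_strand`, `span`,
#'   `evclass`.
#' @export
extract_pair_evidence <- function(path, window, stats) {
  rec <- scan_window(path, window, include_supplementary = FALSE)
  rec <- filter(rec, .data$paired, !.data$mate_unmapped,
                !is.na(.data$mrnm), .data$mrnm == .data$rname)
  if (nrow(rec) == 0) return(empty_pair_tibble())
  mate_start <- rec$mpos - 1
  mate_end <- mate_ref_end(rec)
  own_left <- rec$start < mate_start |
    (rec$start == mate_start & rec$first_in_pair)
  out <- tibble(
    qname = rec$qname,
    left_start = if_else(own_left, rec$start, mate_start),
    left_end = if_else(own_left, rec$end, mate_end),
    right_start = if_else(own_left, mate_start, rec$start),
    right_end = if_else(own_left, mate_end, rec$end),
    left_strand = if_else(own_left, rec$strand, rec$mate_strand),
    right_strand = if_else(own_left, rec$mate_strand, rec$strand)
  )
  # both mates inside the window produce two records for the same pair
  out <- distinct(out, .data$qname, .keep_all = TRUE)
  out$span <- pmax(out$right_end, out$left_end) - out$left_start
  out$evclass <- classify_pair(out$left_strand, out$right_strand,
                               out$span, stats)
  arrange(out, .data$left_start, .data$qname)
}

empty_pair_tibble <- function() {
  tibble(qname = character(0), left_start = numeric(0), left_end = numeric(0),
         right_start = numeric(0), right_end = numeric(0),
         left_strand = character(0), right_strand = character(0),
         span = numeric(0), evclass = character(0))
}

# ---- split evidence ------------------------------------------------------

parse_sa_tag <- function(sa) {
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  parts <- strsplit(entries, ",", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 6L
  if (!all(ok)) {
    warn(paste0("malformed SA tag entry skipped: ", sa))
    parts <- parts[ok]
  }
  if (length(parts) == 0) return(NULL)
  tibble(
    rname = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    strand = vapply(parts, `[[`, "", 3L),
    cigar = vapply(parts, `[[`, "", 4L)
  )
}

# offset of the first aligned base within the original read, from the
# clipping structure: leading clip for + alignments, trailing clip for -
read_offset_from_cigar <- function(cigar, strand) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    clip <- o %in% c("S", "H")
    if (strand[i] == "+") {
      k <- 0L
      for (j in seq_along(o)) { if (clip[j]) k <- k + l[j] else break }
    } else {
      k <- 0L
      for (j in rev(seq_along(o))) { if (clip[j]) k <- k + l[j] else break }
    }
    as.integer(k)
  }, integer(1))
}

#' Extract classified split-read evidence for a window
#'
#' Discovers split alignments through the standard supplementary-alignment
#' tag (`SA:Z:rname,pos,strand,CIGAR,mapQ,NM;...`). For each split read the
#' full segment set is reconstructed, ordered by position within the read
#' (derived from the soft/hard-clip structure), and adjacent segment pairs
#' are emitted, each classified with [classify_split()]. A read seen from
#' both its primary and supplementary records is emitted once.
#' Inter-chromosomal segments are excluded.
#'
#' @inheritParams extract_pair_evidence
#' @return A tibble with columns `qname`, `seg1_start`, `seg1_end`,
#'   `seg2_start`, `seg2_end`, `seg1_strand`, `seg2_strand`,
#'   `read_order_flipped`, `span`, `evclass`.
#' @export
extract_split_evidence <- function(path, window) {
  rec <- scan_window(path, window, include_supplementary = TRUE)
  rec <- filter(rec, !is.na(.data$SA))
  if (nrow(rec) == 0) return(empty_split_tibble())
  rec$mate <- if_else(rec$first_in_pair, "R1", "R2")
  groups <- split(rec, paste(rec$qname, rec$mate))
  out <- purrr::map(groups, function(g) {
    segs <- tibble(rname = g$rname, pos = g$pos, strand = g$strand,
                   cigar = g$cigar)
    for (i in seq_len(nrow(g))) {
      sa <- parse_sa_tag(g$SA[i])
      if (!is.null(sa)) segs <- bind_rows(segs, sa)
    }
    segs <- filter(segs, .data$rname == window$chrom)
    segs <- distinct(segs, .data$pos, .data$strand, .data$cigar,
                     .keep_all = TRUE)
    if (nrow(segs) < 2) return(NULL)
    segs$start <- segs$pos - 1
    segs$end <- segs$start +
      GenomicAlignments::cigarWidthAlongReferenceSpace(segs$cigar)
    segs$read_offset <- read_offset_from_cigar(segs$cigar, segs$strand)
    segs <- arrange(segs, .data$read_offset, .data$start)
    purrr::map(seq_len(nrow(segs) - 1L), function(k) {
      a <- segs[k, ]; b <- segs[k + 1L, ]
      left_first <- a$start <= b$start
      s1 <- if (left_first) a else b
      s2 <- if (left_first) b else a
      # flipped when segment order along the read disagrees with genomic
      # order after accounting for read orientation: a reverse-strand read
      # traverses the genome right-to-left, so its natural order is reversed
      flipped <- if (s1$strand == s2$strand) {
        xor(!left_first, s1$strand == "-")
      } else {
        !left_first
      }
      tibble(
        qname = g$qname[1],
        seg1_start = s1$start, seg1_end = s1$end,
        seg2_start = s2$start, seg2_end = s2$end,
        seg1_strand = s1$strand, seg2_strand = s2$strand,
        read_order_flipped = flipped,
        span = max(s2$end, s1$end) - s1$start
      )
    })
  })
  out <- bind_rows(purrr::flatten(out))
  if (nrow(out) == 0) return(empty_split_tibble())
  # keep pairs with at least one segment overlapping the window
  out <- filter(out,
                (.data$seg1_start < window$end & .data$seg1_end > window$start) |
                (.data$seg2_start < window$end & .data$seg2_end > window$start))
  if (nrow(out) == 0) return(empty_split_tibble())
  out$evclass <- classify_split(out$seg1_strand, out$seg2_strand,
                                out$read_order_flipped)
  arrange(out, .data$seg1_start, .data$qname)
}

empty_split_tibble <- function() {
  tibble(qname = character(0), seg1_start = numeric(0), seg1_end = numeric(0),
         seg2_start = numeric(0), seg2_end = numeric(0),
         seg1_strand = character(0), seg2_strand = character(0),
         read_order_flipped = logical(0), span = numeric(0),
         evclass = character(0))
}

# ---- coverage ------------------------------------------------------------

#' Per-base coverage over a window
#'
#' Counts primary, non-duplicate aligned bases per position: bases the read
#' actually aligns (CIGAR `M`/`=`/`X`); deletions within a read's reference
#' span and soft-clipped bases do not count. Supplementary records are
#' excluded (they are used only for split detection).
#'
#' @inheritParams extract_pair_evidence
#' @return A tibble with columns `pos` (0-based) and `depth`, one row per
#'   window base.
#' @export
compute_coverage <- function(path, window) {
  w <- width.genomic_window(window)
  rec <- scan_window(path, window, include_supplementary = FALSE,
                     tags = character())
  if (nrow(rec) == 0) {
    return(tibble(pos = seq(window$start, window$end - 1), depth = 0L))
  }
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos, ops = c("M", "=", "X"))
  ir <- unlist(blocks, use.names = FALSE)
  ir <- IRanges::shift(ir, -as.integer(window$start))
  ir <- IRanges::restrict(ir, start = 1L, end = w)
  depth <- as.integer(IRanges::coverage(ir, width = w))
  tibble(pos = seq(window$start, window$end - 1), depth = depth)
}

# ---- downsampling --------------------------------------------------------

#' Downsample concordant pairs for plotting
#'
#' All pairs supporting an SV (class other than `NORMAL`) are retained. If
#' the number of `NORMAL` pairs exceeds `max_normals`, a uniform random
#' subset of exactly `max_normals` of them is kept, reproducibly for a fixed
#' seed. Relative row order is preserved.
#'
#' @param pairs A classified pair-evidence tibble.
#' @param max_normals Maximum number of `NORMAL` pairs to keep per window
#'   (default 100).
#' @param seed Integer seed for the uniform subset.
#' @return The downsampled tibble.
#' @export
downsample_normal_pairs <- function(pairs, max_normals = 100, seed = 1) {
  if (max_normals < 0) abort("`max_normals` must be >= 0")
  is_norm <- pairs$evclass == "NORMAL"
  n_norm <- sum(is_norm)
  if (n_norm <= max_normals) return(pairs)
  keep_idx <- withr::with_seed(seed,
    sample(which(is_norm), size = max_normals, replace = FALSE))
  keep <- !is_norm
  keep[keep_idx] <- TRUE
  pairs[keep, , drop = FALSE]
}

# ---- sample tracks -------------------------------------------------------

#' Gather all evidence for one sample over one window
#'
#' Composes the per-sample extraction: insert-size stats are estimated once
#' per file, pairs are extracted, classified and downsampled, split reads
#' extracted, and coverage computed.
#'
#' @inheritParams extract_pair_evidence
#' @param z Threshold multiplier for the deletion span cutoff (default 4).
#' @param max_normals Concordant-pair cap per window (default 100).
#' @param seed Seed for the downsampling subset.
#' @param sample_name Label for the sample; defaults to the file name.
#' @param max_sampled Pairs sampled for insert-stats estimation.
#' @param stats Optional precomputed [insert_stats()]; when supplied,
#'   estimation is skipped.
#' @return A list of class `sample_tracks` with elements `sample_name`,
#'   `window`, `pairs`, `splits`, `coverage`, `insert_stats`.
#' @export
gather_sample_evidence <- function(path, window, z = 4, max_normals = 100,
                                   seed = 1, sample_name = NULL,
                                   max_sampled = 10000, stats = NULL) {
  if (is.null(sample_name)) {
    sample_name <- sub("\\.(bam|cram)$", "", basename(path))
  }
  if (is.null(stats)) {
    stats <- estimate_insert_stats(path, max_sampled = max_sampled, z = z)
  } else {
    stats$z <- z
  }
  pairs <- extract_pair_evidence(path, window, stats)
  pairs <- downsample_normal_pairs(pairs, max_normals = max_normals,
                                   seed = seed)
  splits <- extract_split_evidence(path, window)
  coverage <- compute_coverage(path, window)
  structure(
    list(sample_name = sample_name, window = window, pairs = pairs,
         splits = splits, coverage = coverage, insert_stats = stats),
    class = "sample_tracks"
  )
}

#' @export
print.sample_tracks <- function(x, ...) {
  cat(sprintf(
    "<sample_tracks> %s @ %s:%d-%d: %d pairs (%d discordant), %d splits, mean depth %.1f\n",
    x$sample_name, x$window$chrom, as.integer(x$window$start),
    as.integer(x$window$end), nrow(x$pairs),
    sum(x$pairs$evclass != "NORMAL"), nrow(x$splits),
    mean(x$coverage$depth)))
  invisible(x)
}

#' Tidy evidence observations into one table
#'
#' Returns the per-window evidence dump: one row per pair or split
#' observation with a common column layout (`sample`, `kind`, `class`,
#' `left_start`, `left_end`, `right_start`, `right_end`, `strands`, `span`).
#'
#' @param x A `sample_tracks` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sample_tracks <- function(x, ...) {
  p <- x$pairs
  s <- x$splits
  pt <- tibble(sample = x$sample_name, kind = "pair", class = p$evclass,
               left_start = p$left_start, left_end = p$left_end,
               right_start = p$right_start, right_end = p$right_end,
               strands = paste0(p$left_strand, p$right_strand),
               span = p$span)
  st <- tibble(sample = x$sample_name, kind = "split", class = s$evclass,
               left_start = s$seg1_start, left_end = s$seg1_end,
               right_start = s$seg2_start, right_end = s$seg2_end,
               strands = paste0(s$seg1_strand, s$seg2_strand),
               span = s$span)
  bind_rows(pt, st)
}

#' One-row summary of a sample's evidence
#'
#' @param x A `sample_tracks` object.
#' @param ... Unused.
#' @return A one-row tibble with evidence counts, the modal discordant
#'   class, and mean depth.
#' @export
glance.sample_tracks <- function(x, ...) {
  disc <- x$pairs$evclass[x$pairs$evclass != "NORMAL"]
  modal <- if (length(disc) == 0) NA_character_ else {
    tab <- sort(table(disc), decreasing = TRUE)
    names(tab)[1]
  }
  tibble(sample = x$sample_name,
         n_pairs = nrow(x$pairs),
         n_discordant = length(disc),
         n_splits = nrow(x$splits),
         modal_discordant_class = modal,
         mean_depth = mean(x$coverage$depth))
}

#' Write the per-window evidence dump as TSV
#'
#' @param tracks A `sample_tracks` object or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(tracks, path) {
  if (inherits(tracks, "sample_tracks")) tracks <- list(tracks)
  tab <- bind_rows(purrr::map(tracks, tidy.sample_tracks))
  readr::write_tsv(tab, path)
  invisible(path)
}
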