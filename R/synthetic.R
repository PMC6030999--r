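#' Specify a synthetic alignment simulation
#'
#' Describes the study conditions for the synthetic trio generator: a set of
#' structural variants (one per synthetic contig), sequencing depth, read
#' length, and the insert-size distribution of the emulated library. Reads
#' are placed on the SV-carrying haplotype and mapped back to reference
#' coordinates, so haplotypes carrying a variant emit pairs whose spans and
#' orientations encode it (DEL: +/- with span inflated by the SV length;
#' DUP: everted -/+ across the duplication junction; INV: same-strand pairs
#' across each breakpoint), breakpoint-spanning reads become split
#' (primary + supplementary, SA-tagged) records at rate
#' `split_read_fraction`, and coverage over the variant dips or rises
#' according to genotype.
#'
#' @param svs An [sv_calls()] tibble; each variant lives on its own
#'   synthetic contig. Defaults to a single 2 kb deletion on `"chrS"`.
#' @param reference_length Length of each synthetic contig in bp.
#' @param depth Fold sequencing coverage per sample.
#' @param read_length Read length in bp; must be less than `insert_mean`.
#' @param insert_mean,insert_sd Mean and sd of the library insert (outer
#'   span) distribution in bp; draws are truncated at `read_length`.
#' @param split_read_fraction Fraction of breakpoint-spanning reads emitted
#'   as split alignments (the rest are soft-clipped on one side).
#' @param seed Integer seed; the generator is fully deterministic for a
#'   fixed spec and seed.
#' @return A list of class `simulation_spec`.
#' @export
#' @examples
#' spec <- simulation_spec(sv_call("chrS", 40000, 42000, "DEL"), depth = 30)
simulation_spec <- function(svs = sv_call("chrS", 40000, 42000, "DEL"),
                            reference_length = 100000,
                            depth = 30,
                            read_length = 100,
                            insert_mean = 400,
                            insert_sd = 50,
                            split_read_fraction = 0.5,
                            seed = 1) {
  svs <- sv_calls(svs)
  if (depth <= 0) abort("`depth` must be > 0")
  if (read_length >= insert_mean) {
    abort("`read_length` must be < `insert_mean`")
  }
  if (split_read_fraction < 0 || split_read_fraction > 1) {
    abort("`split_read_fraction` must be in [0, 1]")
  }
  if (anyDuplicated(svs$chrom)) {
    abort("each simulated SV must live on its own contig")
  }
  if (any(svs$svtype == "INS")) {
    abort("insertion signatures are not simulated; use DEL, DUP or INV")
  }
  if (any(svs$start < 0 | svs$end > reference_length)) {
    abort("SV outside the reference contig")
  }
  if (any(svs$end - svs$start >= reference_length / 2)) {
    abort("SV too large relative to the reference contig")
  }
  structure(
    list(svs = svs, reference_length = reference_length, depth = depth,
         read_length = as.integer(read_length), insert_mean = insert_mean,
         insert_sd = insert_sd, split_read_fraction = split_read_fraction,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %d SV(s), %g kb contigs, %gx, %d bp reads, insert %g+/-%g, seed %d\n",
    nrow(x$svs), x$reference_length / 1000, x$depth, x$read_length,
    x$insert_mean, x$insert_sd, x$seed))
  invisible(x)
}

# ---- haplotype coordinate map --------------------------------------------

# Piecewise-linear map from alternate-haplotype coordinates to reference
# coordinates. Regions are half-open [alt_lo, alt_hi); non-flipped regions
# map x -> x + off, flipped (inversion interior) regions map x -> mir - x.
hap_regions <- function(ref_len, sv = NULL) {
  if (is.null(sv)) {
    return(tibble(alt_lo = 0, alt_hi = ref_len, flip = FALSE, off = 0,
                  mir = NA_real_))
  }
  s <- sv$start; e <- sv$end; L <- e - s
  switch(sv$svtype,
    DEL = tibble(alt_lo = c(0, s), alt_hi = c(s, ref_len - L),
                 flip = FALSE, off = c(0, L), mir = NA_real_),
    DUP = tibble(alt_lo = c(0, e, e + L), alt_hi = c(e, e + L, ref_len + L),
                 flip = FALSE, off = c(0, s - e, -L), mir = NA_real_),
    INV = tibble(alt_lo = c(0, s, e), alt_hi = c(s, e, ref_len),
                 flip = c(FALSE, TRUE, FALSE), off = c(0, NA, 0),
                 mir = c(NA, s + e - 1, NA)),
    abort(paste0("unsupported svtype: ", sv$svtype))
  )
}

alt_length <- function(ref_len, sv = NULL) {
  if (is.null(sv)) return(ref_len)
  L <- sv$end - sv$start
  switch(sv$svtype, DEL = ref_len - L, DUP = ref_len + L, INV = ref_len)
}

# map one alt-space read interval [a, b) through the region table; returns
# a data frame of reference segments with read offsets in alt + direction
map_read_slow <- function(a, b, regions) {
  cuts <- regions$alt_lo[regions$alt_lo > a & regions$alt_lo < b]
  bounds <- c(a, cuts, b)
  segs <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    p <- bounds[k]; q <- bounds[k + 1L]
    r <- findInterval(p, regions$alt_lo)
    if (regions$flip[r]) {
      segs[[k]] <- list(ref_start = regions$mir[r] - q + 1,
                        ref_end = regions$mir[r] - p + 1,
                        flip = TRUE, read_from = p - a, read_to = q - a)
    } else {
      segs[[k]] <- list(ref_start = p + regions$off[r],
                        ref_end = q + regions$off[r],
                        flip = FALSE, read_from = p - a, read_to = q - a)
    }
  }
  # merge pieces that are reference-contiguous with the same orientation
  # (a tandem-duplication copy boundary is not a real junction)
  merged <- list(segs[[1]])
  for (k in seq_along(segs)[-1]) {
    last <- merged[[length(merged)]]
    cur <- segs[[k]]
    if (!last$flip && !cur$flip && cur$ref_start == last$ref_end) {
      last$ref_end <- cur$ref_end
      last$read_to <- cur$read_to
      merged[[length(merged)]] <- last
    } else if (last$flip && cur$flip && cur$ref_end == last$ref_start) {
      last$ref_start <- cur$ref_start
      last$read_to <- cur$read_to
      merged[[length(merged)]] <- last
    } else {
      merged <- c(merged, list(cur))
    }
  }
  do.call(rbind.data.frame, merged)
}

# ---- per-contig read placement -------------------------------------------

# simulate one haplotype of one contig: returns a segment table with one row
# per aligned segment of every read
sim_hap_segments <- function(contig, ref_len, sv, frag_prefix, n_frag, rl,
                             imean, isd) {
  if (n_frag == 0) return(NULL)
  regions <- hap_regions(ref_len, sv)
  alt_len <- alt_length(ref_len, sv)
  isize <- pmax(round(rnorm(n_frag, imean, isd)), rl)
  isize <- pmin(isize, alt_len)
  f <- floor(runif(n_frag, 0, alt_len - isize + 1))
  reads <- tibble(
    frag = rep(paste0(frag_prefix, seq_len(n_frag)), 2L),
    mate = rep(c(1L, 2L), each = n_frag),
    alt_strand = rep(c("+", "-"), each = n_frag),
    a = c(f, f + isize - rl),
    b = c(f + rl, f + isize)
  )
  ra <- findInterval(reads$a, regions$alt_lo)
  rb <- findInterval(reads$b - 1, regions$alt_lo)
  fast <- ra == rb
  seg_fast <- NULL
  if (any(fast)) {
    r <- ra[fast]
    fl <- regions$flip[r]
    seg_fast <- tibble(
      frag = reads$frag[fast], mate = reads$mate[fast],
      alt_strand = reads$alt_strand[fast],
      ref_start = if_else(fl, regions$mir[r] - reads$b[fast] + 1,
                          reads$a[fast] + regions$off[r]),
      ref_end = if_else(fl, regions$mir[r] - reads$a[fast] + 1,
                        reads$b[fast] + regions$off[r]),
      flip = fl, read_from = 0, read_to = as.numeric(rl)
    )
  }
  seg_slow <- NULL
  if (any(!fast)) {
    idx <- which(!fast)
    seg_slow <- purrr::map(idx, function(i) {
      m <- map_read_slow(reads$a[i], reads$b[i], regions)
      tibble(frag = reads$frag[i], mate = reads$mate[i],
             alt_strand = reads$alt_strand[i],
             ref_start = m$ref_start, ref_end = m$ref_end, flip = m$flip,
             read_from = m$read_from, read_to = m$read_to)
    })
    seg_slow <- bind_rows(seg_slow)
  }
  segs <- bind_rows(seg_fast, seg_slow)
  segs$contig <- contig
  # reference-space strand: alt + reads keep orientation unless the segment
  # fell in a flipped (inversion) region
  segs$strand <- if_else(xor(segs$alt_strand == "-", segs$flip), "-", "+")
  # offsets within the sequenced read (alt - reads are reverse-complemented)
  segs$seq_from <- if_else(segs$alt_strand == "+", segs$read_from,
                           rl - segs$read_to)
  segs$seq_to <- if_else(segs$alt_strand == "+", segs$read_to,
                         rl - segs$read_from)
  segs
}

make_cigar <- function(lead, match, trail) {
  paste0(if_else(lead > 0, paste0(lead, "S"), ""),
         match, "M",
         if_else(trail > 0, paste0(trail, "S"), ""))
}

# turn a segment table into SAM-ready records for one sample
segments_to_records <- function(segs, rl, imean, isd, split_read_fraction) {
  segs <- mutate(segs, read_id = paste0(.data$frag, "/", .data$mate),
                 seg_len = .data$ref_end - .data$ref_start)
  n_by_read <- dplyr::count(segs, .data$read_id, name = "n_segs")
  segs <- left_join(segs, n_by_read, by = "read_id")

  multi <- unique(segs$read_id[segs$n_segs > 1])
  is_split <- setNames(runif(length(multi)) < split_read_fraction, multi)

  segs <- group_by(segs, .data$read_id)
  segs <- mutate(segs, primary = dplyr::row_number(
    dplyr::desc(.data$seg_len)) == 1L)
  segs <- ungroup(segs)

  read_is_split <- unname(is_split[segs$read_id])
  read_is_split[is.na(read_is_split)] <- FALSE
  # breakpoint-spanning reads not emitted as splits keep only the longer
  # (primary) segment, soft-clipped at the junction
  segs$split <- segs$n_segs > 1 & read_is_split
  segs <- segs[!(segs$n_segs > 1 & !segs$primary & !read_is_split), ]

  # CIGAR: SAM clips are read left-to-right in reference orientation
  lead <- ifelse(segs$strand == "+", segs$seq_from, rl - segs$seq_to)
  trail <- ifelse(segs$strand == "+", rl - segs$seq_to, segs$seq_from)
  segs$cigar <- make_cigar(as.integer(lead), as.integer(segs$seg_len),
                           as.integer(trail))
  segs$pos <- as.integer(segs$ref_start + 1)

  # SA tags cross-reference the other segments of a split read
  sa <- rep(NA_character_, nrow(segs))
  if (any(segs$split)) {
    split_ids <- unique(segs$read_id[segs$split])
    for (id in split_ids) {
      idx <- which(segs$read_id == id)
      ent <- sprintf("%s,%d,%s,%s,60,0;", segs$contig[idx], segs$pos[idx],
                     segs$strand[idx], segs$cigar[idx])
      for (j in seq_along(idx)) {
        sa[idx[j]] <- paste0(ent[-j], collapse = "")
      }
    }
  }
  segs$SA <- sa

  # mate linkage uses each read's primary record
  prim <- filter(segs, .data$primary)
  prim <- mutate(prim, key = paste0(.data$frag, "/", 3L - .data$mate))
  mate_info <- select(prim, key = "key", mate_pos = "pos",
                      mate_strand = "strand", mate_cigar = "cigar",
                      mate_end = "ref_end", mate_start = "ref_start",
                      mate_nsegs = "n_segs")
  segs <- left_join(segs, mate_info,
                    by = c("read_id" = "key"))

  # proper pair: both mates single-segment, +/- in genomic order, span
  # within the concordant envelope
  left_start <- pmin(segs$ref_start, segs$mate_start)
  outer_span <- pmax(segs$ref_end, segs$mate_end) - left_start
  own_left <- segs$ref_start < segs$mate_start |
    (segs$ref_start == segs$mate_start & segs$mate == 1L)
  lstr <- if_else(own_left, segs$strand, segs$mate_strand)
  rstr <- if_else(own_left, segs$mate_strand, segs$strand)
  segs$proper <- segs$n_segs == 1L & segs$mate_nsegs == 1L &
    lstr == "+" & rstr == "-" & outer_span <= imean + 4 * isd
  segs$tlen <- as.integer(if_else(segs$n_segs == 1L & segs$mate_nsegs == 1L,
    if_else(own_left, outer_span, -outer_span), 0))

  segs$flagv <- 1L +
    if_else(segs$proper, 2L, 0L) +
    if_else(segs$strand == "-", 16L, 0L) +
    if_else(segs$mate_strand == "-", 32L, 0L) +
    if_else(segs$mate == 1L, 64L, 128L) +
    if_else(!segs$primary, 2048L, 0L)
  segs
}

# evidence class a pair encodes, from the two primary records (generator
# truth, using the spec's own insert distribution and z = 4)
pair_truth_class <- function(prim, imean, isd) {
  p1 <- filter(prim, .data$mate == 1L)
  p2 <- filter(prim, .data$mate == 2L)
  stopifnot(nrow(p1) == nrow(p2))
  p2 <- p2[match(p1$frag, p2$frag), ]
  own_left <- p1$ref_start < p2$ref_start |
    (p1$ref_start == p2$ref_start)
  ls <- if_else(own_left, p1$ref_start, p2$ref_start)
  re <- pmax(p1$ref_end, p2$ref_end)
  lstr <- if_else(own_left, p1$strand, p2$strand)
  rstr <- if_else(own_left, p2$strand, p1$strand)
  classify_pair(lstr, rstr, re - ls,
                insert_stats(imean, isd, z = 4, n = 1))
}

expected_cov_ratio <- function(svtype, genotype) {
  if (genotype == "ref") return(1.0)
  switch(svtype,
    DEL = if (genotype == "het") 0.5 else 0.0,
    DUP = if (genotype == "het") 1.5 else 2.0,
    INV = 1.0)
}

# simulate all contigs for one sample; returns records + truth rows
sim_sample <- function(spec, genotypes, sample_name, seed) {
  rl <- spec$read_length
  withr::with_seed(seed, {
    all_recs <- vector("list", nrow(spec$svs))
    truth <- vector("list", nrow(spec$svs))
    for (i in seq_len(nrow(spec$svs))) {
      sv <- spec$svs[i, ]
      gt <- genotypes[i]
      segs <- vector("list", 2L)
      for (hap in 1:2) {
        carries <- (hap == 1L && gt %in% c("het", "hom")) ||
          (hap == 2L && gt == "hom")
        hap_sv <- if (carries) sv else NULL
        alt_len <- alt_length(spec$reference_length, hap_sv)
        n_frag <- round((spec$depth / 2) * alt_len / (2 * rl))
        segs[[hap]] <- sim_hap_segments(
          sv$chrom, spec$reference_length, hap_sv,
          frag_prefix = sprintf("%s_h%d_", sv$chrom, hap),
          n_frag = n_frag, rl = rl,
          imean = spec$insert_mean, isd = spec$insert_sd)
      }
      segs <- bind_rows(segs)
      recs <- segments_to_records(segs, rl, spec$insert_mean, spec$insert_sd,
                                  spec$split_read_fraction)
      prim <- filter(recs, .data$primary)
      cls <- pair_truth_class(prim, spec$insert_mean, spec$insert_sd)
      truth[[i]] <- tibble(
        sample = sample_name, chrom = sv$chrom, sv_id = sv$id,
        svtype = sv$svtype, genotype = gt,
        n_support_pairs = sum(cls != "NORMAL"),
        n_support_splits = length(unique(recs$read_id[recs$split])),
        expected_cov_ratio = expected_cov_ratio(sv$svtype, gt)
      )
      all_recs[[i]] <- recs
    }
    list(records = bind_rows(all_recs), truth = bind_rows(truth))
  })
}

records_to_sam <- function(recs, contigs, ref_len, rl) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs, as.integer(ref_len)))
  recs <- recs[order(match(recs$contig, contigs), recs$pos, recs$read_id), ]
  seq <- strrep("A", rl)
  qual <- strrep("I", rl)
  tags <- paste0("MC:Z:", recs$mate_cigar)
  has_sa <- !is.na(recs$SA)
  tags[has_sa] <- paste0(tags[has_sa], "\tSA:Z:", recs$SA[has_sa])
  body <- paste(sub("/[12]$", "", recs$read_id), recs$flagv,
                recs$contig, recs$pos, 60L, recs$cigar, "=",
                recs$mate_pos, recs$tlen, seq, qual, tags, sep = "\t")
  c(header, body)
}

write_indexed_bam <- function(sam_lines, out_bam) {
  sam_path <- sub("\\.bam$", ".sam", out_bam)
  if (identical(sam_path, out_bam)) sam_path <- paste0(out_bam, ".sam")
  writeLines(sam_lines, sam_path)
  dest <- sub("\\.bam$", "", out_bam)
  bam <- Rsamtools::asBam(sam_path, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam_path)
  bam
}

#' Simulate one sample's alignments with planted SV signatures
#'
#' Writes a coordinate-sorted, indexed BAM covering one synthetic contig per
#' variant in the spec, together with a truth table recording the number of
#' SV-supporting pairs and split reads actually planted and the expected
#' coverage ratio over the variant (DEL het about 0.5, DEL hom about 0, DUP
#' het about 1.5, INV about 1.0). Fully deterministic for a fixed spec and
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @param out_bam Output BAM path.
#' @param genotypes Genotype per variant, each of `"ref"`, `"het"`,
#'   `"hom"`; recycled across variants.
#' @param sample_name Sample label recorded in the truth table.
#' @return A list with elements `bam` (path) and `truth` (tibble).
#' @export
simulate_sv_alignments <- function(spec, out_bam, genotypes = "het",
                                   sample_name = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(sample_name)) {
    sample_name <- sub("\\.bam$", "", basename(out_bam))
  }
  genotypes <- rep_len(genotypes, nrow(spec$svs))
  if (!all(genotypes %in% c("ref", "het", "hom"))) {
    abort("genotypes must be 'ref', 'het' or 'hom'")
  }
  sim <- sim_sample(spec, genotypes, sample_name, seed = spec$seed)
  sam <- records_to_sam(sim$records, spec$svs$chrom, spec$reference_length,
                        spec$read_length)
  bam <- write_indexed_bam(sam, out_bam)
  list(bam = bam, truth = sim$truth)
}

#' Simulate a trio with a chosen inheritance pattern
#'
#' The child carries every variant with genotype `child_genotype`; parents
#' carry them according to `inheritance`: `"denovo"` leaves both parents
#' reference, `"paternal"`/`"maternal"` make that parent heterozygous, and
#' `"biparental"` makes both parents heterozygous. Each sample gets its own
#' deterministic seed derived from the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Directory for the three BAMs (`child.bam`, `father.bam`,
#'   `mother.bam`).
#' @param inheritance One of `"denovo"`, `"paternal"`, `"maternal"`,
#'   `"biparental"`; recycled across variants.
#' @param child_genotype Child genotype per variant; recycled.
#' @return A list with `bams` (named paths) and `truth` (tibble over all
#'   three samples).
#' @export
simulate_trio <- function(spec, out_dir,
                          inheritance = "denovo",
                          child_genotype = "het") {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(spec$svs)
  inheritance <- rep_len(inheritance, n)
  ok <- inheritance %in% c("denovo", "paternal", "maternal", "biparental")
  if (!all(ok)) abort("unknown inheritance pattern")
  child_gt <- rep_len(child_genotype, n)
  father_gt <- if_else(inheritance %in% c("paternal", "biparental"),
                       "het", "ref")
  mother_gt <- if_else(inheritance %in% c("maternal", "biparental"),
                       "het", "ref")
  members <- list(child = child_gt, father = father_gt, mother = mother_gt)
  bams <- character(0)
  truth <- list()
  for (k in seq_along(members)) {
    nm <- names(members)[k]
    mspec <- spec
    mspec$seed <- spec$seed + 1000L * k
    res <- simulate_sv_alignments(mspec, file.path(out_dir,
                                                   paste0(nm, ".bam")),
                                  genotypes = members[[k]],
                                  sample_name = nm)
    bams[nm] <- res$bam
    truth[[nm]] <- res$truth
  }
  list(bams = bams, truth = bind_rows(truth))
}

#' Simulate reviewer responses with a known error rate
#'
#' Each reviewer answers each image with its true label with probability
#' `1 - error_rate`, otherwise with a uniformly random wrong label from the
#' answer set. Deterministic for a fixed seed.
#'
#' @param truth Named character vector mapping image id to its true answer
#'   label.
#' @param answers The full ordered answer set (must contain every truth
#'   label).
#' @param n_reviewers Number of simulated reviewers.
#' @param error_rate Per-answer error probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A response tibble with columns `image_id`, `reviewer`, `answer`,
#'   `timestamp`, `elapsed_seconds`.
#' @export
simulate_reviewer_responses <- function(truth, answers, n_reviewers = 9,
                                        error_rate = 0.05, seed = 1) {
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must be in [0, 0.5)")
  }
  if (!all(truth %in% answers)) abort("truth labels must be valid answers")
  ids <- names(truth)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(reviewer = paste0("reviewer", seq_len(n_reviewers)),
                               image_id = ids)
    true_ans <- truth[grid$image_id]
    err <- runif(nrow(grid)) < error_rate
    wrong <- purrr::map_chr(true_ans, function(a) {
      pool <- setdiff(answers, a)
      pool[sample.int(length(pool), 1L)]
    })
    grid$answer <- if_else(err, wrong, unname(true_ans))
    grid$timestamp <- format(
      as.POSIXct("2026-01-01 00:00:00", tz = "UTC") + seq_len(nrow(grid)),
      "%Y-%m-%dT%H:%M:%SZ")
    grid$elapsed_seconds <- round(runif(nrow(grid), 1, 6), 2)
    select(grid, "image_id", "reviewer", "answer", "timestamp",
           "elapsed_seconds")
  })
}
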