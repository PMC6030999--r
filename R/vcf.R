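#' Read structural variant calls from a VCF
#'
#' Extracts one row per record with 0-based half-open coordinates
#' (`start = POS - 1`, `end = INFO/END`) and the SV type from `INFO/SVTYPE`.
#' Records with a missing `END` (e.g. insertions) get `end = start + 1`.
#' The image id is the VCF `ID` when present, otherwise
#' `"chrom_start_end_svtype"` — the same derivation used when images are
#' named, so curation responses can be joined back to records.
#'
#' @param path VCF file (plain or bgzipped).
#' @return An [sv_calls()] tibble with an extra `pos` column (1-based VCF
#'   POS).
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records")
  svtype <- vcfR::extract.info(v, "SVTYPE")
  end <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  pos <- as.numeric(fix$POS)
  start <- pos - 1
  end[is.na(end)] <- start[is.na(end)] + 1
  if (anyNA(svtype)) abort("every record needs INFO/SVTYPE")
  if (!all(svtype %in% SVTYPES)) {
    abort(paste0("unsupported SVTYPE: ",
                 paste(setdiff(unique(svtype), SVTYPES), collapse = ", ")))
  }
  id <- fix$ID
  synth <- is.na(id) | id == "."
  id[synth] <- paste(fix$CHROM[synth], start[synth], end[synth],
                     svtype[synth], sep = "_")
  tibble(chrom = fix$CHROM, start = start, end = end, svtype = svtype,
         id = id, pos = pos)
}

#' Write SV calls as a minimal VCF
#'
#' @param svs An [sv_calls()] tibble.
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, contig_lengths = NULL) {
  svs <- sv_calls(svs)
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">')
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\t.\tSVTYPE=%s;END=%d",
                  svs$chrom, as.integer(svs$start + 1), svs$id, svs$svtype,
                  svs$svtype, as.integer(svs$end))
  writeLines(c(header, body), path)
  invisible(path)
}

# id-derivation rule shared with read_sv_vcf, applied to raw VCF lines
vcf_line_image_id <- function(fields) {
  id <- fields[3]
  if (!is.na(id) && id != ".") return(id)
  info <- fields[8]
  info_field <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  svtype <- info_field("SVTYPE")
  start <- as.numeric(fields[2]) - 1
  end <- suppressWarnings(as.numeric(info_field("END")))
  if (is.na(end)) end <- start + 1
  paste(fields[1], start, end, svtype, sep = "_")
}

#' Annotate a VCF with curation scores
#'
#' Adds one `##INFO` header line declaring the tag and, for every record
#' whose derived image id has a score, appends `TAG=score` (rounded to 4
#' decimals) to the INFO column. Records with no score and all other file
#' content are byte-preserved, so [strip_vcf_scores()] restores the input
#' exactly.
#'
#' @param input Input VCF path (uncompressed text).
#' @param scores A [curation_scores()] tibble, or any tibble with
#'   `image_id` and `score` columns.
#' @param output Output VCF path.
#' @param tag INFO tag name (default `"SVP"`).
#' @return `output`, invisibly.
#' @export
annotate_vcf_with_scores <- function(input, scores, output, tag = "SVP") {
  lines <- readLines(input)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !any(grepl("^#CHROM", lines))) {
    abort("malformed VCF: missing #CHROM header line")
  }
  chrom_line <- grep("^#CHROM", lines)[1]
  info_hdr <- sprintf(
    '##INFO=<ID=%s,Number=1,Type=Float,Description="Curation score aggregated over reviewer responses">',
    tag)
  score_by_id <- setNames(scores$score, scores$image_id)
  body_idx <- setdiff(seq_along(lines), grep("^#", lines))
  for (i in body_idx) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8) abort("malformed VCF record (fewer than 8 fields)")
    id <- vcf_line_image_id(fields)
    sc <- score_by_id[[id]]
    if (is.null(sc) || is.na(sc)) next
    tag_str <- sprintf("%s=%.4f", tag, sc)
    fields[8] <- if (fields[8] == "." || fields[8] == "") tag_str else
      paste0(fields[8], ";", tag_str)
    lines[i] <- paste(fields, collapse = "\t")
  }
  lines <- append(lines, info_hdr, after = chrom_line - 1L)
  writeLines(lines, output)
  invisible(output)
}

#' Remove a score tag from a VCF
#'
#' Inverse of [annotate_vcf_with_scores()]: drops the tag's `##INFO` header
#' line and every `TAG=` entry from record INFO columns.
#'
#' @param input Annotated VCF path.
#' @param output Output VCF path.
#' @param tag INFO tag name (default `"SVP"`).
#' @return `output`, invisibly.
#' @export
strip_vcf_scores <- function(input, output, tag = "SVP") {
  lines <- readLines(input)
  lines <- lines[!grepl(sprintf("^##INFO=<ID=%s,", tag), lines)]
  is_body <- !grepl("^#", lines)
  pat_mid <- sprintf(";%s=[^;\t]*", tag)
  pat_only <- sprintf("%s=[^;\t]*", tag)
  fix_info <- function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    info <- fields[8]
    info <- gsub(pat_mid, "", info)
    if (grepl(paste0("^", pat_only, "$"), info)) info <- "."
    info <- sub(paste0("^", pat_only, ";"), "", info)
    fields[8] <- info
    paste(fields, collapse = "\t")
  }
  lines[is_body] <- vapply(lines[is_body], fix_info, "", USE.NAMES = FALSE)
  writeLines(lines, output)
  invisible(output)
}
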