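#' Curation project configuration
#'
#' A curation project poses one question per image with a fixed, ordered
#' answer set; each answer may carry a single-character keyboard binding for
#' fast scoring. Answer labels and key bindings must be unique and at least
#' two answers are required.
#'
#' @param project Project name.
#' @param question Question text posed for every image.
#' @param answers Ordered character vector of answer labels (>= 2).
#' @param keys Optional character vector of single-character key bindings,
#'   one per answer.
#' @param reviewers Optional character vector of reviewer identifiers.
#' @return A list of class `curation_config`.
#' @export
#' @examples
#' trio_config()
curation_config <- function(project, question, answers, keys = NULL,
                            reviewers = character()) {
  if (length(answers) < 2) abort("config error: need >= 2 answers")
  if (anyDuplicated(answers)) abort("config error: duplicate answers")
  if (!is.null(keys)) {
    if (length(keys) != length(answers)) {
      abort("config error: keys must match answers one-to-one")
    }
    if (anyDuplicated(keys)) abort("config error: duplicate keys")
    if (any(nchar(keys) != 1)) {
      abort("config error: keys must be single characters")
    }
  }
  structure(list(project = project, question = question,
                 answers = as.character(answers), keys = keys,
                 reviewers = reviewers),
            class = "curation_config")
}

#' @export
print.curation_config <- function(x, ...) {
  cat(sprintf("<curation_config> %s\n  Q: %s\n  A: %s\n", x$project,
              x$question, paste(x$answers, collapse = " / ")))
  invisible(x)
}

#' @rdname curation_config
#' @export
trio_config <- function() {
  curation_config(
    project = "trio",
    question = "The SV in the top sample is:",
    answers = c("GOOD", "BAD", "DE NOVO"),
    keys = c("g", "b", "d")
  )
}

#' @rdname curation_config
#' @export
cancer_config <- function() {
  curation_config(
    project = "cancer",
    question = "In which samples does the SV appear?",
    answers = c("TUMOR", "BOTH", "NORMAL", "NEITHER"),
    keys = c("t", "b", "n", "x")
  )
}

#' Read a curation config from JSON
#'
#' Expects the schema `{"project": str, "curationQandA": {"question": str,
#' "answers": [str], "keys": [str]}}`.
#'
#' @param path Path to a JSON file.
#' @return A [curation_config()].
#' @export
load_curation_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$project)) abort("config error: missing field 'project'")
  qa <- cfg$curationQandA
  if (is.null(qa)) abort("config error: missing field 'curationQandA'")
  if (is.null(qa$question)) abort("config error: missing field 'question'")
  if (is.null(qa$answers)) abort("config error: missing field 'answers'")
  curation_config(project = cfg$project, question = qa$question,
                  answers = qa$answers, keys = qa$keys,
                  reviewers = cfg$reviewers %||% character())
}

#' Write a curation config as JSON
#'
#' @param config A [curation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_config <- function(config, path) {
  jsonlite::write_json(
    list(project = config$project,
         curationQandA = list(question = config$question,
                              answers = config$answers,
                              keys = config$keys %||% character()),
         reviewers = config$reviewers),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- project store -------------------------------------------------------

#' Create a local curation project store
#'
#' The store holds the config, the image roster (one row per SV image, from
#' the render manifest or an SV table), and the response log. It replaces a
#' hosted database with a single local JSON file; see
#' [save_curation_store()].
#'
#' @param config A [curation_config()].
#' @param images A tibble with columns `image_id`, `chrom`, `start`, `end`,
#'   `svtype` (a render manifest or [sv_calls()] table; an `id` column is
#'   accepted as `image_id`).
#' @return A list of class `curation_store`.
#' @export
curation_project <- function(config, images) {
  stopifnot(inherits(config, "curation_config"))
  images <- as_tibble(images)
  if (!"image_id" %in% names(images) && "id" %in% names(images)) {
    images <- rename(images, image_id = "id")
  }
  req <- c("image_id", "chrom", "start", "end", "svtype")
  missing_cols <- setdiff(req, names(images))
  if (length(missing_cols) > 0) {
    abort(paste0("images table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(images$image_id)) abort("duplicate image ids")
  structure(
    list(config = config, images = select(images, dplyr::all_of(req)),
         responses = empty_response_tibble()),
    class = "curation_store"
  )
}

empty_response_tibble <- function() {
  tibble(image_id = character(0), reviewer = character(0),
         answer = character(0), timestamp = character(0),
         elapsed_seconds = numeric(0))
}

#' @export
print.curation_store <- function(x, ...) {
  latest <- latest_responses(x)
  cat(sprintf(
    "<curation_store> project '%s': %d images, %d responses (%d reviewers)\n",
    x$config$project, nrow(x$images), nrow(latest),
    dplyr::n_distinct(latest$reviewer)))
  invisible(x)
}

#' Record one reviewer response
#'
#' Appends a response to the project log. A reviewer may re-score an image;
#' the latest response per (image, reviewer) supersedes earlier ones when
#' scores are computed.
#'
#' @param store A [curation_project()] store.
#' @param image_id Image identifier; must be in the store's roster.
#' @param reviewer Reviewer identifier.
#' @param answer One of the config's answer labels.
#' @param timestamp Response time (ISO 8601 string); defaults to now.
#' @param elapsed_seconds Seconds from image display to answer.
#' @return The updated store.
#' @export
record_response <- function(store, image_id, reviewer, answer,
                            timestamp = NULL, elapsed_seconds = 0) {
  stopifnot(inherits(store, "curation_store"))
  if (!image_id %in% store$images$image_id) {
    abort(paste0("unknown image_id: ", image_id))
  }
  if (!answer %in% store$config$answers) {
    abort(paste0("invalid answer '", answer, "'; allowed: ",
                 paste(store$config$answers, collapse = ", ")))
  }
  if (elapsed_seconds < 0) abort("`elapsed_seconds` must be >= 0")
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  store$responses <- bind_rows(
    store$responses,
    tibble(image_id = image_id, reviewer = reviewer, answer = answer,
           timestamp = timestamp,
           elapsed_seconds = as.numeric(elapsed_seconds)))
  store
}

#' Import a batch of responses from a TSV or tibble
#'
#' Rows with an unknown image id or an answer outside the config's answer
#' set are rejected with a warning; accepted rows are appended to the log.
#' The rejected rows are attached as the `"rejected"` attribute of the
#' returned store.
#'
#' @param store A [curation_project()] store.
#' @param responses A tibble or TSV path with columns `image_id`,
#'   `reviewer`, `answer` and optionally `timestamp`, `elapsed_seconds`.
#' @return The updated store, with attribute `"rejected"`.
#' @export
import_responses <- function(store, responses) {
  stopifnot(inherits(store, "curation_store"))
  if (is.character(responses)) {
    responses <- readr::read_tsv(responses, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   image_id = "c", reviewer = "c",
                                   answer = "c", .default = "?"))
  }
  responses <- as_tibble(responses)
  if (!"timestamp" %in% names(responses)) responses$timestamp <- NA_character_
  if (!"elapsed_seconds" %in% names(responses)) responses$elapsed_seconds <- 0
  responses$timestamp <- as.character(responses$timestamp)
  responses$elapsed_seconds <- as.numeric(responses$elapsed_seconds)
  bad <- !(responses$answer %in% store$config$answers) |
    !(responses$image_id %in% store$images$image_id)
  rejected <- responses[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    warn(sprintf("%d response row(s) rejected (unknown image or answer)",
                 nrow(rejected)))
  }
  keep <- responses[!bad, , drop = FALSE]
  store$responses <- bind_rows(
    store$responses,
    select(keep, "image_id", "reviewer", "answer", "timestamp",
           "elapsed_seconds"))
  attr(store, "rejected") <- rejected
  store
}

#' Latest response per (image, reviewer)
#'
#' @param store A [curation_project()] store.
#' @return A response tibble with at most one row per (image, reviewer).
#' @export
latest_responses <- function(store) {
  r <- store$responses
  if (nrow(r) == 0) return(r)
  r$.ord <- seq_len(nrow(r))
  r <- group_by(r, .data$image_id, .data$reviewer)
  r <- slice(r, dplyr::n())
  r <- ungroup(r)
  r <- arrange(r, .data$.ord)
  select(r, -".ord")
}

#' Save or load a curation store as a single JSON file
#'
#' @param store A [curation_project()] store.
#' @param path JSON file path.
#' @return `save_curation_store()` returns `path` invisibly;
#'   `load_curation_store()` returns the store.
#' @export
save_curation_store <- function(store, path) {
  jsonlite::write_json(
    list(config = list(project = store$config$project,
                       curationQandA = list(
                         question = store$config$question,
                         answers = store$config$answers,
                         keys = store$config$keys %||% character()),
                       reviewers = store$config$reviewers),
         images = store$images,
         responses = store$responses),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_curation_store
#' @export
load_curation_store <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- curation_config(project = x$config$project,
                         question = x$config$curationQandA$question,
                         answers = x$config$curationQandA$answers,
                         keys = if (length(x$config$curationQandA$keys) > 0)
                           x$config$curationQandA$keys else NULL,
                         reviewers = x$config$reviewers %||% character())
  store <- curation_project(cfg, as_tibble(x$images))
  if (length(x$responses) > 0 && NROW(x$responses) > 0) {
    resp <- as_tibble(x$responses)
    resp$elapsed_seconds <- as.numeric(resp$elapsed_seconds)
    store$responses <- resp
  }
  store
}

# ---- scoring -------------------------------------------------------------

#' Define a curation score function
#'
#' A score function maps each answer label to a numeric value and reduces a
#' set of responses with an aggregation function. The default reproduces
#' the standard trio scoring: `GOOD` and `DE NOVO` map to 1 (both assert a
#' real variant in the sample of interest), `BAD` to 0, aggregated by the
#' mean.
#'
#' @param values Named numeric vector mapping answer label to value.
#' @param aggregation One of `"mean"`, `"median"`, `"mode"`, `"sd"`,
#'   `"min"`, `"max"`. Mode ties break toward the larger value; `sd` is the
#'   population standard deviation.
#' @return A list of class `score_mapping`.
#' @export
#' @examples
#' score_mapping(c(GOOD = 1, "DE NOVO" = 1, BAD = 0), "mean")
score_mapping <- function(values = c(GOOD = 1, "DE NOVO" = 1, BAD = 0),
                          aggregation = c("mean", "median", "mode", "sd",
                                          "min", "max")) {
  aggregation <- match.arg(aggregation)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    abort("`values` must be a fully named numeric vector")
  }
  structure(list(values = values, aggregation = aggregation),
            class = "score_mapping")
}

#' Aggregate reviewer answers into a curation score
#'
#' @param answers Character vector of answer labels (non-empty; all must be
#'   mapped by `mapping`).
#' @param mapping A [score_mapping()].
#' @return The aggregated numeric score.
#' @export
#' @examples
#' aggregate_curation_score(rep("GOOD", 9), score_mapping())
aggregate_curation_score <- function(answers, mapping = score_mapping()) {
  if (length(answers) == 0) abort("cannot score an empty response set")
  unmapped <- setdiff(unique(answers), names(mapping$values))
  if (length(unmapped) > 0) {
    abort(paste0("unmapped answer(s): ", paste(unmapped, collapse = ", ")))
  }
  v <- unname(mapping$values[answers])
  switch(mapping$aggregation,
    mean = mean(v),
    median = median(v),
    min = min(v),
    max = max(v),
    sd = pop_sd(v),
    mode = {
      tab <- table(v)
      best <- as.numeric(names(tab)[tab == max(tab)])
      max(best)  # ties break toward the larger value
    })
}

SCORE_CLASSES <- c("UNANIMOUS_HIGH", "UNANIMOUS_LOW", "UNAMBIGUOUS_HIGH",
                   "UNAMBIGUOUS_LOW", "AMBIGUOUS")

#' Qualitative class of a curation score
#'
#' Defined for scores under the 0/1 mean mapping: exactly 1 is
#' `UNANIMOUS_HIGH` and exactly 0 `UNANIMOUS_LOW`; otherwise scores above
#' 0.8 are `UNAMBIGUOUS_HIGH` and below 0.2 `UNAMBIGUOUS_LOW` (at most one
#' dissenting vote among nine reviewers), and scores in `[0.2, 0.8]`
#' (bounds included) are `AMBIGUOUS`. The five classes partition `[0, 1]`.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @return Character vector of score classes.
#' @export
#' @examples
#' classify_curation_score(c(1, 8 / 9, 0.5, 0))
classify_curation_score <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    abort("scores must lie in [0, 1]")
  }
  dplyr::case_when(
    score == 1 ~ "UNANIMOUS_HIGH",
    score == 0 ~ "UNANIMOUS_LOW",
    score > 0.8 ~ "UNAMBIGUOUS_HIGH",
    score < 0.2 ~ "UNAMBIGUOUS_LOW",
    TRUE ~ "AMBIGUOUS"
  )
}

is_binary_mean_mapping <- function(mapping) {
  mapping$aggregation == "mean" && all(mapping$values %in% c(0, 1))
}

#' Per-image curation scores
#'
#' Computes, for every image in the roster, the latest-response answer
#' counts, the aggregated score and (for the 0/1 mean mapping) its
#' qualitative class. Images with no responses are kept with `NA` score.
#'
#' @param store A [curation_project()] store.
#' @param mapping A [score_mapping()].
#' @return A tibble with one row per image: `image_id`, `chrom`, `start`,
#'   `end`, `svtype`, `n_responses`, one `count_<answer>` column per
#'   answer, `score`, `score_class`, ordered by (chrom, start).
#' @export
curation_scores <- function(store, mapping = score_mapping()) {
  stopifnot(inherits(store, "curation_store"))
  latest <- latest_responses(store)
  counts <- count(latest, .data$image_id, .data$answer)
  counts$answer <- factor(counts$answer, levels = store$config$answers)
  wide <- tidyr::pivot_wider(counts, names_from = "answer",
                             values_from = "n", values_fill = 0L,
                             names_prefix = "count_", names_expand = TRUE)
  out <- left_join(store$images, wide, by = "image_id")
  cnt_cols <- paste0("count_", store$config$answers)
  for (cc in cnt_cols) {
    if (!cc %in% names(out)) out[[cc]] <- 0L
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  out <- select(out, dplyr::all_of(c("image_id", "chrom", "start", "end",
                                     "svtype", cnt_cols)))
  out$n_responses <- as.integer(rowSums(out[cnt_cols]))
  by_img <- split(latest$answer, latest$image_id)
  out$score <- purrr::map_dbl(out$image_id, function(id) {
    a <- by_img[[id]]
    if (is.null(a) || length(a) == 0) return(NA_real_)
    aggregate_curation_score(a, mapping)
  })
  out$score_class <- NA_character_
  if (is_binary_mean_mapping(mapping)) {
    has <- !is.na(out$score)
    out$score_class[has] <- classify_curation_score(out$score[has])
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write the tab-delimited curation report
#'
#' One row per image with its coordinates, the number of times it was
#' scored, the full set of answer counts, the curation score and its class.
#' Images never scored appear with an empty score field.
#'
#' @param store A [curation_project()] store.
#' @param mapping A [score_mapping()].
#' @param path Optional output TSV path.
#' @return The report tibble (invisibly if `path` is given).
#' @export
generate_report <- function(store, mapping = score_mapping(), path = NULL) {
  report <- curation_scores(store, mapping)
  if (!is.null(path)) {
    out <- report
    out$score <- ifelse(is.na(out$score), "",
                        format(out$score, digits = 15, trim = TRUE))
    readr::write_tsv(out, path, na = "")
    return(invisible(report))
  }
  report
}

# ---- summaries -----------------------------------------------------------

#' Summarize a curated call set
#'
#' After dropping excluded images (for example, images that failed to
#' render) and images with no responses, reports the fraction of variants
#' scored unanimously high/low, unanimously overall, unambiguously (score
#' below 0.2 or above 0.8) and ambiguously, the median SV length for the
#' all/unanimous/unambiguous/ambiguous strata, and counts per SV type.
#' Scores must come from a 0/1 mean mapping.
#'
#' @param scores A [curation_scores()] tibble (needs `image_id`, `score`,
#'   and `svtype`/`start`/`end` columns).
#' @param exclusions Character vector of image ids to exclude.
#' @return A list of class `curation_summary`.
#' @export
summarize_curation <- function(scores, exclusions = character()) {
  s <- filter(scores, !.data$image_id %in% exclusions, !is.na(.data$score))
  if (nrow(s) == 0) abort("no scored images left after exclusion")
  if (any(s$score < 0 | s$score > 1)) {
    abort("summaries are defined for scores in [0, 1] (0/1 mean mapping)")
  }
  cls <- classify_curation_score(s$score)
  size <- s$end - s$start
  n <- nrow(s)
  med <- function(idx) if (any(idx)) median(size[idx]) else NA_real_
  structure(list(
    n_scored = n,
    n_excluded = length(intersect(exclusions, scores$image_id)),
    n_unscored = sum(is.na(scores$score) &
                       !scores$image_id %in% exclusions),
    frac_unanimous_high = mean(cls == "UNANIMOUS_HIGH"),
    frac_unanimous_low = mean(cls == "UNANIMOUS_LOW"),
    frac_unanimous = mean(cls %in% c("UNANIMOUS_HIGH", "UNANIMOUS_LOW")),
    frac_unambiguous = mean(s$score < 0.2 | s$score > 0.8),
    frac_ambiguous = mean(s$score >= 0.2 & s$score <= 0.8),
    median_size_all = med(rep(TRUE, n)),
    median_size_unanimous = med(cls %in% c("UNANIMOUS_HIGH",
                                           "UNANIMOUS_LOW")),
    median_size_unambiguous = med(s$score < 0.2 | s$score > 0.8),
    median_size_ambiguous = med(s$score >= 0.2 & s$score <= 0.8),
    svtype_counts = table(s$svtype)
  ), class = "curation_summary")
}

#' @export
print.curation_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<curation_summary> %d scored (%d excluded, %d unscored)\n",
           "  unanimous %.1f%% (high %.1f%%, low %.1f%%); ",
           "unambiguous %.1f%%; ambiguous %.1f%%\n",
           "  median size: all %s bp, ambiguous %s bp\n"),
    x$n_scored, x$n_excluded, x$n_unscored,
    100 * x$frac_unanimous, 100 * x$frac_unanimous_high,
    100 * x$frac_unanimous_low, 100 * x$frac_unambiguous,
    100 * x$frac_ambiguous,
    format(x$median_size_all), format(x$median_size_ambiguous)))
  invisible(x)
}

#' @export
tidy.curation_summary <- function(x, ...) {
  tibble(
    stratum = c("all", "unanimous", "unambiguous", "ambiguous"),
    fraction = c(1, x$frac_unanimous, x$frac_unambiguous, x$frac_ambiguous),
    median_size = c(x$median_size_all, x$median_size_unanimous,
                    x$median_size_unambiguous, x$median_size_ambiguous))
}

#' @export
glance.curation_summary <- function(x, ...) {
  tibble(n_scored = x$n_scored, n_excluded = x$n_excluded,
         n_unscored = x$n_unscored,
         frac_unanimous = x$frac_unanimous,
         frac_unanimous_high = x$frac_unanimous_high,
         frac_unanimous_low = x$frac_unanimous_low,
         frac_unambiguous = x$frac_unambiguous,
         frac_ambiguous = x$frac_ambiguous)
}

# ---- concordance ---------------------------------------------------------

#' Read orthogonal genotype/copy-number calls from TSV
#'
#' Expects columns `image_id`, `genotype` (one of `hom_ref`, `het`,
#' `hom_alt`, `missing`) and `copy_number` (non-negative or empty).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_orthogonal_calls <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(image_id = "c",
                                               genotype = "c",
                                               copy_number = "d"))
  bad <- setdiff(unique(x$genotype), c("hom_ref", "het", "hom_alt",
                                       "missing", NA))
  if (length(bad) > 0) {
    abort(paste0("unknown genotype value(s): ", paste(bad, collapse = ", ")))
  }
  x
}

#' Concordance of curation scores with orthogonal callers
#'
#' Compares unambiguously scored deletions (score below 0.2 or above 0.8,
#' 0/1 mean mapping) against an orthogonal genotype call and a read-depth
#' copy-number estimate. A low score agrees with a homozygous-reference
#' genotype or a copy-neutral estimate (copy number inside `cn_band`); a
#' high score agrees with a non-reference genotype or a copy number below
#' the band. Copy numbers above the band never count as deletion support
#' and are treated as disagreement with a high score. Missing calls are
#' excluded from the denominators.
#'
#' @param scores A [curation_scores()] tibble.
#' @param calls A tibble with columns `image_id`, `genotype` (one of
#'   `hom_ref`, `het`, `hom_alt`, `missing`) and `copy_number` (non-negative
#'   or `NA`).
#' @param cn_band Copy-neutral band, default `c(1.4, 2.4)` (exclusive
#'   lower, inclusive upper).
#' @return A list of class `sv_concordance`: per-method agreement fractions
#'   and eligible counts, plus a breakdown tibble of agreement by method and
#'   score side.
#' @export
concordance_with_orthogonal <- function(scores, calls,
                                        cn_band = c(1.4, 2.4)) {
  calls <- as_tibble(calls)
  s <- filter(scores, .data$svtype == "DEL", !is.na(.data$score),
              .data$score < 0.2 | .data$score > 0.8)
  s <- left_join(s, calls, by = "image_id")
  if (nrow(s) == 0) abort("no unambiguous deletions to compare")
  s$side <- if_else(s$score > 0.8, "high", "low")

  gt <- filter(s, !is.na(.data$genotype), .data$genotype != "missing")
  gt$agree <- (gt$side == "low" & gt$genotype == "hom_ref") |
    (gt$side == "high" & gt$genotype %in% c("het", "hom_alt"))

  cn <- filter(s, !is.na(.data$copy_number))
  neutral <- cn$copy_number > cn_band[1] & cn$copy_number <= cn_band[2]
  loss <- cn$copy_number < cn_band[1]
  cn$agree <- (cn$side == "low" & neutral) | (cn$side == "high" & loss)

  if (nrow(gt) == 0 && nrow(cn) == 0) {
    abort("no orthogonal calls available for the eligible deletions")
  }
  breakdown <- bind_rows(
    mutate(count(gt, .data$side, .data$agree), method = "genotype"),
    mutate(count(cn, .data$side, .data$agree), method = "copy_number"))
  breakdown <- select(breakdown, "method", "side", "agree", "n")
  structure(list(
    genotype_agreement = if (nrow(gt) > 0) mean(gt$agree) else NA_real_,
    cn_agreement = if (nrow(cn) > 0) mean(cn$agree) else NA_real_,
    n_genotype = nrow(gt),
    n_copy_number = nrow(cn),
    breakdown = breakdown
  ), class = "sv_concordance")
}

#' @export
print.sv_concordance <- function(x, ...) {
  cat(sprintf(
    "<sv_concordance> genotype agreement %.1f%% (n=%d); copy-number agreement %.1f%% (n=%d)\n",
    100 * x$genotype_agreement, x$n_genotype,
    100 * x$cn_agreement, x$n_copy_number))
  invisible(x)
}

#' @export
tidy.sv_concordance <- function(x, ...) x$breakdown

#' @export
glance.sv_concordance <- function(x, ...) {
  tibble(genotype_agreement = x$genotype_agreement,
         cn_agreement = x$cn_agreement,
         n_genotype = x$n_genotype, n_copy_number = x$n_copy_number)
}
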