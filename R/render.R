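#' Plotting window around an SV
#'
#' Pads the variant interval on both sides by
#' `max(min_pad, round(pad_fraction * sv_length))`, clamped at zero.
#'
#' @param sv A one-row [sv_call()] tibble.
#' @param pad_fraction Pad as a fraction of the SV length (default 0.5).
#' @param min_pad Minimum pad in bp (default 1,000).
#' @return A [genomic_window()].
#' @export
#' @examples
#' compute_window(sv_call("chr1", 1000, 2000, "DEL"), 0.5, 100)
compute_window <- function(sv, pad_fraction = 0.5, min_pad = 1000) {
  if (pad_fraction < 0) abort("`pad_fraction` must be >= 0")
  if (min_pad < 0) abort("`min_pad` must be >= 0")
  pad <- max(min_pad, round(pad_fraction * (sv$end - sv$start)))
  genomic_window(sv$chrom, max(0, sv$start - pad), sv$end + pad)
}

#' Load gene/annotation intervals intersecting a window
#'
#' Reads a BED (0-based half-open) or GFF3 (1-based inclusive, converted)
#' annotation file and returns the intervals intersecting the window, with
#' `gene` and `exon` kinds distinguished for GFF3 and `region` used for
#' BED.
#'
#' @param path Annotation file; format chosen by extension
#'   (`.bed`/`.gff`/`.gff3`, optionally `.gz`).
#' @param window A [genomic_window()].
#' @return A tibble with columns `start`, `end`, `label`, `kind`, sorted by
#'   start; attribute `"source"` carries the file name.
#' @export
load_gene_annotations <- function(path, window) {
  base <- sub("\\.(gz|bgz)$", "", path)
  ext <- tolower(tools::file_ext(base))
  gr_win <- GenomicRanges::GRanges(
    window$chrom, IRanges::IRanges(window$start + 1, window$end))
  if (ext == "bed") {
    g <- rtracklayer::import(path, format = "bed", which = gr_win)
    kind <- rep("region", length(g))
    label <- if (!is.null(g$name)) as.character(g$name) else
      rep(NA_character_, length(g))
  } else if (ext %in% c("gff", "gff3")) {
    g <- rtracklayer::import(path, format = "gff3", which = gr_win)
    type <- as.character(g$type)
    keep <- type %in% c("gene", "exon")
    g <- g[keep]
    kind <- type[keep]
    nm <- g$Name
    if (is.null(nm)) nm <- g$ID
    label <- as.character(nm)
  } else {
    abort(paste0("unknown annotation format: .", ext,
                 " (expected .bed or .gff3)"))
  }
  out <- tibble(
    start = GenomicRanges::start(g) - 1,
    end = as.numeric(GenomicRanges::end(g)),
    label = label,
    kind = kind
  )
  out <- arrange(filter(out, .data$end > window$start,
                        .data$start < window$end), .data$start)
  attr(out, "source") <- basename(path)
  out
}

# ---- figure construction -------------------------------------------------

# alpha per glyph, proportional to how crowded its span/position
# neighborhood is: dense stacks of concordant pairs fade individually while
# isolated discordant glyphs stay opaque
density_alpha <- function(x, y, xrange, yrange, nbins = 24) {
  if (length(x) == 0) return(numeric(0))
  bx <- pmin(nbins, 1L + floor(nbins * (x - xrange[1]) /
                                 max(1, diff(xrange))))
  by <- pmin(nbins, 1L + floor(nbins * y / max(1, yrange[2])))
  key <- paste(bx, by)
  dens <- table(key)[key]
  pmax(0.15, pmin(1, 1 / sqrt(as.numeric(dens))))
}

build_sample_panel <- function(tracks, window, span_cap) {
  ev <- tidy.sample_tracks(tracks)
  xr <- c(window$start, window$end)
  cov <- tracks$coverage
  max_depth <- max(cov$depth, 1)
  p <- ggplot2::ggplot()
  # coverage as a grey filled profile on the secondary (right) axis,
  # rescaled into span units
  p <- p + ggplot2::geom_area(
    data = cov,
    ggplot2::aes(x = .data$pos + 0.5, y = .data$depth / max_depth * span_cap),
    fill = "grey80", color = NA)
  if (nrow(ev) > 0) {
    ev$y <- pmin(ev$span, span_cap)  # large spans clamp to the axis top
    ev$alpha <- density_alpha((ev$left_start + ev$right_end) / 2, ev$y,
                              xr, c(0, span_cap))
    pairs <- filter(ev, .data$kind == "pair")
    splits <- filter(ev, .data$kind == "split")
    if (nrow(pairs) > 0) {
      p <- p +
        ggplot2::geom_segment(
          data = pairs,
          ggplot2::aes(x = .data$left_start, xend = .data$right_end,
                       y = .data$y, yend = .data$y, color = .data$class,
                       alpha = .data$alpha),
          linetype = "solid", linewidth = 0.4) +
        ggplot2::geom_point(
          data = tidyr::pivot_longer(pairs, c("left_start", "right_end"),
                                     values_to = "xend"),
          ggplot2::aes(x = .data$xend, y = .data$y, color = .data$class,
                       alpha = .data$alpha),
          shape = 15, size = 1)
    }
    if (nrow(splits) > 0) {
      p <- p +
        ggplot2::geom_segment(
          data = splits,
          ggplot2::aes(x = .data$left_start, xend = .data$right_end,
                       y = .data$y, yend = .data$y, color = .data$class,
                       alpha = .data$alpha),
          linetype = "dashed", linewidth = 0.4) +
        ggplot2::geom_point(
          data = tidyr::pivot_longer(splits, c("left_start", "right_end"),
                                     values_to = "xend"),
          ggplot2::aes(x = .data$xend, y = .data$y, color = .data$class,
                       alpha = .data$alpha),
          shape = 16, size = 1)
    }
  }
  p <- p +
    ggplot2::scale_color_manual(values = evidence_colors(), drop = TRUE) +
    ggplot2::scale_alpha_identity() +
    ggplot2::scale_y_continuous(
      name = "Insert size (bp)", limits = c(0, span_cap),
      sec.axis = ggplot2::sec_axis(~ . / span_cap * max_depth,
                                   name = "Coverage")) +
    ggplot2::coord_cartesian(xlim = xr, expand = FALSE) +
    ggplot2::labs(subtitle = tracks$sample_name) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.title.x = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank())
  p
}

build_locator_panel <- function(sv, window) {
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = tibble(xmin = sv$start, xmax = sv$end),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = 0.25, ymax = 0.75),
      fill = "black") +
    ggplot2::coord_cartesian(xlim = c(window$start, window$end),
                             ylim = c(0, 1), expand = FALSE) +
    ggplot2::theme_void(base_size = 9)
}

build_annotation_panel <- function(ann, window) {
  ann$y <- ifelse(ann$kind == "exon", 0.35, 0.5)
  ann$h <- ifelse(ann$kind == "exon", 0.3, 0.12)
  ggplot2::ggplot(ann) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = pmax(.data$start, window$start),
                   xmax = pmin(.data$end, window$end),
                   ymin = .data$y - .data$h / 2,
                   ymax = .data$y + .data$h / 2,
                   fill = .data$kind)) +
    ggplot2::geom_text(
      data = distinct(filter(ann, !is.na(.data$label),
                             .data$kind != "exon"), .data$label,
                      .keep_all = TRUE),
      ggplot2::aes(x = (pmax(.data$start, window$start) +
                          pmin(.data$end, window$end)) / 2,
                   y = 0.8, label = .data$label), size = 2.5) +
    ggplot2::scale_fill_manual(values = c(gene = "steelblue4",
                                          exon = "steelblue2",
                                          region = "grey40")) +
    ggplot2::coord_cartesian(xlim = c(window$start, window$end),
                             ylim = c(0, 1), expand = FALSE) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = sprintf("Position on %s (bp)", window$chrom)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.title.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Compose the per-SV evidence figure
#'
#' Builds the stacked figure: an SV locator bar spanning the call, one
#' panel per sample in the given order (paired-end glyphs as solid
#' connectors with square ends, split-read glyphs as dashed connectors with
#' circle ends, both positioned by genomic x and outer span y and colored
#' by evidence class; coverage as a grey filled profile against a
#' secondary right axis), and an annotation panel below when annotations
#' are present. All panels share the window's x range. The span axis is
#' linear up to the 98th percentile of plotted spans; larger spans clamp to
#' the axis top.
#'
#' @param sv A one-row [sv_call()] tibble.
#' @param samples List of `sample_tracks` (order preserved; the sample of
#'   interest first).
#' @param window A [genomic_window()]; defaults to [compute_window()] of
#'   the sv.
#' @param annotations Optional annotation tibble from
#'   [load_gene_annotations()].
#' @param title Figure title; defaults to a locus description.
#' @return A list of class `sv_figure` with elements `figure` (patchwork),
#'   `panels` (tibble of panel kinds and glyph counts), `sv`, `window`.
#' @export
build_sv_figure <- function(sv, samples, window = NULL, annotations = NULL,
                            title = NULL) {
  if (length(samples) == 0) abort("need at least one sample")
  if (inherits(samples, "sample_tracks")) samples <- list(samples)
  if (is.null(window)) window <- compute_window(sv)
  spans <- unlist(purrr::map(samples,
                             ~ c(.x$pairs$span, .x$splits$span)))
  span_cap <- if (length(spans) > 0) {
    max(stats::quantile(spans, 0.98, names = FALSE), 1)
  } else 1
  if (is.null(title)) {
    title <- sprintf("%s %s:%s-%s", sv$svtype, sv$chrom,
                     format(sv$start, big.mark = ","),
                     format(sv$end, big.mark = ","))
  }
  panels <- list(build_locator_panel(sv, window))
  panel_info <- tibble(kind = "locator", sample = NA_character_,
                       n_glyphs = 0L)
  for (tr in samples) {
    panels <- c(panels, list(build_sample_panel(tr, window, span_cap)))
    panel_info <- bind_rows(panel_info,
                            tibble(kind = "sample", sample = tr$sample_name,
                                   n_glyphs = nrow(tr$pairs) +
                                     nrow(tr$splits)))
  }
  has_ann <- !is.null(annotations) && nrow(annotations) > 0
  if (has_ann) {
    panels <- c(panels, list(build_annotation_panel(annotations, window)))
    panel_info <- bind_rows(panel_info,
                            tibble(kind = "annotation",
                                   sample = NA_character_, n_glyphs = 0L))
  }
  heights <- c(0.35, rep(2, length(samples)), if (has_ann) 0.8)
  fig <- patchwork::wrap_plots(panels, ncol = 1, heights = heights) +
    patchwork::plot_annotation(title = title)
  structure(list(figure = fig, panels = panel_info, sv = sv,
                 window = window),
            class = "sv_figure")
}

#' @export
print.sv_figure <- function(x, ...) {
  cat(sprintf("<sv_figure> %s: %d panel(s)\n", x$sv$id, nrow(x$panels)))
  invisible(x)
}

#' Sanitize an SV id into an image file name
#'
#' Characters outside `[A-Za-z0-9._-]` are replaced by `_`.
#'
#' @param id SV/image identifier.
#' @return File name `"<sanitized id>.png"`.
#' @export
image_filename <- function(id) {
  paste0(gsub("[^A-Za-z0-9._-]", "_", id), ".png")
}

#' Render an SV evidence figure to a PNG file
#'
#' @param sv,samples,window,annotations,title Passed to
#'   [build_sv_figure()].
#' @param path Output PNG path; defaults to [image_filename()] of the SV id
#'   in the working directory.
#' @param dpi Raster resolution (default 100).
#' @param width,height Figure size in inches.
#' @return The `sv_figure` object, invisibly, with `$path` set.
#' @export
render_sv_figure <- function(sv, samples, path = NULL, window = NULL,
                             annotations = NULL, title = NULL, dpi = 100,
                             width = 8, height = NULL) {
  fig <- build_sv_figure(sv, samples, window = window,
                         annotations = annotations, title = title)
  if (is.null(path)) path <- image_filename(sv$id)
  if (!dir.exists(dirname(path))) {
    abort(paste0("output directory does not exist: ", dirname(path)))
  }
  if (is.null(height)) height <- 1 + 1.6 * sum(fig$panels$kind == "sample") +
    0.9 * sum(fig$panels$kind == "annotation")
  if (capabilities("cairo")) {
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi, type = "cairo")
  } else {
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(fig$figure)
  fig$path <- path
  invisible(fig)
}
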