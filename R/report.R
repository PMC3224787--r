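#' @import ggplot2
#' @importFrom rlang .data
#' @importFrom grDevices png pdf dev.off
#' @importFrom utils read.delim
NULL

## ---- writeTable methods ---------------------------------------------------

#' @describeIn writeTable length-distribution statistics
#'   (`length_distribution.tsv` layout).
#' @export
setMethod("writeTable", "LengthStats", function(x, path, ...) {
  .writeTSV(x@table, path, "length-distribution")
})

#' @describeIn writeTable per-label mono- and dinucleotide frequencies, one
#'   row per label, 20 frequency columns.
#' @export
setMethod("writeTable", "NucFreqTable", function(x, path, ...) {
  df <- data.frame(label = rownames(x@mono), x@mono, x@di,
                   ambiguous = as.integer(x@ambiguous),
                   stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  .writeTSV(df, path, "nucleotide-frequency")
})

#' @describeIn writeTable transition matrix; `what` selects `"freqs"`
#'   (default) or `"counts"`.
#' @param what which matrix of a `TransitionMatrix` to write.
#' @export
setMethod("writeTable", "TransitionMatrix", function(x, path,
                                                     what = c("freqs", "counts"),
                                                     ...) {
  what <- match.arg(what)
  m <- if (what == "freqs") x@freqs else x@counts
  df <- data.frame(label = rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  rownames(df) <- NULL
  .writeTSV(df, path, "transition", list(matrix = what))
})

#' @describeIn writeTable the aggregation profile's long table.
#' @export
setMethod("writeTable", "AggregationProfile", function(x, path, ...) {
  .writeTSV(x@table, path, "aggregation",
            c(list(mode = x@mode), x@params))
})

#' @describeIn writeTable overlap results; `what` selects `"pr"`
#'   (label, group, precision, recall; default) or `"counts"` (bases,
#'   segment and record hit counts).
#' @export
setMethod("writeTable", "OverlapTable", function(x, path,
                                                 what = c("pr", "counts"),
                                                 ...) {
  what <- match.arg(what)
  if (what == "pr") {
    return(.writeTSV(x@pr, path, "overlap", x@params))
  }
  labs <- rownames(x@bases); grps <- colnames(x@bases)
  df <- expand.grid(label = labs, group = grps, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  df$bases <- as.vector(x@bases)
  df$segments_hit <- as.vector(x@segmentHits)
  df$records_hit <- as.vector(x@recordHits)
  df$label_segments <- x@labelTotals$segments[df$label]
  df$label_bases <- x@labelTotals$bases[df$label]
  df$group_records <- x@groupTotals$records[df$group]
  df$fraction <- if (x@params$mode == "bases")
    df$bases / ifelse(df$label_bases > 0, df$label_bases, NA_real_)
  else df$segments_hit / ifelse(df$label_segments > 0, df$label_segments,
                                NA_real_)
  .writeTSV(df, path, "overlap", x@params)
})

#' @describeIn writeTable pairwise label edit distances (long form with
#'   Jaccard similarity).
#' @export
setMethod("writeTable", "EditDistanceMatrix", function(x, path, ...) {
  df <- expand.grid(label1 = x@labels1, label2 = x@labels2,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$distance <- as.vector(x@distance)
  df$jaccard <- as.vector(x@jaccard)
  .writeTSV(df, path, "compare")
})

#' @describeIn writeTable per-track, per-label signal statistics.
#' @export
setMethod("writeTable", "SignalStats", function(x, path, ...) {
  .writeTSV(x@stats, path, "signal-distribution")
})

#' @describeIn writeTable nearest-feature distances (the data.frame returned
#'   by [featureDistance()]).
#' @export
setMethod("writeTable", "data.frame", function(x, path, ...) {
  .writeTSV(x, path, "feature-distance")
})

## ---- plotting -------------------------------------------------------------

.savePlot <- function(p, outdir, stem, width = 7, height = 5) {
  files <- character()
  for (ext in c("png", "pdf")) {
    f <- file.path(outdir, paste0(stem, ".", ext))
    ok <- tryCatch({
      ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
      TRUE
    }, error = function(e) {
      warning("could not render ", f, ": ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) files <- c(files, f)
  }
  files
}

.heatmapPlot <- function(m, xlab, ylab, fill = "value") {
  df <- expand.grid(row = rownames(m), col = colnames(m),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  df$value <- as.vector(m)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey80", name = fill) +
    labs(x = xlab, y = ylab) +
    theme_minimal(base_size = 10) +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @describeIn writePlots violin plot of segment lengths per label and a bar
#'   plot of base (and, unless `noSegments`, segment) fractions.
#' @param noSegments suppress the segment-fraction series of the bar plot.
#' @export
setMethod("writePlots", "LengthStats", function(x, outdir, noSegments = FALSE,
                                                ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(
    label = factor(rep(names(x@lengths), lengths(x@lengths)),
                   levels = names(x@lengths)),
    length = unlist(x@lengths, use.names = FALSE))
  pv <- ggplot(df, aes(x = .data$label, y = .data$length)) +
    geom_violin(fill = "steelblue", scale = "width") +
    scale_y_log10() +
    labs(x = "label", y = "segment length (bases)") +
    theme_minimal(base_size = 10)
  tab <- x@table
  bar <- data.frame(label = rep(tab$label, 2L),
                    series = rep(c("bases", "segments"), each = nrow(tab)),
                    fraction = c(tab$frac_bases, tab$frac_segments))
  if (noSegments) bar <- bar[bar$series == "bases", , drop = FALSE]
  bar$label <- factor(bar$label, levels = tab$label)
  pb <- ggplot(bar, aes(x = .data$label, y = .data$fraction,
                        fill = .data$series)) +
    geom_col(position = "dodge") +
    labs(x = "label", y = "fraction") +
    theme_minimal(base_size = 10)
  invisible(c(.savePlot(pv, outdir, "length_distribution_violin"),
              .savePlot(pb, outdir, "length_distribution_bar")))
})

#' @describeIn writePlots heat map of row-conditional transition frequencies.
#' @export
setMethod("writePlots", "TransitionMatrix", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .heatmapPlot(x@freqs, "following label", "preceding label",
                    "frequency")
  invisible(.savePlot(p, outdir, "transition_heatmap"))
})

#' @describeIn writePlots heat map of dinucleotide frequencies by label.
#' @export
setMethod("writePlots", "NucFreqTable", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .heatmapPlot(x@di, "dinucleotide", "label", "frequency")
  invisible(.savePlot(p, outdir, "nucleotide_frequency_heatmap",
                      width = 9))
})

#' @describeIn writePlots enrichment line plot along the offset / bin /
#'   component axis, one line per label, faceted by group and component.
#' @export
setMethod("writePlots", "AggregationProfile", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  df <- x@table
  df$component <- factor(df$component, levels = unique(df$component))
  p <- ggplot(df, aes(x = .data$bin, y = .data$enrichment,
                      color = .data$label)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    facet_grid(group ~ component, scales = "free_x", space = "free_x") +
    labs(x = if (x@mode == "point") "offset (bases)" else "bin",
         y = expression(log[2] * ((f[obs] + 1) / (f[rand] + 1)))) +
    theme_minimal(base_size = 9)
  invisible(.savePlot(p, outdir, "aggregation", width = 10))
})

#' @describeIn writePlots per-group precision-recall scatter and an overlap
#'   fraction heat map.
#' @export
setMethod("writePlots", "OverlapTable", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pr <- x@pr
  p1 <- ggplot(pr, aes(x = .data$recall, y = .data$precision,
                       color = .data$label)) +
    geom_point(size = 2) +
    facet_wrap(~group) +
    lims(x = c(0, 1), y = c(0, 1)) +
    theme_minimal(base_size = 10)
  frac <- if (x@params$mode == "bases")
    x@bases / ifelse(x@labelTotals$bases > 0, x@labelTotals$bases, NA_real_)
  else x@segmentHits / ifelse(x@labelTotals$segments > 0,
                              x@labelTotals$segments, NA_real_)
  p2 <- .heatmapPlot(frac, "annotation group", "segment label",
                     paste("fraction of", x@params$mode))
  invisible(c(.savePlot(p1, outdir, "overlap_pr"),
              .savePlot(p2, outdir, "overlap_heatmap")))
})

#' @describeIn writePlots heat map of pairwise label edit distances.
#' @export
setMethod("writePlots", "EditDistanceMatrix", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .heatmapPlot(x@distance, "labels of segmentation 2",
                    "labels of segmentation 1", "bases")
  invisible(.savePlot(p, outdir, "compare_heatmap"))
})

#' @describeIn writePlots clustered, row-normalized heat map of per-label
#'   signal means with SD bars.
#' @export
setMethod("writePlots", "SignalStats", function(x, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  m <- x@normalized[x@rowOrder, x@colOrder, drop = FALSE]
  s <- x@sdRel[x@rowOrder, x@colOrder, drop = FALSE]
  df <- expand.grid(track = rownames(m), label = colnames(m),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df$track <- factor(df$track, levels = rev(rownames(m)))
  df$label <- factor(df$label, levels = colnames(m))
  df$value <- as.vector(m)
  df$sdRel <- as.vector(s)
  p <- ggplot(df, aes(x = .data$label, y = .data$track)) +
    geom_tile(aes(fill = .data$value)) +
    geom_segment(aes(x = as.integer(.data$label) - 0.45 * .data$sdRel,
                     xend = as.integer(.data$label) + 0.45 * .data$sdRel,
                     y = as.integer(.data$track),
                     yend = as.integer(.data$track)),
                 linewidth = 0.8, color = "black", na.rm = TRUE) +
    scale_fill_viridis_c(na.value = "grey80",
                         name = "row-normalized mean") +
    labs(x = "label", y = "track") +
    theme_minimal(base_size = 10)
  invisible(.savePlot(p, outdir, "signal_distribution_heatmap"))
})

## ---- HTML report ----------------------------------------------------------

.htmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.relPath <- function(path, base) {
  p <- strsplit(normalizePath(path, winslash = "/"), "/")[[1]]
  b <- strsplit(normalizePath(base, winslash = "/"), "/")[[1]]
  i <- 0L
  while (i < min(length(p), length(b)) && p[i + 1L] == b[i + 1L]) i <- i + 1L
  paste(c(rep("..", length(b) - i), p[(i + 1L):length(p)]), collapse = "/")
}

.tsvCommand <- function(path) {
  l <- readLines(path, n = 1L)
  if (grepl("^# command: ", l)) sub("^# command: ", "", l) else NA_character_
}

.tsvParams <- function(path) {
  h <- readLines(path, n = 3L)
  pl <- grep("^# parameters: ", h, value = TRUE)
  if (length(pl)) sub("^# parameters: ", "", pl[1L]) else ""
}

#' Collate command outputs into one HTML report
#'
#' Scans each result directory for the tab-delimited files and plot images
#' written by the analysis commands and assembles a single page with one
#' section per command: embedded PNG plots (relative links by default),
#' links to the TSV files, and the parameter headers surfaced. Statistics
#' are never recomputed; the page is a pure collation of on-disk outputs.
#' Directories with no recognizable outputs are skipped with a warning.
#'
#' @param dirs character vector of result directories.
#' @param output output HTML path.
#' @param title page title.
#' @param inlineImages embed PNGs as data URIs instead of relative links.
#' @return `output`, invisibly.
#' @export
htmlReport <- function(dirs, output, title = "segexplore report",
                       inlineImages = FALSE) {
  if (!length(dirs)) stop("empty directory list", call. = FALSE)
  outBase <- dirname(output)
  dir.create(outBase, recursive = TRUE, showWarnings = FALSE)
  body <- character()
  for (d in dirs) {
    tsvs <- list.files(d, pattern = "\\.tsv$", full.names = TRUE)
    pngs <- list.files(d, pattern = "\\.png$", full.names = TRUE)
    pdfs <- list.files(d, pattern = "\\.pdf$", full.names = TRUE)
    others <- list.files(d, pattern = "\\.(bed|gff3?|gtf|bedgraph|dot)$",
                         full.names = TRUE)
    if (!length(tsvs) && !length(pngs) && !length(others)) {
      warning("no recognizable outputs in ", d, "; section skipped",
              call. = FALSE)
      next
    }
    cmds <- unique(stats::na.omit(vapply(tsvs, .tsvCommand, character(1))))
    secTitle <- if (length(cmds)) paste(cmds, collapse = ", ") else basename(d)
    body <- c(body, sprintf('<section id="%s">', .htmlEscape(basename(d))),
              sprintf("<h2>%s</h2>", .htmlEscape(secTitle)))
    for (f in tsvs) {
      par <- .tsvParams(f)
      body <- c(body, sprintf(
        '<p><a href="%s">%s</a> <code>%s</code></p>',
        .htmlEscape(.relPath(f, outBase)), .htmlEscape(basename(f)),
        .htmlEscape(par)))
    }
    for (f in pngs) {
      src <- if (inlineImages)
        paste0("data:image/png;base64,",
               .base64enc(readBin(f, "raw", file.info(f)$size)))
      else .htmlEscape(.relPath(f, outBase))
      body <- c(body, sprintf(
        '<figure><img src="%s" alt="%s" style="max-width:100%%"/><figcaption>%s</figcaption></figure>',
        src, .htmlEscape(basename(f)), .htmlEscape(basename(f))))
    }
    for (f in c(pdfs, others))
      body <- c(body, sprintf('<p><a href="%s">%s</a></p>',
                              .htmlEscape(.relPath(f, outBase)),
                              .htmlEscape(basename(f))))
    body <- c(body, "</section>")
  }
  doc <- c("<!DOCTYPE html>",
           '<html xmlns="http://www.w3.org/1999/xhtml"><head>',
           '<meta charset="utf-8"/>',
           sprintf("<title>%s</title>", .htmlEscape(title)),
           "<style>body{font-family:sans-serif;max-width:1100px;margin:auto}",
           "section{border-top:1px solid #ccc;padding:1em 0}</style>",
           "</head><body>",
           sprintf("<h1>%s</h1>", .htmlEscape(title)),
           body,
           "</body></html>")
  writeLines(doc, output)
  invisible(output)
}

## minimal base64 encoder for inline images (raw -> character)
.base64enc <- function(raw) {
  alpha <- c(LETTERS, letters, 0:9, "+", "/")
  n <- length(raw)
  pad <- (3L - n %% 3L) %% 3L
  raw <- c(raw, as.raw(rep(0L, pad)))
  m <- matrix(as.integer(raw), nrow = 3L)
  b1 <- m[1, ] %/% 4L
  b2 <- (m[1, ] %% 4L) * 16L + m[2, ] %/% 16L
  b3 <- (m[2, ] %% 16L) * 4L + m[3, ] %/% 64L
  b4 <- m[3, ] %% 64L
  out <- paste(alpha[rbind(b1, b2, b3, b4) + 1L], collapse = "")
  if (pad > 0)
    out <- paste0(substr(out, 1L, nchar(out) - pad),
                  strrep("=", pad))
  out
}
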