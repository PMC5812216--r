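# Score/spanning filtering and the static evidence plot: color-coded read
# tracks around the breakpoint, rendered as standalone SVG plus an HTML
# report and machine-readable tables.

#' Filter settings for the evidence display
#'
#' @param min_alpha minimum normalized alignment score, 0-100; the comparison
#'   is inclusive (`alpha >= min_alpha`), so the conventional threshold of 95
#'   retains reads scoring exactly 95.
#' @param spanning_only keep only junction-spanning reads (for pairs: pairs
#'   with at least one spanning mate).
#' @param paired treat results as read pairs grouped by name: a pair is kept
#'   only when BOTH mates pass the score threshold.
#' @return An object of class `"filter_settings"`.
#' @export
filter_settings <- function(min_alpha = 0, spanning_only = FALSE,
                            paired = FALSE) {
  min_alpha <- as.numeric(min_alpha)
  if (is.na(min_alpha) || min_alpha < 0 || min_alpha > 100)
    stop("min_alpha must lie in [0, 100]")
  structure(list(min_alpha = min_alpha, spanning_only = isTRUE(spanning_only),
                 paired = isTRUE(paired)),
            class = "filter_settings")
}

#' Apply score and spanning filters to alignment results
#'
#' Single-end semantics: a read is retained iff `alpha >= min_alpha` and
#' (when `spanning_only`) it spans the junction. Paired semantics: mates are
#' grouped by read name; a pair is retained iff BOTH mates pass the score
#' threshold, and, under `spanning_only`, at least one mate spans. Raising
#' `min_alpha` never adds reads.
#'
#' @param results a list of `"fan_alignment"` objects.
#' @param settings a [filter_settings()].
#' @return The retained subset, same class as the input list.
#' @export
apply_filters <- function(results, settings) {
  stopifnot(inherits(settings, "filter_settings"))
  if (length(results) == 0L) return(results)
  alpha <- vapply(results, function(r) as.numeric(r$alpha), 0)
  alpha[is.na(alpha)] <- -Inf  # unscorable (empty) reads never pass
  spanning <- vapply(results, function(r) isTRUE(r$spanning), FALSE)
  if (settings$paired) {
    name <- vapply(results, function(r) r$read_name, "")
    pass <- tapply(alpha >= settings$min_alpha, name, all)
    if (settings$spanning_only)
      pass <- pass & tapply(spanning, name, any)[names(pass)]
    keep <- name %in% names(pass)[pass]
  } else {
    keep <- alpha >= settings$min_alpha &
      (!settings$spanning_only | spanning)
  }
  out <- results[keep]
  class(out) <- class(results)
  out
}

# Fixed 12-color palette (colorblind-aware, derived from common qualitative
# palettes). Cycled with darkening when a panel has more references.
FAN_PALETTE <- c("#4E79A7", "#F28E2B", "#59A14F", "#E15759",
                 "#B07AA1", "#76B7B2", "#EDC948", "#FF9DA7",
                 "#9C755F", "#BAB0AC", "#2F4B7C", "#A05195")

#' Assign a color to every panel reference
#'
#' Deterministic, collision-free mapping from a fixed palette: colors follow
#' the sorted reference labels, so identical panels (in any order) always
#' map to identical colors. Panels larger than the palette cycle through it
#' with progressive darkening (with a warning).
#'
#' @param panel a [reference_panel()].
#' @return Named character vector: label -> hex color.
#' @export
assign_colors <- function(panel) {
  labels <- panel_labels(panel)
  sorted <- sort(labels, method = "radix")
  n <- length(sorted)
  if (n > length(FAN_PALETTE))
    warning(sprintf("panel has %d references; palette of %d cycles with shade variation",
                    n, length(FAN_PALETTE)))
  idx <- ((seq_len(n) - 1L) %% length(FAN_PALETTE)) + 1L
  round_ <- (seq_len(n) - 1L) %/% length(FAN_PALETTE)
  cols <- vapply(seq_len(n), function(k) {
    col <- FAN_PALETTE[[idx[[k]]]]
    if (round_[[k]] > 0L) {
      rgb <- grDevices::col2rgb(col) * 0.65^round_[[k]]
      col <- grDevices::rgb(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 255)
    }
    col
  }, "")
  stats::setNames(cols, sorted)[labels]
}

#' Lay out alignment results as plot tracks
#'
#' Converts filtered results into a renderable plot model. Track x
#' coordinates are junction-relative base offsets (left references end at
#' offset -1, right references start at 0). Mates sharing a read name are
#' co-plotted on one row joined by a connector. Ordering: spanning reads (or
#' pairs with a spanning mate) first, then left-only, then right-only, each
#' by descending alpha, ties by name.
#'
#' @param results filtered list of `"fan_alignment"` objects.
#' @param panel the [reference_panel()] used for alignment.
#' @param settings a [filter_settings()] (controls pairing).
#' @return An object of class `"fan_plot"`: `tracks` (one row per colored
#'   segment), `connectors`, `legend`, `xlim`, `n_tracks`.
#' @export
layout_tracks <- function(results, panel, settings = filter_settings()) {
  colors <- assign_colors(panel)
  per_result_segments <- function(r, mate_tag) {
    segs <- NULL
    if (!is.na(r$left_ref)) {
      segs <- rbind(segs, data.frame(
        label = r$left_ref, color = unname(colors[[r$left_ref]]),
        x0 = r$left_offsets[[1L]], x1 = r$left_offsets[[2L]] + 1L,
        stringsAsFactors = FALSE))
    }
    if (!is.na(r$right_ref)) {
      segs <- rbind(segs, data.frame(
        label = r$right_ref, color = unname(colors[[r$right_ref]]),
        x0 = r$right_offsets[[1L]], x1 = r$right_offsets[[2L]] + 1L,
        stringsAsFactors = FALSE))
    }
    if (!is.null(segs)) {
      segs$name <- r$read_name
      segs$mate <- mate_tag
      segs$alpha <- r$alpha
      segs$strand <- r$strand
      segs$spanning <- isTRUE(r$spanning)
    }
    segs
  }
  # group results into display units (pairs or single reads)
  if (settings$paired) {
    names_ <- vapply(results, function(r) r$read_name, "")
    groups <- split(seq_along(results), names_)
  } else {
    groups <- as.list(seq_along(results))
    names(groups) <- sprintf("%s#%d",
                             vapply(results, function(r) r$read_name, ""),
                             seq_along(results))
  }
  units <- lapply(groups, function(ix) {
    rs <- results[ix]
    alpha <- max(vapply(rs, function(r)
      ifelse(is.na(r$alpha), -Inf, r$alpha), 0))
    spanning <- any(vapply(rs, function(r) isTRUE(r$spanning), FALSE))
    has_left <- any(vapply(rs, function(r) !is.na(r$left_ref), FALSE))
    has_right <- any(vapply(rs, function(r) !is.na(r$right_ref), FALSE))
    side_class <- if (spanning) 1L else if (has_left && !has_right) 2L
                  else if (has_right) 3L else 4L
    list(ix = ix, alpha = alpha, spanning = spanning,
         side_class = side_class,
         name = results[[ix[[1L]]]]$read_name)
  })
  ord <- order(vapply(units, `[[`, 0L, "side_class"),
               -vapply(units, `[[`, 0, "alpha"),
               vapply(units, `[[`, "", "name"))
  units <- units[ord]
  tracks <- NULL
  connectors <- NULL
  for (row in seq_along(units)) {
    u <- units[[row]]
    row_segs <- NULL
    for (k in seq_along(u$ix)) {
      r <- results[[u$ix[[k]]]]
      segs <- per_result_segments(r, mate_tag = if (is.na(r$mate)) 0L else r$mate)
      if (!is.null(segs)) {
        segs$row <- row
        row_segs <- rbind(row_segs, segs)
      }
    }
    if (!is.null(row_segs) && nrow(row_segs) > 1L) {
      gap_lo <- max(row_segs$x0)
      gap_hi <- min(row_segs$x1)
      if (gap_lo > gap_hi) {  # disjoint segments: join with a connector
        connectors <- rbind(connectors,
                            data.frame(row = row, x0 = gap_hi, x1 = gap_lo))
      }
    }
    tracks <- rbind(tracks, row_segs)
  }
  legend <- data.frame(label = names(colors), color = unname(colors),
                       stringsAsFactors = FALSE)
  max_left <- max(vapply(panel$left, function(e) nchar(e$seq), 0L))
  max_right <- max(vapply(panel$right, function(e) nchar(e$seq), 0L))
  structure(list(tracks = tracks, connectors = connectors, legend = legend,
                 xlim = c(-max_left, max_right),
                 n_tracks = length(units)),
            class = "fan_plot")
}

#' @export
print.fan_plot <- function(x, ...) {
  cat(sprintf("fusion evidence plot: %d track(s), %d reference(s), x in [%d, %d]\n",
              x$n_tracks, nrow(x$legend), x$xlim[[1L]], x$xlim[[2L]]))
  invisible(x)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the evidence plot and report files
#'
#' Writes a standalone SVG (one group element per read track, one per legend
#' entry, plus the dashed breakpoint guide), a single-file HTML report
#' embedding the SVG above a sortable table, and TSV/JSON tables of the
#' retained alignments. Output is byte-stable for identical inputs.
#'
#' @param plot a `"fan_plot"` from [layout_tracks()].
#' @param results the same filtered results the plot was laid out from
#'   (for the tables).
#' @param out_dir output directory (created if needed).
#' @param basename file stem for the four artifacts.
#' @return Invisibly, a named character vector of the paths written.
#' @export
render_report <- function(plot, results, out_dir, basename = "fusion_report") {
  stopifnot(inherits(plot, "fan_plot"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop(sprintf("cannot create output directory: %s", out_dir))
  }
  svg_path <- file.path(out_dir, paste0(basename, ".svg"))
  html_path <- file.path(out_dir, paste0(basename, ".html"))
  tsv_path <- file.path(out_dir, paste0(basename, ".tsv"))
  json_path <- file.path(out_dir, paste0(basename, ".json"))
  svg <- build_svg(plot)
  writeLines(svg, svg_path, sep = "\n")
  tab <- write_results(results, tsv_path = tsv_path, json_path = json_path)
  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset=\"utf-8\"/>",
            "<title>Fusion breakpoint evidence</title>",
            "<style>body{font-family:sans-serif;margin:20px} table{border-collapse:collapse} td,th{border:1px solid #999;padding:3px 8px;font-size:12px}</style>",
            "</head><body>",
            "<h1>Fusion breakpoint evidence</h1>",
            svg,
            "<h2>Retained alignments</h2>",
            html_table(tab),
            "</body></html>")
  writeLines(html, html_path, sep = "\n")
  invisible(c(svg = svg_path, html = html_path, tsv = tsv_path,
              json = json_path))
}

html_table <- function(tab) {
  head <- paste0("<tr>", paste0("<th>", svg_escape(names(tab)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(tab)), function(r) {
    cells <- vapply(tab[r, ], function(v) {
      if (is.numeric(v)) sprintf("%.2f", v) else svg_escape(as.character(v))
    }, "")
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, "")
  c("<table>", head, rows, "</table>")
}

# SVG geometry constants (pixels).
SVG_SCALE <- 3        # px per base
SVG_TRACK_H <- 8
SVG_TRACK_GAP <- 4
SVG_MARGIN <- 30
SVG_LEGEND_ROW <- 16

build_svg <- function(plot) {
  xpix <- function(x) SVG_MARGIN + (x - plot$xlim[[1L]]) * SVG_SCALE
  legend_h <- nrow(plot$legend) * SVG_LEGEND_ROW + 10
  tracks_h <- max(plot$n_tracks, 1L) * (SVG_TRACK_H + SVG_TRACK_GAP)
  width <- ceiling(xpix(plot$xlim[[2L]]) + SVG_MARGIN)
  height <- legend_h + tracks_h + SVG_MARGIN
  ypix <- function(row) legend_h + (row - 1L) * (SVG_TRACK_H + SVG_TRACK_GAP)
  out <- c(sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
                   width, height, width, height))
  # legend: one group per entry
  for (k in seq_len(nrow(plot$legend))) {
    y <- 5 + (k - 1L) * SVG_LEGEND_ROW
    out <- c(out, sprintf(
      "<g class=\"legend-entry\"><rect x=\"%d\" y=\"%d\" width=\"12\" height=\"10\" fill=\"%s\"/><text x=\"%d\" y=\"%d\" font-size=\"10\">%s</text></g>",
      SVG_MARGIN, y, plot$legend$color[[k]], SVG_MARGIN + 16, y + 9,
      svg_escape(plot$legend$label[[k]])))
  }
  # breakpoint guide
  out <- c(out, sprintf(
    "<line class=\"breakpoint-guide\" x1=\"%.1f\" y1=\"%d\" x2=\"%.1f\" y2=\"%d\" stroke=\"#333\" stroke-dasharray=\"4,3\"/>",
    xpix(0), legend_h - 5, xpix(0), legend_h + tracks_h))
  # connectors under the tracks
  if (!is.null(plot$connectors)) {
    for (k in seq_len(nrow(plot$connectors))) {
      cn <- plot$connectors[k, ]
      y <- ypix(cn$row) + SVG_TRACK_H / 2
      out <- c(out, sprintf(
        "<line class=\"mate-connector\" x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"#888\" stroke-width=\"1\"/>",
        xpix(cn$x0), y, xpix(cn$x1), y))
    }
  }
  # read tracks: one group per display row
  if (!is.null(plot$tracks) && nrow(plot$tracks) > 0L) {
    for (row in sort(unique(plot$tracks$row))) {
      segs <- plot$tracks[plot$tracks$row == row, , drop = FALSE]
      y <- ypix(row)
      rects <- vapply(seq_len(nrow(segs)), function(s) {
        sprintf("<rect x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%d\" fill=\"%s\"/>",
                xpix(segs$x0[[s]]), y,
                (segs$x1[[s]] - segs$x0[[s]]) * SVG_SCALE, SVG_TRACK_H,
                segs$color[[s]])
      }, "")
      tooltip <- sprintf("%s (strand %s, alpha %.2f%s)",
                         segs$name[[1L]], segs$strand[[1L]],
                         max(segs$alpha),
                         if (any(segs$spanning)) ", spanning" else "")
      out <- c(out, sprintf("<g class=\"read-track\"><title>%s</title>%s</g>",
                            svg_escape(tooltip),
                            paste(rects, collapse = "")))
    }
  }
  c(out, "</svg>")
}
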