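## Coverage heatmaps: one row per group (e.g. donor), x axis = residue
## position over the full target length. Tiles are centered on integer
## positions with unit width (tile i spans i-0.5 .. i+0.5), so region
## boundaries fall on half-integer edges; that makes the alignment
## between quant values, domain separators and PTM ticks unambiguous.

DEFAULT_REGION_COLORS <- c(cdr = "#E85D5D", mutation = "#8E44AD",
                           domain = NA, other = "#7FB3D5")

#' Plot configuration for coverage heatmaps
#'
#' @param color_scale \code{"greyscale"} (white to black, the PSM
#'   default), \code{"white_to_blue"} (the intensity/area default) or a
#'   character vector of >= 2 colors for a custom ramp.
#' @param region_colors Named vector mapping region labels (or categories
#'   \code{cdr}/\code{mutation}/\code{other}) to overlay colors.
#' @param ptm_tick_colors Named vector mapping PTM labels to tick colors.
#' @param scale_normalization \code{"global"} (one fill scale across all
#'   facets, the default: cross-condition comparison is the headline use)
#'   or \code{"per_facet"} (each target panel rescaled to its own max).
#' @param domain_labels,axis_ticks Logical label options.
#' @param window Optional \code{c(start, end)} residue window to zoom to.
#' @param width,height,dpi Output dimensions (inches) and resolution.
#' @param strict_colors Error on a region label with no configured color
#'   instead of falling back to the category default.
#' @param allow_empty Render empty axes instead of erroring on an empty
#'   quant table.
#' @return A list of class \code{"PlotConfig"}.
#' @export
plotConfig <- function(color_scale = NULL, region_colors = character(0),
                       ptm_tick_colors = character(0),
                       scale_normalization = c("global", "per_facet"),
                       domain_labels = TRUE, axis_ticks = TRUE,
                       window = NULL, width = 10, height = NULL,
                       dpi = 300, strict_colors = FALSE,
                       allow_empty = FALSE) {
  scale_normalization <- match.arg(scale_normalization)
  if (dpi <= 0) stop("dpi must be > 0")
  if (is.character(color_scale) && length(color_scale) > 1 &&
        length(color_scale) < 2)
    stop("custom color ramps need >= 2 anchors")
  structure(list(color_scale = color_scale, region_colors = region_colors,
                 ptm_tick_colors = ptm_tick_colors,
                 scale_normalization = scale_normalization,
                 domain_labels = domain_labels, axis_ticks = axis_ticks,
                 window = window, width = width, height = height,
                 dpi = dpi, strict_colors = strict_colors,
                 allow_empty = allow_empty),
            class = "PlotConfig")
}

fillScaleFor <- function(metric, color_scale, limits) {
  cs <- color_scale %||% if (metric == "psm") "greyscale"
                         else "white_to_blue"
  ## non-raster colorbar keeps vector output free of embedded bitmaps,
  ## so repeated SVG renders are byte-identical
  gd <- ggplot2::guide_colorbar(display = "rectangles")
  if (length(cs) > 1)
    return(ggplot2::scale_fill_gradientn(colors = cs, limits = limits,
                                         na.value = "white", guide = gd))
  switch(cs,
         greyscale = ggplot2::scale_fill_gradient(
           low = "white", high = "black", limits = limits,
           na.value = "white", guide = gd),
         white_to_blue = ggplot2::scale_fill_gradient(
           low = "white", high = "#08306B", limits = limits,
           na.value = "white", guide = gd),
         stop("unknown color_scale: ", cs))
}

groupKeyColumn <- function(df, group_cols) {
  if (!length(group_cols)) return(rep("all", nrow(df)))
  do.call(paste, c(lapply(group_cols, function(g) df[[g]]), sep = " / "))
}

regionOverlayColor <- function(labels, categories, config) {
  cols <- character(length(labels))
  for (i in seq_along(labels)) {
    if (labels[i] %in% names(config$region_colors))
      cols[i] <- config$region_colors[[labels[i]]]
    else if (categories[i] %in% names(config$region_colors))
      cols[i] <- config$region_colors[[categories[i]]]
    else if (isTRUE(config$strict_colors))
      stop("no color configured for region label '", labels[i], "'")
    else cols[i] <- DEFAULT_REGION_COLORS[[categories[i]]]
  }
  cols
}

## Internal panel builder shared by renderCoveragePlot / renderComparison.
buildCoveragePanel <- function(pq, targets, config, ptm_positions = NULL) {
  q <- as.data.frame(quantTable(pq))
  if (!nrow(q) && !isTRUE(config$allow_empty))
    stop("empty quant table (use allow_empty to render empty axes)")
  lens <- setNames(width(targetSequences(targets)), targetIds(targets))
  unknown <- setdiff(q$target_id, names(lens))
  if (length(unknown))
    stop("quant references unknown target(s): ",
         paste(unknown, collapse = ", "))
  tids <- if (nrow(q)) intersect(names(lens), unique(q$target_id))
          else names(lens)
  q <- q[q$target_id %in% tids, , drop = FALSE]
  q$group <- groupKeyColumn(q, groupBy(pq))
  groups <- sort(unique(q$group))
  if (!length(groups)) groups <- "all"
  q$y <- match(q$group, groups)
  if (config$scale_normalization == "per_facet" && nrow(q)) {
    mx <- tapply(q$value, q$target_id, max)
    q$fill_value <- q$value / pmax(as.vector(mx[q$target_id]), .Machine$double.eps)
    limits <- c(0, 1)
  } else {
    q$fill_value <- q$value
    limits <- c(0, if (nrow(q)) max(q$value) else 1)
  }
  ng <- length(groups)
  ## per-target x extent so facets show the full sequence
  extent <- data.frame(target_id = tids, xmin = 0.5,
                       xmax = as.vector(lens[tids]) + 0.5)
  p <- ggplot2::ggplot() +
    ggplot2::geom_blank(data = extent,
                        ggplot2::aes(xmin = xmin, xmax = xmax),
                        inherit.aes = FALSE) +
    ggplot2::geom_rect(data = extent,
                       ggplot2::aes(xmin = xmin, xmax = xmax),
                       ymin = 0.7, ymax = ng + 0.3,
                       fill = NA, color = "grey70", linewidth = 0.3)
  reg <- as.data.frame(targetRegions(targets))
  reg <- reg[reg$target_id %in% tids, , drop = FALSE]
  if (nrow(reg)) {
    overlay <- reg
    overlay$fill <- regionOverlayColor(overlay$label, overlay$category,
                                       config)
    overlay <- overlay[!is.na(overlay$fill), , drop = FALSE]
    if (nrow(overlay))
      p <- p + ggplot2::geom_rect(
        data = overlay,
        ggplot2::aes(xmin = start - 0.5, xmax = end + 0.5),
        ymin = 0.6, ymax = ng + 0.4, fill = overlay$fill, alpha = 0.25)
  }
  if (nrow(q))
    p <- p + ggplot2::geom_tile(
      data = q, ggplot2::aes(x = position, y = y, fill = fill_value),
      width = 1, height = 0.6)
  if (nrow(reg)) {
    seps <- data.frame(
      target_id = rep(reg$target_id, 2L),
      x = c(reg$start - 0.5, reg$end + 0.5))
    p <- p + ggplot2::geom_vline(
      data = seps, ggplot2::aes(xintercept = x),
      color = "grey30", linetype = "dashed", linewidth = 0.3)
    if (isTRUE(config$domain_labels))
      p <- p + ggplot2::geom_text(
        data = reg,
        ggplot2::aes(x = (start + end) / 2, label = label),
        y = ng + 0.55, size = 2.8, vjust = 0)
  }
  if (!is.null(ptm_positions) && nrow(ptm_positions) &&
        nrow(q)) {
    tk <- as.data.frame(ptm_positions)
    tk <- tk[tk$target_id %in% tids, , drop = FALSE]
    if (nrow(tk)) {
      tk$group <- groupKeyColumn(tk, intersect(groupBy(pq), colnames(tk)))
      tk$y0 <- match(tk$group, groups)
      tk <- tk[!is.na(tk$y0), , drop = FALSE]
      ## ticks sit in a fixed band above the heatmap bar; coincident
      ## ticks stack vertically in label-sorted order
      tk <- tk[order(tk$target_id, tk$group, tk$position, tk$ptm_label), ,
               drop = FALSE]
      key <- paste(tk$target_id, tk$group, tk$position)
      tk$stack <- stats::ave(seq_len(nrow(tk)), key,
                             FUN = seq_along) - 1L
      cols <- ifelse(tk$ptm_label %in% names(config$ptm_tick_colors),
                     config$ptm_tick_colors[tk$ptm_label],
                     NA)
      if (any(is.na(cols))) {
        lv <- sort(unique(tk$ptm_label[is.na(cols)]))
        pal <- rep_len(DEFAULT_PTM_PALETTE, length(lv))
        cols[is.na(cols)] <- pal[match(tk$ptm_label[is.na(cols)], lv)]
      }
      tk$color <- cols
      p <- p + ggplot2::geom_segment(
        data = tk,
        ggplot2::aes(x = position, xend = position,
                     y = y0 + 0.33 + stack * 0.06,
                     yend = y0 + 0.33 + stack * 0.06 + 0.05),
        color = tk$color, linewidth = 0.7)
    }
  }
  p <- p +
    fillScaleFor(metric(pq), config$color_scale, limits) +
    ggplot2::facet_grid(cols = ggplot2::vars(target_id),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(breaks = seq_len(ng), labels = groups,
                                limits = c(0.3, ng + 0.8),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "residue position", y = NULL,
                  fill = metric(pq)) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!isTRUE(config$axis_ticks))
    p <- p + ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                            axis.ticks.x = ggplot2::element_blank())
  if (!is.null(config$window))
    p <- p + ggplot2::coord_cartesian(
      xlim = c(config$window[1] - 0.5, config$window[2] + 0.5))
  p
}

openDevice <- function(file, config, n_panels = 1L) {
  fmt <- tolower(tools::file_ext(file))
  h <- config$height %||% (1.2 + 1.0 * n_panels)
  switch(fmt,
         png = grDevices::png(file, width = config$width, height = h,
                              units = "in", res = config$dpi),
         svg = grDevices::svg(file, width = config$width, height = h),
         pdf = grDevices::pdf(file, width = config$width, height = h),
         stop("unsupported output format: ", fmt))
}

writeSidecarMatrix <- function(pq, file) {
  side <- paste0(file, ".matrix.tsv")
  df <- as.data.frame(quantTable(pq))
  df$group <- groupKeyColumn(df, groupBy(pq))
  if (nrow(df)) {
    dt <- data.table::dcast(data.table::data.table(df),
                            target_id + group ~ position,
                            value.var = "value", fill = 0)
  } else {
    dt <- data.table::data.table(target_id = character(0),
                                 group = character(0))
  }
  data.table::fwrite(dt, side, sep = "\t", quote = FALSE)
  side
}

#' Render a linearized peptide coverage heatmap
#'
#' One heatmap row per group, residue position on x over the full target
#' length (uncovered positions blank), targets side by side as facets,
#' dashed separators and labels at region boundaries, CDR/mutation
#' regions overlaid in their configured colors, and PTM tick marks in a
#' band above each heatmap bar. PSM quant defaults to a white-to-black
#' gradient, intensity/area to white-to-blue. A sidecar TSV of the exact
#' plotted matrix is always written next to the image.
#'
#' @param pq A \code{PositionQuant}.
#' @param targets The \code{TargetSet} (lengths, regions).
#' @param ptm_positions Optional data.frame (target_id, group columns,
#'   position, ptm_label) of modification sites to tick-mark.
#' @param config A \code{\link{plotConfig}}.
#' @param file Output image path (.png/.svg/.pdf); \code{NULL} returns
#'   the plot without writing.
#' @return Invisibly, a list with \code{plot} (ggplot), \code{file} and
#'   \code{sidecar}.
#' @export
renderCoveragePlot <- function(pq, targets, ptm_positions = NULL,
                               config = plotConfig(), file = NULL) {
  stopifnot(is(pq, "PositionQuant"), is(targets, "TargetSet"))
  p <- buildCoveragePanel(pq, targets, config, ptm_positions)
  side <- NULL
  if (!is.null(file)) {
    openDevice(file, config)
    print(p)
    grDevices::dev.off()
    side <- writeSidecarMatrix(pq, file)
  }
  invisible(list(plot = p, file = file, sidecar = side))
}

#' Render stacked heatmaps of several metrics for the same matches
#'
#' Vertically stacked panels (e.g. PSM above, intensity below) with a
#' shared x axis and aligned region separators; each panel keeps its own
#' metric's color scale.
#'
#' @param pqs List of \code{PositionQuant}s sharing targets and groups.
#' @inheritParams renderCoveragePlot
#' @return Invisibly, a list with \code{plot} (patchwork), \code{panels}
#'   (list of ggplots), \code{file} and \code{sidecars}.
#' @export
renderComparison <- function(pqs, targets, ptm_positions = NULL,
                             config = plotConfig(), file = NULL) {
  stopifnot(length(pqs) >= 1)
  tsets <- lapply(pqs, function(pq)
    sort(unique(as.data.frame(quantTable(pq))$target_id)))
  if (length(unique(vapply(tsets, paste, character(1),
                           collapse = ","))) > 1)
    stop("panels reference different targets; metrics must share matches")
  panels <- lapply(seq_along(pqs), function(i)
    buildCoveragePanel(pqs[[i]], targets, config,
                       if (i == 1) ptm_positions else NULL))
  combined <- if (length(panels) == 1) panels[[1]]
              else patchwork::wrap_plots(panels, ncol = 1)
  sides <- NULL
  if (!is.null(file)) {
    openDevice(file, config, n_panels = length(panels))
    print(combined)
    grDevices::dev.off()
    sides <- vapply(seq_along(pqs), function(i)
      writeSidecarMatrix(pqs[[i]], sprintf("%s.panel%d", file, i)),
      character(1))
  }
  invisible(list(plot = combined, panels = panels, file = file,
                 sidecars = sides))
}

#' Render one lane per peptide occurrence (non-collapsed view)
#'
#' Each match occurrence is drawn as its own horizontal segment; lanes
#' are packed greedily (first fit) so non-overlapping occurrences share a
#' lane. The collapsed heatmap is the package default; this view shows
#' individual peptides.
#'
#' @param ms A \code{MatchSet}.
#' @param targets The \code{TargetSet}.
#' @param config A \code{\link{plotConfig}}.
#' @param file Optional output image path.
#' @return Invisibly, a list with \code{plot} and \code{file}.
#' @export
renderPeptideLanes <- function(ms, targets, config = plotConfig(),
                               file = NULL) {
  m <- as.data.frame(matches(ms)[, c("record_id", "target_id", "start",
                                     "end"), drop = FALSE])
  if (!nrow(m) && !isTRUE(config$allow_empty))
    stop("empty match table (use allow_empty to render empty axes)")
  m <- m[order(m$target_id, m$start, m$end), , drop = FALSE]
  m$lane <- NA_integer_
  for (tid in unique(m$target_id)) {
    idx <- which(m$target_id == tid)
    lane_end <- numeric(0)
    for (i in idx) {
      fit <- which(lane_end < m$start[i])
      lane <- if (length(fit)) fit[1] else length(lane_end) + 1L
      lane_end[lane] <- m$end[i]
      m$lane[i] <- lane
    }
  }
  lens <- setNames(width(targetSequences(targets)), targetIds(targets))
  p <- ggplot2::ggplot(m) +
    ggplot2::geom_segment(ggplot2::aes(x = start - 0.5, xend = end + 0.5,
                                       y = lane, yend = lane),
                          linewidth = 2, color = "#2C7FB8") +
    ggplot2::facet_grid(cols = ggplot2::vars(target_id),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "residue position", y = "lane") +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(file)) {
    openDevice(file, config)
    print(p)
    grDevices::dev.off()
  }
  invisible(list(plot = p, file = file))
}
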