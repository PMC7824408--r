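# Virtual gel rendering: deterministic SVG and fixed-grid text output.
# Band mobility follows the standard log-size model
#   m(L) = clamp(a - b * log10(L), 0, 1),
# with 0 the well and 1 the gel front.

#' Gel rendering parameters
#'
#' @param intercept_a,slope_b Mobility model constants
#'   (`m(L) = clamp(a - b*log10(L), 0, 1)`); `slope_b` must be positive.
#'   When omitted, they are auto-fitted per gel so the largest and smallest
#'   visible bands map to 0.05 and 0.95 of the gel height (see
#'   [render_gel()]).
#' @param min_visible Bands below this size (nt) are excluded before
#'   rendering (default 15).
#' @param gel_height_px,lane_width_px SVG geometry (pixels).
#' @param text_rows Number of rows of the text rendering grid (default 40).
#' @return An object of class `dmcc_gel_params`.
#' @export
gel_params <- function(intercept_a = NULL, slope_b = NULL, min_visible = 15L,
                       gel_height_px = 420L, lane_width_px = 70L,
                       text_rows = 40L) {
  if (!is.null(slope_b) && slope_b <= 0)
    stop("slope_b must be > 0", call. = FALSE)
  structure(list(intercept_a = intercept_a, slope_b = slope_b,
                 min_visible = as.integer(min_visible),
                 gel_height_px = as.integer(gel_height_px),
                 lane_width_px = as.integer(lane_width_px),
                 text_rows = as.integer(text_rows)),
            class = "dmcc_gel_params")
}

#' A single gel lane
#'
#' @param label Lane label.
#' @param band_sizes Fragment sizes in nt (stored descending).
#' @param is_ladder Is this a reference/ladder lane (rendered
#'   distinguished)?
#' @return An object of class `dmcc_gel_lane`.
#' @export
gel_lane <- function(label, band_sizes, is_ladder = FALSE) {
  band_sizes <- as.integer(sort(band_sizes, decreasing = TRUE))
  stopifnot(all(band_sizes >= 1L))
  structure(list(label = label, band_sizes = band_sizes,
                 is_ladder = isTRUE(is_ladder)), class = "dmcc_gel_lane")
}

#' Relative band mobility
#'
#' `m(L) = clamp(a - b * log10(L), 0, 1)`: strictly decreasing in fragment
#' size wherever unclamped, so smaller fragments run further.
#'
#' @param size Fragment size in nt (>= 1).
#' @param params A [gel_params()] with `intercept_a` and `slope_b` set.
#' @return Relative mobility in `[0, 1]`.
#' @examples
#' migration(100, gel_params(intercept_a = 2, slope_b = 0.5))  # 1
#' @export
migration <- function(size, params) {
  stopifnot(inherits(params, "dmcc_gel_params"))
  if (any(size < 1)) stop("fragment size must be >= 1 nt", call. = FALSE)
  if (is.null(params$intercept_a) || is.null(params$slope_b))
    stop("gel params lack mobility constants; use auto-fit via render_gel()",
         call. = FALSE)
  m <- params$intercept_a - params$slope_b * log10(size)
  pmin(pmax(m, 0), 1)
}

# fit a, b so that the extreme visible sizes land at 0.05 and 0.95
auto_fit_mobility <- function(params, sizes) {
  lo <- min(sizes); hi <- max(sizes)
  if (hi == lo) {
    b <- 1
    a <- 0.5 + b * log10(hi)
  } else {
    b <- (0.95 - 0.05) / (log10(hi) - log10(lo))
    a <- 0.05 + b * log10(hi)
  }
  params$intercept_a <- a
  params$slope_b <- b
  params
}

#' Render lanes as a virtual gel
#'
#' Deterministic rendering (byte-identical across runs for identical
#' input): no timestamps, no random ids. Lanes appear in the given order;
#' each band sits at [migration()] of its size; ladder lanes are visually
#' distinguished and bands are labelled with their sizes. The text format
#' renders a fixed-height character grid for diffable tests.
#'
#' @param lanes List of [gel_lane()]s (at least one).
#' @param params A [gel_params()]; when its mobility constants are `NULL`
#'   they are auto-fitted to the visible size range of these lanes.
#' @param format `"svg"` or `"text"`.
#' @return A single character scalar: the SVG document or the text grid.
#' @export
render_gel <- function(lanes, params = gel_params(), format = c("svg", "text")) {
  format <- match.arg(format)
  if (length(lanes) == 0L) stop("no lanes to render", call. = FALSE)
  if (inherits(lanes, "dmcc_gel_lane")) lanes <- list(lanes)
  stopifnot(all(vapply(lanes, inherits, TRUE, "dmcc_gel_lane")))
  vis <- lapply(lanes, function(l) l$band_sizes[l$band_sizes >= params$min_visible])
  all_sizes <- unlist(vis)
  if (length(all_sizes) == 0L)
    stop("no visible bands in any lane at min_visible = ",
         params$min_visible, call. = FALSE)
  if (is.null(params$intercept_a) || is.null(params$slope_b))
    params <- auto_fit_mobility(params, all_sizes)
  if (format == "svg") render_gel_svg(lanes, vis, params)
  else render_gel_text(lanes, vis, params)
}

render_gel_svg <- function(lanes, vis, params) {
  lw <- params$lane_width_px
  gh <- params$gel_height_px
  top <- 30L                               # header row for labels
  width <- lw * length(lanes) + 20L
  height <- gh + top + 10L
  fmt <- function(x) formatC(x, format = "f", digits = 1)
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#202030"/>',
            width, height))
  for (i in seq_along(lanes)) {
    lane <- lanes[[i]]
    x0 <- 10L + (i - 1L) * lw
    lane_fill <- if (lane$is_ladder) "#3a3a55" else "#2a2a3f"
    out <- c(out,
      sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
              x0, top, lw - 8L, gh, lane_fill),
      sprintf(paste0('<text x="%s" y="20" fill="#e8e8f0" font-size="11" ',
                     'font-family="monospace" text-anchor="middle">%s</text>'),
              fmt(x0 + (lw - 8L) / 2), xml_escape(lane$label)))
    for (sz in vis[[i]]) {
      y <- top + migration(sz, params) * gh
      band_col <- if (lane$is_ladder) "#9fd3ff" else "#f2f2f2"
      out <- c(out,
        sprintf('<rect x="%d" y="%s" width="%d" height="3" fill="%s"/>',
                x0 + 2L, fmt(y - 1.5), lw - 12L, band_col),
        sprintf(paste0('<text x="%d" y="%s" fill="#c8c8d8" font-size="9" ',
                       'font-family="monospace">%d</text>'),
                x0 + 2L, fmt(y - 3), sz))
    }
  }
  paste0(paste(c(out, "</svg>"), collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_gel_text <- function(lanes, vis, params) {
  rows <- params$text_rows
  col_w <- 12L
  grid <- matrix(" ", nrow = rows, ncol = col_w * length(lanes))
  for (i in seq_along(lanes)) {
    cols <- (i - 1L) * col_w + seq_len(col_w - 2L)
    for (sz in vis[[i]]) {
      r <- 1L + as.integer(round(migration(sz, params) * (rows - 1L)))
      band <- if (lanes[[i]]$is_ladder) "=" else "#"
      label <- formatC(sz, width = 5, flag = " ")
      cells <- c(rep(band, 4L), strsplit(label, "")[[1]])
      grid[r, cols[seq_along(cells)]] <- cells
    }
  }
  header <- vapply(lanes, function(l) {
    lab <- substr(l$label, 1L, col_w - 2L)
    formatC(lab, width = col_w, flag = "-")
  }, "")
  paste0(paste(header, collapse = ""), "\n",
         paste(apply(grid, 1L, paste, collapse = ""), collapse = "\n"), "\n")
}
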