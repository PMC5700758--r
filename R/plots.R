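# Graphical views of an ensemble's PB statistics: distribution map,
# Neq profile, and a WebLogo-like stacked-letter plot.

# PB letter colours for the logo: helix-like blocks in red, strand-like in
# blue, coil in green (the field's usual convention).
.pb_colors <- c(
  a = "#1f78b4", b = "#1f78b4", c = "#1f78b4", d = "#08306b",
  e = "#1f78b4", f = "#1f78b4",
  g = "#33a02c", h = "#33a02c", i = "#33a02c", j = "#33a02c",
  k = "#e31a1c", l = "#e31a1c", m = "#99000d",
  n = "#e31a1c", o = "#e31a1c", p = "#e31a1c")

#' Plot the PB distribution map
#'
#' Heatmap of per-position PB frequencies: residue positions on the x-axis,
#' the 16 PBs `a`..`p` on the y-axis, coloured from blue (frequency 0, the
#' PB is never sampled there) to red (frequency 1, always found there) on a
#' colourblind-safe diverging scale.
#'
#' @param matrix A `pb_count` object.
#' @param residue_min,residue_max Optional inclusive residue frame.
#' @return A ggplot object.
#' @export
plot_pb_map <- function(matrix, residue_min = NULL, residue_max = NULL) {
  freq <- map_data(matrix)
  ids <- matrix$residue_ids
  frame <- .resolve_frame(ids, residue_min, residue_max)
  keep <- which(ids >= frame[1L] & ids <= frame[2L])
  df <- data.frame(
    resid = rep(ids[keep], times = 16L),
    pb = factor(rep(letters[1:16], each = length(keep)),
                levels = letters[1:16]),
    freq = as.vector(freq[keep, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resid, y = .data$pb,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = 0.5,
                                  limits = c(0, 1), name = "frequency") +
    ggplot2::labs(x = "residue number", y = "protein block") +
    ggplot2::theme_minimal()
}

#' Plot an Neq profile
#'
#' @param profile An `neq_profile` from [neq_profile()].
#' @return A ggplot object (Neq versus residue number; the y-axis spans
#'   1 to 16, the theoretical Neq range at assigned positions).
#' @export
plot_neq <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$resid, y = .data$neq)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue number", y = "Neq") +
    ggplot2::coord_cartesian(ylim = c(0, 16)) +
    ggplot2::theme_minimal()
}

#' Plot a WebLogo-like PB frequency logo
#'
#' Stacked letters per position, each PB letter drawn with height
#' proportional to its frequency at that position; the most frequent PB
#' sits on top. Helix-like PBs are drawn in red, strand-like in blue and
#' coil-like in green.
#'
#' @inheritParams plot_pb_map
#' @return A ggplot object.
#' @export
plot_pb_logo <- function(matrix, residue_min = NULL, residue_max = NULL) {
  ld <- logo_data(matrix, residue_min, residue_max)
  rows <- lapply(names(ld), function(id) {
    h <- ld[[id]]
    if (length(h) == 0L) return(NULL)
    # stack from the bottom so the tallest letter ends on top
    h <- rev(h)
    top <- cumsum(h)
    data.frame(resid = as.integer(id), pb = names(h), height = unname(h),
               ymin = top - h, ymax = top)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no assigned positions in the requested frame")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$resid - 0.45,
                                    xmax = .data$resid + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = "white", color = "grey80", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$resid, y = (.data$ymin + .data$ymax) / 2,
      label = .data$pb, color = .data$pb, size = .data$height)) +
    ggplot2::scale_color_manual(values = .pb_colors, guide = "none") +
    ggplot2::scale_size_continuous(range = c(1, 6), guide = "none") +
    ggplot2::labs(x = "residue number", y = "PB frequency") +
    ggplot2::theme_minimal()
}
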