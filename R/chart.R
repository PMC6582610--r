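## Nested pie-chart rendering of a double digest map, written as standalone
## SVG text so that output is byte-identical for a fixed specification.

.svgNum <- function(x) formatC(x, format = "f", digits = 3, drop0trailing = TRUE)

.arcPath <- function(cx, cy, r0, r1, a0, a1) {
  # annulus sector from angle a0 to a1 (radians, 0 = twelve o'clock,
  # increasing clockwise)
  pt <- function(r, a) c(cx + r * sin(a), cy - r * cos(a))
  p1 <- pt(r1, a0); p2 <- pt(r1, a1); p3 <- pt(r0, a1); p4 <- pt(r0, a0)
  large <- as.integer((a1 - a0) %% (2 * pi) > pi)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          .svgNum(p1[1]), .svgNum(p1[2]), .svgNum(r1), .svgNum(r1), large,
          .svgNum(p2[1]), .svgNum(p2[2]), .svgNum(p3[1]), .svgNum(p3[2]),
          .svgNum(r0), .svgNum(r0), large, .svgNum(p4[1]), .svgNum(p4[2]))
}

.ringColors <- function(n, hue) {
  grDevices::hcl(h = hue, c = 45, l = seq(45, 85, length.out = max(n, 2L))[seq_len(n)])
}

#' Render a double digest map as nested pie charts (SVG)
#'
#' Draws three concentric rings -- A-map (outer), B-map (middle), double
#' digest C-map (inner) by default -- with arc lengths proportional to
#' fragment lengths, read clockwise from twelve o'clock. Zero-length
#' fragments (coincident cut sites) are rendered as labelled radial tick
#' marks. Output is deterministic for a fixed specification.
#'
#' @param solution a [SolutionRecord-class]; must be exact (fitness 1)
#'   unless \code{approximate = TRUE}.
#' @param instance the [DDPInstance-class] the solution refers to (padded
#'   internally).
#' @param path output SVG file.
#' @param ringOrder permutation of c("a","b","c") from outer to inner ring.
#' @param startAngle starting angle in degrees clockwise from twelve
#'   o'clock.
#' @param approximate set TRUE to render a non-exact (approximate) map.
#' @param size canvas size in pixels.
#' @return invisibly, \code{path}.
#' @export
renderChart <- function(solution, instance, path,
                        ringOrder = c("a", "b", "c"), startAngle = 0,
                        approximate = FALSE, size = 420) {
  if (!approximate && solution@fitness != 1)
    stop("solution is not exact; pass approximate = TRUE to render anyway")
  instance <- padToCanonical(instance)
  aMap <- permuteFragments(instance@a, solution@mu)
  bMap <- permuteFragments(instance@b, solution@nu)
  cMap <- solution@dds
  L <- sum(aMap)
  if (sum(bMap) != L || sum(cMap) != L)
    stop("ring totals disagree; solution does not match instance")
  if (!setequal(ringOrder, c("a", "b", "c")))
    stop("ringOrder must be a permutation of a, b, c")

  rings <- list(a = list(frag = aMap, hue = 10, label = "A"),
                b = list(frag = bMap, hue = 130, label = "B"),
                c = list(frag = cMap, hue = 250, label = "C"))[ringOrder]
  cx <- size / 2; cy <- size / 2
  radii <- seq(size * 0.46, size * 0.10, length.out = 4L)

  out <- c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                          "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
                   size, size, size, size),
           sprintf("<!-- total length %d; rings outer to inner: %s -->",
                   L, paste(ringOrder, collapse = ",")))
  for (r in seq_along(rings)) {
    frag <- rings[[r]]$frag
    cols <- .ringColors(length(frag), rings[[r]]$hue)
    r1 <- radii[r]; r0 <- radii[r + 1L]
    ang <- startAngle * pi / 180 + 2 * pi * c(0, cumsum(frag)) / L
    out <- c(out, sprintf("<g id=\"ring-%s\">", names(rings)[r]))
    for (i in seq_along(frag)) {
      if (frag[i] == 0L) {
        # coincident cut: radial tick with a zero label
        x0 <- cx + r0 * sin(ang[i]); y0 <- cy - r0 * cos(ang[i])
        x1 <- cx + r1 * sin(ang[i]); y1 <- cy - r1 * cos(ang[i])
        out <- c(out, sprintf(paste0("<line class=\"zero-fragment\" ",
          "x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"black\" ",
          "stroke-width=\"2\"/>"),
          .svgNum(x0), .svgNum(y0), .svgNum(x1), .svgNum(y1)),
          sprintf("<text x=\"%s\" y=\"%s\" font-size=\"9\">0</text>",
                  .svgNum(x1), .svgNum(y1)))
      } else {
        mid <- (ang[i] + ang[i + 1L]) / 2
        rm <- (r0 + r1) / 2
        # a single full-turn fragment degenerates as an SVG arc; nick it
        if (ang[i + 1L] - ang[i] >= 2 * pi) ang[i + 1L] <- ang[i] + 2 * pi - 1e-3
        out <- c(out,
          sprintf("<path d=\"%s\" fill=\"%s\" stroke=\"white\"/>",
                  .arcPath(cx, cy, r0, r1, ang[i], ang[i + 1L]), cols[i]),
          sprintf("<text x=\"%s\" y=\"%s\" font-size=\"10\" text-anchor=\"middle\">%d</text>",
                  .svgNum(cx + rm * sin(mid)), .svgNum(cy - rm * cos(mid)),
                  frag[i]))
      }
    }
    out <- c(out, "</g>")
  }
  out <- c(out, sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"12\" ",
                               "text-anchor=\"middle\">%s (L = %d)</text>"),
                        .svgNum(cx), .svgNum(cy), instance@name, L),
           "</svg>")
  writeLines(out, path)
  invisible(path)
}
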