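# Deterministic SVG output of a Collier de Perles layout: one bead per
# slot (squares for anchors), residue letters, conserved-position
# emphasis, and optional difference / hydrogen-bond overlays. Output is
# byte-identical for identical inputs: fixed attribute order, fixed
# 2-decimal precision, no metadata.

#' Rendering style for Collier de Perles plots
#'
#' Colors and conventions. The field's standard conventions are the
#' defaults:
#' hydrophobic beads blue, CDR1/2/3 accents red/orange/purple, conserved
#' letters red and bold, anchors drawn as squares, difference borders
#' pink, hydrogen bonds green. All other colors (volume classes, the 11
#' physicochemical classes, ...) are a documented package palette.
#'
#' @param mode One of \code{"hydropathy"}, \code{"volume"},
#'   \code{"physicochemical"}, \code{"profile50"} (hydrophobic positions
#'   at the 50 percent threshold), \code{"profile80"} (dominant class at
#'   the 80 percent threshold).
#' @param ... Named style overrides (see the returned list for keys).
#' @return Named list of class \code{cdp_style}.
#' @export
render_style <- function(mode = c("hydropathy", "volume", "physicochemical",
                                  "profile50", "profile80"), ...) {
  mode <- match.arg(mode)
  style <- list(
    mode = mode,
    palettes = list(
      hydropathy = c(hydrophobic = "#1f77b4", neutral = "#bdbdbd",
                     hydrophilic = "#ff7f0e"),
      volume = c(very_small = "#edf8e9", small = "#bae4b3",
                 medium = "#74c476", large = "#31a354",
                 very_large = "#006d2c"),
      physicochemical = c(alanine = "#8dd3c7", cysteine = "#ffffb3",
                          acidic = "#fb8072", aromatic = "#bebada",
                          glycine = "#80b1d3", histidine = "#fdb462",
                          aliphatic = "#b3de69", basic = "#fccde5",
                          methionine = "#d9d9d9", polar = "#bc80bd",
                          proline = "#ccebc5")),
    hydrophobic_fill = "#1f77b4",
    default_fill = "#ffffff",
    gap_stroke = "#bbbbbb",
    bead_stroke = "#333333",
    cdr_colors = c("CDR1-IMGT" = "#d62728", "CDR2-IMGT" = "#ff7f0e",
                   "CDR3-IMGT" = "#9467bd"),
    conserved_color = "#d62728",
    difference_stroke = "#ff69b4",
    hbond_color = "#2ca02c",
    backbone_color = "#cccccc",
    text_color = "#000000",
    profile_dimension = "physicochemical",
    threshold50 = 0.5,
    threshold80 = 0.8,
    scale = 40,
    margin = 1.2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(style))
  if (length(unknown))
    stop("unknown style key(s): ", paste(unknown, collapse = ", "))
  style[names(dots)] <- dots
  structure(style, class = "cdp_style")
}

num2 <- function(x) sprintf("%.2f", x)

#' Render a Collier de Perles as SVG
#'
#' @param layout A \code{cdp_layout} of \code{g} (one- or two-layer).
#' @param g The \code{gapped_domain} being drawn.
#' @param style A \code{cdp_style} from [render_style()].
#' @param profile A \code{position_profile}; required for the
#'   \code{profile50} / \code{profile80} modes.
#' @param differences Positions to highlight with the difference border:
#'   a character vector of slot labels or a \code{cdp_comparison} (its
#'   substitution and length-difference positions are used).
#' @param hbonds data.frame from [detect_hbonds()] (columns \code{donor},
#'   \code{acceptor}); drawn as green lines between bead centers.
#' @param path Optional output file; the document is also returned.
#' @return The SVG document as a single character string, invisibly if
#'   \code{path} is given.
#' @export
render_svg <- function(layout, g, style = render_style(), profile = NULL,
                       differences = NULL, hbonds = NULL, path = NULL) {
  stopifnot(inherits(layout, "cdp_layout"), inherits(g, "gapped_domain"),
            inherits(style, "cdp_style"))
  beads <- layout$beads
  slots <- g$slots
  if (!identical(beads$position, slots$position))
    stop("layout and domain do not share the same slots")
  if (style$mode %in% c("profile50", "profile80") && is.null(profile))
    stop("mode ", sQuote(style$mode), " requires a profile")
  if (inherits(differences, "cdp_comparison"))
    differences <- c(differences$substitutions$position,
                     differences$length_differences$position)
  sc <- style$scale
  r <- layout$geometry$bead_radius * sc
  px <- (beads$x - min(beads$x) + style$margin) * sc
  py <- (beads$y - min(beads$y) + style$margin) * sc
  width <- max(px) + style$margin * sc
  height <- max(py) + style$margin * sc
  conserved <- as.character(scheme_constants()$conserved)
  anchors <- as.character(scheme_constants()$anchors)
  table <- imgt_class_table()
  hydro50 <- if (style$mode == "profile50")
    hydrophobic_positions(profile, style$threshold50)
  fill_of <- function(i) {
    pos <- beads$position[i]
    res <- slots$residue[i]
    switch(style$mode,
      hydropathy = , volume = , physicochemical = {
        if (is.na(res)) return(style$default_fill)
        cl <- classify(res, table)[[style$mode]]
        if (is.na(cl)) style$default_fill else style$palettes[[style$mode]][[cl]]
      },
      profile50 = if (pos %in% hydro50) style$hydrophobic_fill
                  else style$default_fill,
      profile80 = {
        cl <- dominant_class(profile, pos, style$profile_dimension,
                             style$threshold80)
        if (is.na(cl)) style$default_fill
        else style$palettes[[style$profile_dimension]][[cl]]
      })
  }
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   num2(width), num2(height), num2(width), num2(height)))
  # backbone path per layer (consecutive slots of the same layer)
  for (L in unique(beads$layer)) {
    idx <- which(beads$layer == L)
    segs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    dstr <- vapply(segs, function(is) {
      paste0("M", num2(px[is[1L]]), " ", num2(py[is[1L]]),
             paste0(vapply(is[-1L], function(i)
               paste0(" L", num2(px[i]), " ", num2(py[i])), ""),
               collapse = ""))
    }, "")
    out <- c(out, sprintf('<path class="backbone" d="%s" fill="none" stroke="%s" stroke-width="1.00"/>',
                          paste(dstr, collapse = " "), style$backbone_color))
  }
  if (!is.null(hbonds) && nrow(hbonds)) {
    di <- match(as.character(hbonds$donor), beads$position)
    ai <- match(as.character(hbonds$acceptor), beads$position)
    if (anyNA(di) || anyNA(ai))
      stop("hydrogen bond references a position absent from the layout")
    out <- c(out, sprintf(
      '<line class="hbond" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2.00"/>',
      num2(px[di]), num2(py[di]), num2(px[ai]), num2(py[ai]),
      style$hbond_color))
  }
  for (i in seq_len(nrow(beads))) {
    pos <- beads$position[i]
    res <- slots$residue[i]
    is_gap <- is.na(res)
    fill <- fill_of(i)
    stroke <- if (pos %in% differences) style$difference_stroke
      else if (is_gap) style$gap_stroke
      else if (slots$region[i] %in% names(style$cdr_colors))
        style$cdr_colors[[slots$region[i]]]
      else style$bead_stroke
    swidth <- if (pos %in% differences) "3.00" else "1.50"
    if (pos %in% anchors) {
      out <- c(out, sprintf(
        '<rect class="bead anchor" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
        num2(px[i] - r), num2(py[i] - r), num2(2 * r), num2(2 * r),
        fill, stroke, swidth))
    } else {
      out <- c(out, sprintf(
        '<circle class="bead" cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
        num2(px[i]), num2(py[i]), num2(r), fill, stroke, swidth))
    }
    if (!is_gap) {
      cons <- pos %in% conserved
      out <- c(out, sprintf(
        '<text class="label%s" x="%s" y="%s" text-anchor="middle" dominant-baseline="central" font-family="monospace" font-size="%s" font-weight="%s" fill="%s">%s</text>',
        if (cons) " conserved" else "", num2(px[i]), num2(py[i]),
        num2(r * 1.2), if (cons) "bold" else "normal",
        if (cons) style$conserved_color else style$text_color, res))
    }
  }
  out <- c(out, "</svg>")
  doc <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
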