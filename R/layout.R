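# 2D bead coordinates for the one-layer and two-layer Collier de Perles.
# Strands are vertical serpentine columns, CDR loops are arcs above the
# junctions; the two-layer view splits the 9 strands over two sheets.

#' Layout geometry configuration
#'
#' Geometry constants in abstract bead units. Defaults are packaged in
#' \code{inst/extdata/geometry.cfg}; a user file with \code{key=value}
#' lines (\code{#} comments allowed) overrides individual keys.
#'
#' @param path Optional path to a key=value geometry file.
#' @return Named list: \code{spacing}, \code{bead_radius},
#'   \code{arc_height_per_bead}, \code{max_step}, \code{layer_dx},
#'   \code{layer_dy}.
#' @export
cdp_geometry <- function(path = NULL) {
  geom <- list(spacing = 1.0, bead_radius = 0.35, arc_height_per_bead = 0.3,
               max_step = 1.6, layer_dx = 0.35, layer_dy = 0.25)
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("malformed geometry line: ", sQuote(ln))
      key <- trimws(kv[[1L]])
      if (!key %in% names(geom))
        stop("unknown geometry key: ", sQuote(key))
      val <- suppressWarnings(as.numeric(trimws(kv[[2L]])))
      if (is.na(val)) stop("non-numeric geometry value for ", sQuote(key))
      geom[[key]] <- val
    }
  }
  geom
}

#' The V-domain strand table
#'
#' Nine beta strands (A, B, C, C-prime, C-second, D, E, F, G) with their
#' IMGT position ranges and their sheet (front/back) for the two-layer
#' display. The packaged defaults tile the four FR-IMGT regions exactly;
#' the front/back split is G, F, C, C-prime, C-second versus A, B, E, D.
#'
#' @param path Optional path to a replacement TSV (columns \code{strand},
#'   \code{start}, \code{end}, \code{sheet}, \code{sheet_order}).
#' @return data.frame with the 9 strands, validated to cover the FR-IMGT
#'   positions exactly.
#' @export
v_strand_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "v_strands.tsv", package = "collier")
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("strand", "start", "end", "sheet", "sheet_order")
  if (!all(needed %in% names(tab)))
    stop("strand table is missing column(s): ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  if (nrow(tab) != 9L)
    stop("a V domain has 9 strands, table has ", nrow(tab))
  covered <- sort(unlist(Map(seq.int, tab$start, tab$end)))
  reg <- scheme_constants()$regions
  fr <- reg[grepl("^FR", reg$region), ]
  fr_positions <- sort(unlist(Map(seq.int, fr$start, fr$end)))
  if (!identical(as.integer(covered), as.integer(fr_positions)))
    stop("strand ranges must tile the FR-IMGT positions exactly")
  if (!all(tab$sheet %in% c("front", "back")))
    stop("strand sheet must be 'front' or 'back'")
  tab[order(tab$start), ]
}

# Block label per slot: strand name for FR positions, CDR1/2/3 for loops.
slot_blocks <- function(slots, strands) {
  block <- character(nrow(slots))
  cdr <- grepl("^CDR", slots$region)
  block[cdr] <- sub("-IMGT$", "", slots$region[cdr])
  for (i in seq_len(nrow(strands))) {
    sel <- !cdr & slots$number >= strands$start[i] &
      slots$number <= strands$end[i]
    block[sel] <- strands$strand[i]
  }
  block
}

# Shared placement engine. Strand columns run vertically with serpentine
# (alternating) direction; a strand chains from the previous strand of the
# same layer when the backbone connects them (directly or through a loop
# of that layer), otherwise it starts a fresh sub-path. Loops are arcs
# above the junction between their flanking strand endpoints.
layout_engine <- function(g, geometry, strands, layers) {
  slots <- g$slots
  n <- nrow(slots)
  block <- slot_blocks(slots, strands)
  runs <- rle(block)
  nruns <- length(runs$values)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  is_strand <- runs$values %in% strands$strand
  # loop layer = layer of the following strand
  run_layer <- character(nruns)
  run_layer[is_strand] <- layers[runs$values[is_strand]]
  for (r in which(!is_strand)) {
    nxt <- which(is_strand & seq_len(nruns) > r)[1L]
    run_layer[r] <- if (is.na(nxt)) run_layer[r - 1L] else run_layer[nxt]
  }
  sp <- geometry$spacing
  layer_names <- unique(run_layer)
  # column x per strand within its layer
  if (identical(layer_names, "single")) {
    colx <- stats::setNames(seq_len(sum(is_strand)) * sp,
                            runs$values[is_strand])
    offs <- list(single = c(0, 0))
  } else {
    colx <- stats::setNames(numeric(nrow(strands)), strands$strand)
    for (sh in unique(strands$sheet)) {
      sub <- strands[strands$sheet == sh, ]
      colx[sub$strand[order(sub$sheet_order)]] <-
        seq_len(nrow(sub)) * sp
    }
    offs <- list(front = c(0, 0),
                 back = c(geometry$layer_dx, geometry$layer_dy))
  }
  x <- y <- numeric(n)
  layer_of_slot <- character(n)
  dirdown <- stats::setNames(rep(TRUE, length(layer_names)), layer_names)
  strand_first <- strand_last <- vector("list", nruns)  # bead coords
  # pass 1: strands
  for (r in seq_len(nruns)) {
    if (!is_strand[r]) next
    L <- run_layer[r]
    off <- offs[[L]]
    len <- runs$lengths[r]
    xs <- colx[[runs$values[r]]] + off[[1L]]
    # chain from the previous strand of this layer when the backbone
    # connects to it directly or through a same-layer loop
    prev_r <- r - 1L
    if (prev_r >= 1L && !is_strand[prev_r] && run_layer[prev_r] == L)
      prev_r <- prev_r - 1L
    chained <- prev_r >= 1L && is_strand[prev_r] && run_layer[prev_r] == L
    down <- dirdown[[L]]
    y0 <- if (chained) strand_last[[prev_r]][[2L]]
          else if (down) off[[2L]] else off[[2L]] + (len - 1L) * sp
    ys <- y0 + (seq_len(len) - 1L) * sp * (if (down) 1 else -1)
    idx <- run_start[r]:run_end[r]
    x[idx] <- xs
    y[idx] <- ys
    layer_of_slot[idx] <- L
    strand_first[[r]] <- c(xs, ys[[1L]])
    strand_last[[r]] <- c(xs, ys[[len]])
    dirdown[[L]] <- !down
  }
  # pass 2: loops (arcs above the junction)
  for (r in seq_len(nruns)) {
    if (is_strand[r]) next
    L <- run_layer[r]
    len <- runs$lengths[r]
    nxt <- which(is_strand & seq_len(nruns) > r)[1L]
    if (is.na(nxt))
      stop("a CDR loop must be followed by a strand")   # nocov
    p1 <- strand_first[[nxt]]
    prev_r <- r - 1L
    p0 <- if (prev_r >= 1L && is_strand[prev_r] && run_layer[prev_r] == L)
      strand_last[[prev_r]] else c(p1[[1L]] - sp, p1[[2L]])
    h <- geometry$arc_height_per_bead * (len + 1L) * sp
    t <- seq_len(len) / (len + 1L)
    idx <- run_start[r]:run_end[r]
    x[idx] <- p0[[1L]] + (p1[[1L]] - p0[[1L]]) * t
    y[idx] <- p0[[2L]] + (p1[[2L]] - p0[[2L]]) * t - h * sin(pi * t)
    layer_of_slot[idx] <- L
  }
  out <- data.frame(position = slots$position, x = x, y = y,
                    layer = layer_of_slot, block = block,
                    stringsAsFactors = FALSE)
  blocks <- data.frame(block = runs$values,
                       kind = ifelse(is_strand, "strand", "loop"),
                       layer = run_layer, n_slots = runs$lengths,
                       stringsAsFactors = FALSE)
  structure(list(beads = out, blocks = blocks, geometry = geometry),
            class = "cdp_layout")
}

#' One-layer Collier de Perles layout
#'
#' Places every slot of a gapped domain (gaps included) on the plane: the
#' nine strands as consecutive vertical serpentine columns, the three CDR
#' loops as arcs above the strand junctions. Consecutive slots are always
#' within the geometry's \code{max_step} of each other.
#'
#' @param g A \code{gapped_domain}.
#' @param geometry Geometry list from [cdp_geometry()].
#' @param strands Strand table from [v_strand_table()].
#' @return An object of class \code{cdp_layout}: \code{beads} (data.frame:
#'   \code{position}, \code{x}, \code{y}, \code{layer}, \code{block}),
#'   \code{blocks} (block summary: 9 strands + 3 loops), \code{geometry}.
#' @export
layout_one_layer <- function(g, geometry = cdp_geometry(),
                             strands = v_strand_table()) {
  stopifnot(inherits(g, "gapped_domain"))
  layers <- stats::setNames(rep("single", nrow(strands)), strands$strand)
  layout_engine(g, geometry, strands, layers)
}

#' Two-layer Collier de Perles layout
#'
#' Like [layout_one_layer()], but each strand is assigned to one of the
#' two sheets of the V-domain sandwich (default front G, F, C, C-prime,
#' C-second; back A, B, E, D) and laid out
#' within its own layer; the back layer is offset by the geometry's
#' \code{layer_dx}/\code{layer_dy}. CDR loops are drawn on the layer of
#' the strand that follows them.
#'
#' @inheritParams layout_one_layer
#' @return A \code{cdp_layout} whose \code{layer} column is \code{"front"}
#'   or \code{"back"}.
#' @export
layout_two_layers <- function(g, geometry = cdp_geometry(),
                              strands = v_strand_table()) {
  stopifnot(inherits(g, "gapped_domain"))
  layers <- stats::setNames(strands$sheet, strands$strand)
  layout_engine(g, geometry, strands, layers)
}

#' Write a layout as TSV
#'
#' @param layout A \code{cdp_layout}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  stopifnot(inherits(layout, "cdp_layout"))
  utils::write.table(layout$beads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
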