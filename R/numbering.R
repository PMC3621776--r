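# IMGT unique numbering for V domains: 128 positions, FR/CDR delimitations,
# conserved positions, anchors, and top-of-loop gap placement.

#' IMGT V-domain numbering scheme constants
#'
#' The IMGT unique numbering assigns V-domain residues to positions 1-128,
#' tiled into standardized framework (FR-IMGT) and complementarity
#' determining (CDR-IMGT) regions: FR1 1-26, CDR1 27-38, FR2 39-55,
#' CDR2 56-65, FR3 66-104, CDR3 105-117, FR4 118-128. Five positions are
#' conserved across V domains (1st-CYS 23, CONSERVED-TRP 41, hydrophobic 89,
#' 2nd-CYS 104, J-PHE or J-TRP 118) and six framework anchors (26, 39, 55,
#' 66, 104, 118) flank and support the three CDR loops.
#'
#' @return A list with components:
#'   \describe{
#'     \item{regions}{data.frame with columns \code{region}, \code{start},
#'       \code{end} tiling positions 1-128.}
#'     \item{conserved}{named integer vector of the 5 conserved positions;
#'       names give their role.}
#'     \item{anchors}{integer vector of the 6 anchor positions.}
#'     \item{cdr_capacity}{named integer vector, maximum residues per CDR
#'       before insertion positions are needed (12, 10, 13).}
#'   }
#' @examples
#' sc <- scheme_constants()
#' sc$conserved
#' sc$anchors
#' @export
scheme_constants <- function() {
  regions <- data.frame(
    region = c("FR1-IMGT", "CDR1-IMGT", "FR2-IMGT", "CDR2-IMGT",
               "FR3-IMGT", "CDR3-IMGT", "FR4-IMGT"),
    start  = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
    end    = c(26L, 38L, 55L, 65L, 104L, 117L, 128L),
    stringsAsFactors = FALSE
  )
  list(
    regions = regions,
    conserved = c("1st-CYS" = 23L, "CONSERVED-TRP" = 41L,
                  "hydrophobic" = 89L, "2nd-CYS" = 104L,
                  "J-PHE-or-J-TRP" = 118L),
    anchors = c(26L, 39L, 55L, 66L, 104L, 118L),
    cdr_capacity = c("CDR1-IMGT" = 12L, "CDR2-IMGT" = 10L, "CDR3-IMGT" = 13L)
  )
}

# Parse a position label ("89", "111.1") into number + insertion suffix.
# Returns list(number, insertion); insertion is NA for plain positions.
parse_position <- function(label) {
  label <- as.character(label)
  parts <- strsplit(label, ".", fixed = TRUE)
  num <- vapply(parts, function(p) suppressWarnings(as.integer(p[[1L]])), 1L)
  ins <- vapply(parts, function(p)
    if (length(p) > 1L) suppressWarnings(as.integer(p[[2L]])) else NA_integer_, 1L)
  bad <- is.na(num) | vapply(parts, length, 1L) > 2L
  if (any(bad))
    stop("malformed IMGT position label: ", paste(label[bad], collapse = ", "))
  if (any(!is.na(ins) & (!(num %in% c(111L, 112L)) | ins < 1L)))
    stop("insertion suffixes are only defined on positions 111 and 112 ",
         "(offending label: ",
         paste(label[!is.na(ins) & (!(num %in% c(111L, 112L)) | ins < 1L)],
               collapse = ", "), ")")
  list(number = num, insertion = ins)
}

#' Region of an IMGT position
#'
#' Maps a position (1-128, or a CDR3 insertion label such as \code{"111.1"})
#' to the FR-IMGT / CDR-IMGT region that contains it.
#'
#' @param position Integer position or character label (insertion labels
#'   \code{"111.<k>"} / \code{"112.<k>"} allowed). Vectorized.
#' @return Character vector of region labels
#'   (\code{"FR1-IMGT"} ... \code{"FR4-IMGT"},
#'    \code{"CDR1-IMGT"} ... \code{"CDR3-IMGT"}).
#' @examples
#' region_of(104)       # "FR3-IMGT"
#' region_of("111.1")   # "CDR3-IMGT"
#' @export
region_of <- function(position) {
  p <- parse_position(position)
  if (any(p$number < 1L | p$number > 128L))
    stop("IMGT position out of range 1-128: ",
         paste(p$number[p$number < 1L | p$number > 128L], collapse = ", "))
  reg <- scheme_constants()$regions
  idx <- vapply(p$number, function(n) which(reg$start <= n & reg$end >= n), 1L)
  reg$region[idx]
}

# Region bounds lookup by short or long CDR name ("CDR1" or "CDR1-IMGT").
cdr_region_row <- function(region) {
  region <- sub("-IMGT$", "", toupper(region))
  if (!region %in% c("CDR1", "CDR2", "CDR3"))
    stop("not a CDR region: ", region)
  reg <- scheme_constants()$regions
  reg[reg$region == paste0(region, "-IMGT"), ]
}

#' Gap positions for a CDR of a given length
#'
#' IMGT gapping places missing CDR positions "at the top of the loop": the
#' occupied positions of a CDR of observed length \code{L} are the first
#' \code{ceiling(L/2)} and the last \code{floor(L/2)} positions of the
#' region, and the remaining middle positions are gapped. This closed form
#' is equivalent to removing positions middle-out (CDR3: 111, 112, 110,
#' 113, ...; CDR1: 33, 32, 34, 31, ...; CDR2: 61, 60, 62, 59, ...).
#'
#' @param region \code{"CDR1"}, \code{"CDR2"} or \code{"CDR3"}
#'   (\code{-IMGT} suffix accepted).
#' @param observed_length Integer number of residues actually present,
#'   between 0 and the region capacity (12/10/13). CDR3 lengths above 13
#'   take insertion positions instead, see [extra_positions()].
#' @return Sorted integer vector of gapped (empty) positions; length equals
#'   capacity minus \code{observed_length}.
#' @examples
#' gap_positions("CDR1", 8)  # 31 32 33 34
#' gap_positions("CDR3", 9)  # 110 111 112 113
#' @export
gap_positions <- function(region, observed_length) {
  row <- cdr_region_row(region)
  capacity <- row$end - row$start + 1L
  observed_length <- as.integer(observed_length)
  if (length(observed_length) != 1L || is.na(observed_length) ||
      observed_length < 0L || observed_length > capacity)
    stop("observed length for ", row$region, " must be in 0..", capacity,
         " (got ", observed_length, ")")
  positions <- seq.int(row$start, row$end)
  keep_head <- ceiling(observed_length / 2)
  keep_tail <- floor(observed_length / 2)
  occupied <- c(utils::head(positions, keep_head),
                utils::tail(positions, keep_tail))
  sort(setdiff(positions, occupied))
}

#' Insertion positions for a long CDR3
#'
#' CDR3 loops longer than the 13-position capacity take insertion positions
#' at the top of the loop, labelled \code{112.1, 111.1, 112.2, 111.2, ...}
#' in order of addition. In display order the loop runs
#' \code{..., 111, 111.1, ..., 111.k, 112.m, ..., 112.1, 112, ...}.
#'
#' @param cdr3_length Integer CDR3 length, greater than 13.
#' @param max_extra Maximum number of insertions supported (default 20,
#'   i.e. CDR3 lengths up to 33).
#' @return Character vector of insertion labels in order of addition
#'   (\code{"112.1"}, \code{"111.1"}, ...), length \code{cdr3_length - 13}.
#' @examples
#' extra_positions(14)  # "112.1"
#' extra_positions(15)  # "112.1" "111.1"
#' @export
extra_positions <- function(cdr3_length, max_extra = 20L) {
  cdr3_length <- as.integer(cdr3_length)
  if (length(cdr3_length) != 1L || is.na(cdr3_length) || cdr3_length <= 13L)
    stop("extra_positions applies to CDR3 lengths above 13 (got ",
         cdr3_length, ")")
  n_extra <- cdr3_length - 13L
  if (n_extra > max_extra)
    stop("CDR3 length ", cdr3_length, " exceeds the configured maximum of ",
         13L + max_extra)
  i <- seq_len(n_extra)
  ifelse(i %% 2L == 1L,
         paste0("112.", (i + 1L) %/% 2L),
         paste0("111.", i %/% 2L))
}

#' Slot labels of a V domain in display order
#'
#' The ordered position labels of a numbered V domain: \code{1..128}, with
#' any CDR3 insertions interleaved in display order
#' (\code{111, 111.1, ..., 112.1, 112}).
#'
#' @param n_extra Number of CDR3 insertion positions (0 for standard
#'   domains).
#' @return Character vector of slot labels, length \code{128 + n_extra}.
#' @export
v_slots <- function(n_extra = 0L) {
  n_extra <- as.integer(n_extra)
  stopifnot(length(n_extra) == 1L, !is.na(n_extra), n_extra >= 0L)
  if (n_extra == 0L) return(as.character(1:128))
  ins <- extra_positions(13L + n_extra)
  i111 <- ins[startsWith(ins, "111.")]
  i112 <- ins[startsWith(ins, "112.")]
  # suffixes ascending after 111, descending before 112
  i111 <- i111[order(as.integer(sub("^111\\.", "", i111)))]
  i112 <- i112[order(as.integer(sub("^112\\.", "", i112)), decreasing = TRUE)]
  c(as.character(1:111), i111, i112, as.character(112:128))
}
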