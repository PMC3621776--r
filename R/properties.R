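# IMGT amino acid property classes: hydropathy (3), volume (5),
# physicochemical (11). Memberships are data (inst/extdata), not code.

AA_STANDARD20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HYDROPATHY_CLASSES <- c("hydrophobic", "neutral", "hydrophilic")

#' Load the IMGT amino acid classification table
#'
#' Reads the packaged table assigning each of the 20 standard residues to
#' one hydropathy class (hydrophobic / neutral / hydrophilic), one of 5
#' volume classes and one of 11 physicochemical classes. Each dimension is
#' validated to partition the 20 residues.
#'
#' @param path Path to a tab-separated table with columns \code{residue},
#'   \code{hydropathy}, \code{volume}, \code{physicochemical}; lines
#'   starting with \code{#} are comments. Defaults to the packaged table.
#' @return An object of class \code{aa_class_table}: a list with
#'   \code{entries} (data.frame, one row per residue) and \code{catalogs}
#'   (list of class-name vectors per dimension).
#' @examples
#' tab <- load_class_tables()
#' nrow(tab$entries)                     # 20
#' lengths(tab$catalogs)                 # 3, 5, 11
#' @export
load_class_tables <- function(path = system.file("extdata",
                                                 "imgt_aa_classes.tsv",
                                                 package = "collier")) {
  entries <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE)
  needed <- c("residue", "hydropathy", "volume", "physicochemical")
  if (!all(needed %in% names(entries)))
    stop("classification table is missing column(s): ",
         paste(setdiff(needed, names(entries)), collapse = ", "))
  entries$residue <- toupper(entries$residue)
  if (anyDuplicated(entries$residue))
    stop("duplicate residue in classification table: ",
         paste(unique(entries$residue[duplicated(entries$residue)]),
               collapse = ", "))
  missing <- setdiff(AA_STANDARD20, entries$residue)
  if (length(missing))
    stop("classification table is missing residue(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(entries$residue, AA_STANDARD20)
  if (length(unknown))
    stop("classification table has non-standard residue(s): ",
         paste(unknown, collapse = ", "))
  bad_h <- setdiff(unique(entries$hydropathy), HYDROPATHY_CLASSES)
  if (length(bad_h))
    stop("unknown hydropathy class name(s): ", paste(bad_h, collapse = ", "))
  catalogs <- list(
    hydropathy = HYDROPATHY_CLASSES,
    volume = unique(entries$volume),
    physicochemical = unique(entries$physicochemical)
  )
  if (length(unique(entries$hydropathy)) != 3L)
    stop("hydropathy dimension must have exactly 3 classes, found ",
         length(unique(entries$hydropathy)))
  if (length(catalogs$volume) != 5L)
    stop("volume dimension must have exactly 5 classes, found ",
         length(catalogs$volume))
  if (length(catalogs$physicochemical) != 11L)
    stop("physicochemical dimension must have exactly 11 classes, found ",
         length(catalogs$physicochemical))
  entries <- entries[match(AA_STANDARD20, entries$residue), needed]
  rownames(entries) <- entries$residue
  structure(list(entries = entries, catalogs = catalogs),
            class = "aa_class_table")
}

# Memoized default table so classify()/compare_residues() are cheap.
imgt_class_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_class_tables()
    cache
  }
})

#' Classify a residue into the IMGT property classes
#'
#' @param residue Single one-letter residue code (lowercase accepted).
#' @param table An \code{aa_class_table}, by default the packaged IMGT one.
#' @param strict If \code{TRUE}, a non-standard residue (X, B, Z, gaps, ...)
#'   is an error; if \code{FALSE} (default) it yields an assignment with
#'   \code{classifiable = FALSE} and \code{NA} classes, so callers can fall
#'   back to a default bead style.
#' @return A list of class \code{aa_property_assignment}:
#'   \code{residue}, \code{hydropathy}, \code{volume},
#'   \code{physicochemical}, \code{classifiable}.
#' @examples
#' classify("I")$hydropathy   # "hydrophobic"
#' classify("R")$hydropathy   # "hydrophilic"
#' classify("X")$classifiable # FALSE
#' @export
classify <- function(residue, table = imgt_class_table(), strict = FALSE) {
  stopifnot(is.character(residue), length(residue) == 1L)
  res <- toupper(trimws(residue))
  if (nchar(res) != 1L)
    stop("classify expects a single one-letter residue code, got ",
         sQuote(residue))
  if (!res %in% AA_STANDARD20) {
    if (strict)
      stop(structure(class = c("collier_unclassifiable", "error", "condition"),
                     list(message = paste0("unclassifiable residue: ",
                                           sQuote(res)),
                          call = sys.call(-1L))))
    return(structure(list(residue = res, hydropathy = NA_character_,
                          volume = NA_character_,
                          physicochemical = NA_character_,
                          classifiable = FALSE),
                     class = "aa_property_assignment"))
  }
  row <- table$entries[res, ]
  structure(list(residue = res, hydropathy = row$hydropathy,
                 volume = row$volume, physicochemical = row$physicochemical,
                 classifiable = TRUE),
            class = "aa_property_assignment")
}

#' Default labels for amino acid changes
#'
#' Maps the triple of class-equality booleans (hydropathy, volume,
#' physicochemical) to a change label. The default tiers changes by how
#' many of the three IMGT dimensions are conserved; an identical residue is
#' always labelled \code{"identical"} regardless of the map.
#'
#' @return Named character vector keyed by three-letter \code{T}/\code{F}
#'   strings in dimension order hydropathy, volume, physicochemical.
#' @export
default_change_labels <- function() {
  c(TTT = "very similar",
    TTF = "similar", TFT = "similar", FTT = "similar",
    TFF = "dissimilar", FTF = "dissimilar", FFT = "dissimilar",
    FFF = "very dissimilar")
}

#' Characterize an amino acid change
#'
#' Compares two residues dimension by dimension (hydropathy, volume,
#' physicochemical) and labels the change, as used to annotate differences
#' from a reference sequence.
#'
#' @param a,b One-letter residue codes.
#' @param table An \code{aa_class_table}.
#' @param label_map Named character vector keyed like
#'   [default_change_labels()].
#' @return A list of class \code{aa_change}: \code{residue_from},
#'   \code{residue_to}, \code{same_hydropathy}, \code{same_volume},
#'   \code{same_physicochemical}, \code{label}.
#' @examples
#' compare_residues("I", "L")$same_hydropathy  # TRUE (both hydrophobic)
#' compare_residues("I", "R")$same_hydropathy  # FALSE
#' @export
compare_residues <- function(a, b, table = imgt_class_table(),
                             label_map = default_change_labels()) {
  ca <- classify(a, table, strict = TRUE)
  cb <- classify(b, table, strict = TRUE)
  same <- c(identical(ca$hydropathy, cb$hydropathy),
            identical(ca$volume, cb$volume),
            identical(ca$physicochemical, cb$physicochemical))
  key <- paste(ifelse(same, "T", "F"), collapse = "")
  label <- if (ca$residue == cb$residue) "identical" else unname(label_map[key])
  structure(list(residue_from = ca$residue, residue_to = cb$residue,
                 same_hydropathy = same[[1L]], same_volume = same[[2L]],
                 same_physicochemical = same[[3L]], label = label),
            class = "aa_change")
}
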