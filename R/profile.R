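# Per-position statistical profiles over sets of gapped domains, used for
# the "50% hydrophobic positions" and "80% class" display options.

#' Build a per-position class-frequency profile
#'
#' Counts, at every IMGT position, how many domains occupy the position
#' and how often each hydropathy / volume / physicochemical class occurs
#' there. Frequencies are computed over the domains occupying a position
#' with a classifiable residue (gaps never dilute them; unclassifiable
#' residues count toward occupancy but not toward any class).
#'
#' @param domains Non-empty list of \code{gapped_domain} objects under the
#'   common scheme.
#' @param table Classification table.
#' @return An object of class \code{position_profile}: \code{positions}
#'   (slot labels in display order), \code{occupancy} (named integer),
#'   \code{counts} (list of position x class matrices per dimension),
#'   \code{n_classifiable} (named integer denominators) and
#'   \code{n_domains}.
#' @examples
#' d <- lapply(1:2, function(i)
#'   gap_sequence(synthesize_domain(c(8, 8, 13), seed = i)))
#' p <- build_profile(d)
#' p$occupancy[["1"]]  # 2
#' @export
build_profile <- function(domains, table = imgt_class_table()) {
  if (inherits(domains, "gapped_domain")) domains <- list(domains)
  if (!length(domains)) stop("build_profile needs at least one domain")
  stopifnot(all(vapply(domains, inherits, TRUE, "gapped_domain")))
  n_extra <- max(vapply(domains, function(d) nrow(d$slots), 1L)) - 128L
  labels <- v_slots(n_extra)
  dims <- names(table$catalogs)
  counts <- lapply(dims, function(d) {
    m <- matrix(0L, nrow = length(labels), ncol = length(table$catalogs[[d]]),
                dimnames = list(labels, table$catalogs[[d]]))
    m
  })
  names(counts) <- dims
  occupancy <- stats::setNames(integer(length(labels)), labels)
  n_classifiable <- occupancy
  ent <- table$entries
  for (dom in domains) {
    res <- dom$slots$residue[match(labels, dom$slots$position)]
    occ <- !is.na(res)
    occupancy[occ] <- occupancy[occ] + 1L
    cls <- occ & res %in% ent$residue
    n_classifiable[cls] <- n_classifiable[cls] + 1L
    idx <- which(cls)
    for (d in dims) {
      classes <- ent[res[idx], d]
      for (k in seq_along(idx))
        counts[[d]][idx[k], classes[k]] <- counts[[d]][idx[k], classes[k]] + 1L
    }
  }
  structure(list(positions = labels, occupancy = occupancy, counts = counts,
                 n_classifiable = n_classifiable,
                 n_domains = length(domains)),
            class = "position_profile")
}

#' Class frequencies at a position
#'
#' @param profile A \code{position_profile}.
#' @param position Slot label or number.
#' @param dimension \code{"hydropathy"}, \code{"volume"} or
#'   \code{"physicochemical"}.
#' @return Named numeric vector of class frequencies (summing to 1 over
#'   classifiable residues; all zero where nothing classifiable was seen).
#' @export
class_frequencies <- function(profile, position,
                              dimension = c("hydropathy", "volume",
                                            "physicochemical")) {
  stopifnot(inherits(profile, "position_profile"))
  dimension <- match.arg(dimension)
  pos <- as.character(position)
  if (!pos %in% profile$positions)
    stop("unknown position: ", pos)
  cnt <- profile$counts[[dimension]][pos, ]
  denom <- profile$n_classifiable[[pos]]
  if (denom == 0L) return(cnt * 0)
  cnt / denom
}

#' Positions hydrophobic in a given fraction of sequences
#'
#' The "50% hydrophobic positions" display colors a position blue when a
#' hydrophobic residue occurs there in 50% or more of the profiled
#' sequences; the boundary is inclusive.
#'
#' @param profile A \code{position_profile}.
#' @param threshold Fraction in (0, 1]; default 0.5.
#' @return Character vector of slot labels whose hydrophobic-class
#'   frequency is \code{>= threshold}.
#' @export
hydrophobic_positions <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "position_profile"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  freq <- profile$counts$hydropathy[, "hydrophobic"] /
    pmax(profile$n_classifiable, 1L)
  freq[profile$n_classifiable == 0L] <- 0
  profile$positions[freq >= threshold]
}

#' Dominant class at a position
#'
#' The "80% class" displays color a position by the class reaching the
#' threshold frequency there. At thresholds above 0.5 at most one class
#' can qualify; the boundary is inclusive (a frequency of exactly 0.8
#' qualifies at threshold 0.8).
#'
#' @param profile A \code{position_profile}.
#' @param position Slot label or number.
#' @param dimension One of \code{"hydropathy"}, \code{"volume"},
#'   \code{"physicochemical"}.
#' @param threshold Fraction in (0, 1]; default 0.8.
#' @return The qualifying class name, or \code{NA_character_} if none
#'   reaches the threshold.
#' @export
dominant_class <- function(profile, position,
                           dimension = c("hydropathy", "volume",
                                         "physicochemical"),
                           threshold = 0.8) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  freq <- class_frequencies(profile, position, dimension)
  hit <- which(freq >= threshold)
  if (!length(hit)) return(NA_character_)
  names(freq)[hit[[1L]]]
}

#' Write a profile as TSV
#'
#' One row per (position, dimension, class): columns \code{position},
#' \code{occupancy}, \code{n_classifiable}, \code{dimension}, \code{class},
#' \code{count}, \code{frequency}. The number of source domains is stored
#' in a \code{# n_domains=} header comment.
#'
#' @param profile A \code{position_profile}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "position_profile"))
  rows <- do.call(rbind, lapply(names(profile$counts), function(d) {
    m <- profile$counts[[d]]
    data.frame(position = rep(rownames(m), ncol(m)),
               occupancy = rep(unname(profile$occupancy), ncol(m)),
               n_classifiable = rep(unname(profile$n_classifiable), ncol(m)),
               dimension = d,
               class = rep(colnames(m), each = nrow(m)),
               count = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  rows$frequency <- ifelse(rows$n_classifiable > 0,
                           rows$count / rows$n_classifiable, 0)
  ord <- order(match(rows$position, profile$positions),
               match(rows$dimension, names(profile$counts)))
  rows <- rows[ord, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_domains=", profile$n_domains), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile_tsv()]
#'
#' @param path TSV path.
#' @param table Classification table (defines the class catalogs).
#' @return A \code{position_profile}.
#' @export
read_profile_tsv <- function(path, table = imgt_class_table()) {
  first <- readLines(path, n = 1L)
  n_domains <- if (grepl("^# n_domains=", first))
    as.integer(sub("^# n_domains=", "", first)) else NA_integer_
  rows <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = c(position = "character"))
  labels <- unique(rows$position)
  counts <- lapply(names(table$catalogs), function(d) {
    sub <- rows[rows$dimension == d, ]
    m <- matrix(0L, nrow = length(labels), ncol = length(table$catalogs[[d]]),
                dimnames = list(labels, table$catalogs[[d]]))
    m[cbind(match(sub$position, labels), match(sub$class, colnames(m)))] <-
      sub$count
    m
  })
  names(counts) <- names(table$catalogs)
  firsts <- rows[!duplicated(rows$position), ]
  structure(list(positions = labels,
                 occupancy = stats::setNames(firsts$occupancy,
                                             firsts$position)[labels],
                 counts = counts,
                 n_classifiable = stats::setNames(firsts$n_classifiable,
                                                  firsts$position)[labels],
                 n_domains = n_domains),
            class = "position_profile")
}
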