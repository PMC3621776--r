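# Gapping of ungapped V-domain sequences onto the 128 IMGT positions:
# motif-based anchor detection, gap placement, round-trips, reference
# comparison, and a deterministic fixture generator.

FR_LENGTHS <- c(FR1 = 26L, FR2 = 17L, FR3 = 39L, FR4 = 11L)

# Evaluate code under a given RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

clean_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(gsub("[[:space:]]", "", seq))
}

numbering_error <- function(anchor, detail) {
  stop(structure(
    class = c("collier_not_numberable", "error", "condition"),
    list(message = paste0("not a numberable V domain: ", anchor,
                          " anchor failed (", detail, ")"),
         call = NULL)))
}

#' Locate the conserved anchor residues of an ungapped V domain
#'
#' Searches for a motif-consistent assignment of the four sequence anchors
#' of a V domain: 1st-CYS (position 23), CONSERVED-TRP (41), 2nd-CYS (104)
#' and J-PHE/J-TRP (118), such that the implied framework lengths are
#' standard and the implied CDR lengths are within capacity (CDR1 <= 12,
#' CDR2 <= 10, CDR3 <= 13 plus insertions).
#'
#' Framework lengths are taken at full capacity (FR1 26, FR2 17, FR3 39,
#' FR4 11). Two common germline indels are additionally admitted: FR1 of
#' 25 residues (gap at position 10) and FR3 of 38 residues (gap at
#' position 73). Candidate assignments are tried deterministically: full
#' FR1 before the 10-gap; given a full FR1, full FR3 before the 73-gap;
#' given a 25-residue FR1 the 73-gap variant is preferred, because the two
#' germline gaps co-occur in expressed IG heavy chains. Within a framework
#' choice, smaller CDR1 then smaller CDR2 lengths are tried first.
#'
#' @param seq Ungapped amino-acid sequence (one-letter code).
#' @param min_length,max_length Accepted V-domain sequence lengths.
#' @param max_extra Maximum number of CDR3 insertion positions.
#' @return A list of class \code{anchor_hits}: 1-based sequence indices
#'   \code{first_cys}, \code{conserved_trp}, \code{second_cys},
#'   \code{j_anchor}; the chosen \code{fr1_length} and \code{fr3_length};
#'   and the implied \code{cdr_lengths} (integer triple).
#' @export
detect_anchors <- function(seq, min_length = 85L, max_length = 140L,
                           max_extra = 20L) {
  s <- clean_sequence(seq)
  n <- nchar(s)
  if (n < min_length || n > max_length)
    numbering_error("length", paste0("sequence length ", n,
                                     " outside ", min_length, "-", max_length))
  ch <- strsplit(s, "")[[1L]]
  stage <- "1st-CYS"   # deepest anchor reached, for error reporting
  for (fr1 in c(26L, 25L)) {
    cys1 <- fr1 - 3L   # index of position 23 (10-gap precedes it when fr1 = 25)
    if (ch[cys1] != "C") next
    stage <- max_stage(stage, "CONSERVED-TRP")
    fr3s <- if (fr1 == 26L) c(39L, 38L) else c(38L, 39L)
    for (fr3 in fr3s) {
      for (a in 0:12) {
        w <- fr1 + a + 3L
        if (w > n || ch[w] != "W") next
        stage <- max_stage(stage, "2nd-CYS")
        for (b in 0:10) {
          c2 <- fr1 + a + 17L + b + fr3
          if (c2 > n || ch[c2] != "C") next
          stage <- max_stage(stage, "J-PHE-or-J-TRP")
          cl3 <- n - (fr1 + a + 17L + b + fr3 + 11L)
          if (cl3 < 0L || cl3 > 13L + max_extra) next
          j <- c2 + cl3 + 1L
          if (!ch[j] %in% c("F", "W")) next
          return(structure(list(
            first_cys = cys1, conserved_trp = w, second_cys = c2,
            j_anchor = j, fr1_length = fr1, fr3_length = fr3,
            cdr_lengths = c(CDR1 = a, CDR2 = b, CDR3 = cl3)),
            class = "anchor_hits"))
        }
      }
    }
  }
  numbering_error(stage, "no consistent anchor assignment")
}

# Ranking of anchor stages, so the reported failure names the first anchor
# that could never be placed.
max_stage <- function(cur, new) {
  order <- c("1st-CYS", "CONSERVED-TRP", "2nd-CYS", "J-PHE-or-J-TRP")
  order[max(match(cur, order), match(new, order))]
}

new_gapped_domain <- function(slots, name = NULL, warnings = character()) {
  occ <- !is.na(slots$residue)
  cdr <- vapply(c("CDR1-IMGT", "CDR2-IMGT", "CDR3-IMGT"),
                function(r) sum(occ & slots$region == r), 1L)
  names(cdr) <- c("CDR1", "CDR2", "CDR3")
  fr_gaps <- slots$number[!occ & grepl("^FR", slots$region)]
  structure(list(slots = slots, cdr_lengths = cdr,
                 fr_gaps = sort(unique(fr_gaps)),
                 warnings = warnings, name = name),
            class = "gapped_domain")
}

# Conserved-slot contents check (C23, W41, hydrophobic 89, C104, F/W 118);
# mismatches are reported as warnings so unusual/engineered domains still
# render.
check_conserved <- function(slots, table = imgt_class_table()) {
  res_at <- function(pos) slots$residue[slots$position == as.character(pos)]
  warn <- character()
  chk <- function(pos, ok, what) {
    r <- res_at(pos)
    if (length(r) != 1L || is.na(r)) return(sprintf(
      "conserved position %d (%s) is not occupied", pos, what))
    if (!ok(r)) return(sprintf(
      "conserved position %d (%s) holds %s", pos, what, r))
    character()
  }
  warn <- c(warn,
            chk(23L, function(r) r == "C", "1st-CYS"),
            chk(41L, function(r) r == "W", "CONSERVED-TRP"),
            chk(89L, function(r) isTRUE(classify(r, table)$hydropathy ==
                                          "hydrophobic"), "hydrophobic"),
            chk(104L, function(r) r == "C", "2nd-CYS"),
            chk(118L, function(r) r %in% c("F", "W"), "J-PHE-or-J-TRP"))
  warn
}

slot_skeleton <- function(n_extra = 0L) {
  labels <- v_slots(n_extra)
  p <- parse_position(labels)
  data.frame(position = labels, number = p$number, insertion = p$insertion,
             region = region_of(labels), residue = NA_character_,
             stringsAsFactors = FALSE)
}

#' Gap an ungapped V-domain sequence onto the IMGT positions
#'
#' Detects the conserved anchors (see [detect_anchors()]), measures the
#' three CDR lengths, and distributes the residues over the 128 IMGT
#' positions, gapping each CDR at the top of the loop
#' (see [gap_positions()]) and inserting CDR3 positions beyond length 13
#' (see [extra_positions()]). Conserved-position contents are checked and
#' mismatches recorded as warnings.
#'
#' @param seq Ungapped amino-acid sequence.
#' @param name Optional sequence name carried on the result.
#' @param strict If \code{TRUE}, conserved-position warnings become errors.
#' @param table Classification table used for the position-89 hydropathy
#'   check.
#' @return An object of class \code{gapped_domain}: \code{slots}
#'   (data.frame with \code{position}, \code{number}, \code{insertion},
#'   \code{region}, \code{residue}; \code{NA} residue marks a gap),
#'   \code{cdr_lengths} (named integer triple), \code{fr_gaps},
#'   \code{warnings}, \code{name}.
#' @examples
#' s <- synthesize_domain(c(8, 8, 13), seed = 1)
#' g <- gap_sequence(s)
#' g$cdr_lengths                      # 8 8 13
#' setdiff(1:128, g$slots$number[!is.na(g$slots$residue)])  # 31 32 33 34 60 61
#' @export
gap_sequence <- function(seq, name = NULL, strict = FALSE,
                         table = imgt_class_table()) {
  s <- clean_sequence(seq)
  hits <- detect_anchors(s)
  a <- hits$cdr_lengths[["CDR1"]]
  b <- hits$cdr_lengths[["CDR2"]]
  cl3 <- hits$cdr_lengths[["CDR3"]]
  slots <- slot_skeleton(max(0L, cl3 - 13L))
  gaps <- c(if (hits$fr1_length == 25L) 10L,
            gap_positions("CDR1", a),
            gap_positions("CDR2", b),
            if (cl3 <= 13L) gap_positions("CDR3", cl3),
            if (hits$fr3_length == 38L) 73L)
  occupied <- !(slots$number %in% gaps & is.na(slots$insertion))
  if (sum(occupied) != nchar(s))
    stop("internal error: slot/residue count mismatch")   # nocov
  slots$residue[occupied] <- strsplit(s, "")[[1L]]
  warnings <- check_conserved(slots, table)
  if (strict && length(warnings))
    stop("conserved-position mismatch: ", paste(warnings, collapse = "; "))
  new_gapped_domain(slots, name = name, warnings = warnings)
}

#' Parse a pre-gapped V-domain sequence
#'
#' Accepts a 128-slot (or longer, with CDR3 insertions) gapped sequence in
#' the IMGT convention, with \code{.} (or \code{-}, normalized) marking
#' gaps. Germline framework gaps at arbitrary positions are accepted as
#' given.
#'
#' @param gapped Gapped sequence string of length 128 + insertions.
#' @param name Optional name.
#' @param strict If \code{TRUE}, conserved-position warnings become errors.
#' @param table Classification table for the conserved checks.
#' @return A \code{gapped_domain}.
#' @export
parse_gapped <- function(gapped, name = NULL, strict = FALSE,
                         table = imgt_class_table()) {
  s <- gsub("-", ".", clean_sequence(gapped), fixed = TRUE)
  n <- nchar(s)
  if (n < 128L)
    stop("gapped V-domain sequences have at least 128 slots, got ", n)
  slots <- slot_skeleton(n - 128L)
  ch <- strsplit(s, "")[[1L]]
  slots$residue <- ifelse(ch == ".", NA_character_, ch)
  warnings <- check_conserved(slots, table)
  if (strict && length(warnings))
    stop("conserved-position mismatch: ", paste(warnings, collapse = "; "))
  new_gapped_domain(slots, name = name, warnings = warnings)
}

#' Ungap a gapped domain
#'
#' Drops the gaps and concatenates the residues in display order;
#' \code{ungap(gap_sequence(s))} reproduces \code{s} exactly.
#'
#' @param g A \code{gapped_domain}.
#' @return Ungapped sequence string.
#' @export
ungap <- function(g) {
  stopifnot(inherits(g, "gapped_domain"))
  paste(g$slots$residue[!is.na(g$slots$residue)], collapse = "")
}

#' Gapped string representation of a domain
#'
#' @param g A \code{gapped_domain}.
#' @return The slot contents in display order, gaps as \code{.}.
#' @export
as_gapped_string <- function(g) {
  stopifnot(inherits(g, "gapped_domain"))
  paste(ifelse(is.na(g$slots$residue), ".", g$slots$residue), collapse = "")
}

#' @export
print.gapped_domain <- function(x, ...) {
  cat(sprintf("<gapped_domain%s> CDR-IMGT lengths [%s]\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              paste(x$cdr_lengths, collapse = ".")))
  if (length(x$fr_gaps))
    cat("  framework gaps at:", paste(x$fr_gaps, collapse = ", "), "\n")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Compare a gapped domain to a gapped reference
#'
#' Reports one substitution per position occupied in both domains with
#' differing residues, annotated with the IMGT change characteristics, and
#' separately the positions occupied in exactly one of the two (length
#' differences, e.g. differing CDR lengths).
#'
#' @param query,reference \code{gapped_domain} objects under the same
#'   scheme.
#' @param table Classification table.
#' @param label_map Change label map, see [default_change_labels()].
#' @return A list of class \code{cdp_comparison}: \code{substitutions}
#'   (data.frame: position, region, query, reference, same_hydropathy,
#'   same_volume, same_physicochemical, label) and
#'   \code{length_differences} (data.frame: position, region, query,
#'   reference with \code{.} for the absent side).
#' @export
compare_to_reference <- function(query, reference,
                                 table = imgt_class_table(),
                                 label_map = default_change_labels()) {
  stopifnot(inherits(query, "gapped_domain"),
            inherits(reference, "gapped_domain"))
  eq <- max(nrow(query$slots), nrow(reference$slots)) - 128L
  labels <- v_slots(eq)
  rq <- query$slots$residue[match(labels, query$slots$position)]
  rr <- reference$slots$residue[match(labels, reference$slots$position)]
  both <- !is.na(rq) & !is.na(rr)
  diff <- both & rq != rr
  subs <- data.frame(position = labels[diff], region = region_of(labels[diff]),
                     query = rq[diff], reference = rr[diff],
                     same_hydropathy = logical(sum(diff)),
                     same_volume = logical(sum(diff)),
                     same_physicochemical = logical(sum(diff)),
                     label = character(sum(diff)),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(subs))) {
    chg <- tryCatch(compare_residues(subs$query[i], subs$reference[i],
                                     table, label_map),
                    collier_unclassifiable = function(e) NULL)
    if (is.null(chg)) {
      subs$same_hydropathy[i] <- subs$same_volume[i] <-
        subs$same_physicochemical[i] <- NA
      subs$label[i] <- "unclassifiable"
    } else {
      subs$same_hydropathy[i] <- chg$same_hydropathy
      subs$same_volume[i] <- chg$same_volume
      subs$same_physicochemical[i] <- chg$same_physicochemical
      subs$label[i] <- chg$label
    }
  }
  one <- xor(is.na(rq), is.na(rr))
  lend <- data.frame(position = labels[one], region = region_of(labels[one]),
                     query = ifelse(is.na(rq[one]), ".", rq[one]),
                     reference = ifelse(is.na(rr[one]), ".", rr[one]),
                     stringsAsFactors = FALSE)
  structure(list(substitutions = subs, length_differences = lend),
            class = "cdp_comparison")
}

#' Write a difference table as TSV
#'
#' One row per substitution (columns position, region, query, reference,
#' same_hydropathy, same_volume, same_physicochemical, label) followed by
#' the length differences labelled \code{length-difference}.
#'
#' @param comparison A \code{cdp_comparison}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_differences_tsv <- function(comparison, path) {
  stopifnot(inherits(comparison, "cdp_comparison"))
  subs <- comparison$substitutions
  lend <- comparison$length_differences
  if (nrow(lend)) {
    lend$same_hydropathy <- lend$same_volume <-
      lend$same_physicochemical <- NA
    lend$label <- "length-difference"
    subs <- rbind(subs, lend[, names(subs)])
  }
  utils::write.table(subs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pick the closest reference domain
#'
#' Scores each entry of a user-supplied gapped reference directory by
#' position-wise identity over co-occupied slots and returns the best one;
#' ties are broken by directory order.
#'
#' @param query A \code{gapped_domain}.
#' @param directory Named list of \code{gapped_domain} (e.g. from
#'   [read_gapped_fasta()]).
#' @return A list: \code{name}, \code{index}, \code{reference} (the
#'   selected domain), \code{identity} (fraction), \code{n_compared}
#'   (co-occupied slots).
#' @export
pick_closest_reference <- function(query, directory) {
  stopifnot(inherits(query, "gapped_domain"))
  if (!length(directory)) stop("reference directory is empty")
  score <- function(ref) {
    eq <- max(nrow(query$slots), nrow(ref$slots)) - 128L
    labels <- v_slots(eq)
    rq <- query$slots$residue[match(labels, query$slots$position)]
    rr <- ref$slots$residue[match(labels, ref$slots$position)]
    both <- !is.na(rq) & !is.na(rr)
    c(identity = if (any(both)) mean(rq[both] == rr[both]) else 0,
      n = sum(both))
  }
  scores <- vapply(directory, score, c(identity = 0, n = 0))
  best <- which.max(scores["identity", ])   # first maximum on ties
  nm <- names(directory)[best]
  list(name = if (is.null(nm)) NA_character_ else nm,
       index = unname(best), reference = directory[[best]],
       identity = unname(scores["identity", best]),
       n_compared = as.integer(scores["n", best]))
}

#' Synthesize a V-domain sequence with chosen CDR lengths
#'
#' Deterministic (per seed) fixture generator: draws random residues, then
#' places the conserved motif residues at the offsets implied by
#' full-capacity frameworks (C at position 23, W at 41, a hydrophobic
#' residue at 89, C at 104, W at 118). Positions that could mimic the
#' CONSERVED-TRP or 2nd-CYS motif at a smaller CDR length are resampled
#' away from W/C so that motif-based anchor detection is unambiguous.
#'
#' @param cdr_lengths Integer triple (CDR1, CDR2, CDR3); CDR1 <= 12,
#'   CDR2 <= 10, CDR3 <= 33 (insertions beyond 13).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param table Classification table (source of the hydrophobic residue
#'   set).
#' @return Ungapped sequence string of length
#'   \code{93 + sum(cdr_lengths)}.
#' @examples
#' nchar(synthesize_domain(c(8, 8, 13), seed = 1))  # 122
#' @export
synthesize_domain <- function(cdr_lengths, seed = NULL,
                              table = imgt_class_table()) {
  stopifnot(length(cdr_lengths) == 3L)
  cdr_lengths <- as.integer(cdr_lengths)
  a <- cdr_lengths[[1L]]; b <- cdr_lengths[[2L]]; cl3 <- cdr_lengths[[3L]]
  cap <- c(12L, 10L, 33L)
  if (any(is.na(cdr_lengths)) || any(cdr_lengths < 0L) ||
      any(cdr_lengths > cap))
    stop("CDR lengths must be within capacities [", paste(cap, collapse = ", "),
         "], got [", paste(cdr_lengths, collapse = ", "), "]")
  hydrophobic <- table$entries$residue[
    table$entries$hydropathy == "hydrophobic"]
  with_seed_(seed, {
    n <- 93L + a + b + cl3
    ch <- sample(AA_STANDARD20, n, replace = TRUE)
    ch[23L] <- "C"
    ch[29L + a] <- "W"
    ch[67L + a + b] <- sample(hydrophobic, 1L)
    ch[82L + a + b] <- "C"
    ch[83L + a + b + cl3] <- "W"
    # no decoy CONSERVED-TRP at a smaller CDR1 length
    decoy_w <- if (a > 0L) 29L + 0:(a - 1L) else integer()
    for (i in decoy_w)
      if (ch[i] == "W") ch[i] <- sample(setdiff(AA_STANDARD20, "W"), 1L)
    # no decoy 2nd-CYS at a smaller CDR2 length
    decoy_c <- if (b > 0L) 82L + a + 0:(b - 1L) else integer()
    for (i in decoy_c)
      if (ch[i] == "C") ch[i] <- sample(setdiff(AA_STANDARD20, "C"), 1L)
    paste(ch, collapse = "")
  })
}
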