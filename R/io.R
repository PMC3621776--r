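# FASTA input/output. Plain amino-acid FASTA and the gapped dialect
# ('.' gaps, one 128+ slot record per domain) both go through Biostrings.

#' Read an amino-acid FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no records in FASTA file: ", path)
  out <- toupper(gsub("[[:space:]]", "", as.character(set)))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read a gapped FASTA file as gapped domains
#'
#' Records use the IMGT gapped convention: one character per slot in
#' display order, \code{.} (or \code{-}) for gaps, at least 128 slots.
#'
#' @param path Gapped FASTA file path.
#' @param strict Passed to [parse_gapped()].
#' @return Named list of \code{gapped_domain} objects.
#' @export
read_gapped_fasta <- function(path, strict = FALSE) {
  seqs <- read_fasta(path)
  out <- lapply(seq_along(seqs), function(i)
    parse_gapped(seqs[[i]], name = names(seqs)[i], strict = strict))
  names(out) <- names(seqs)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write gapped domains as gapped FASTA
#'
#' Each domain becomes one record of its slot contents in display order,
#' gaps as \code{.} (128 columns for standard domains, more with CDR3
#' insertions).
#'
#' @param domains List of \code{gapped_domain} (or a single one).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gapped_fasta <- function(domains, path) {
  if (inherits(domains, "gapped_domain")) domains <- list(domains)
  strs <- vapply(domains, as_gapped_string, "")
  nms <- names(domains)
  if (is.null(nms)) nms <- rep("", length(domains))
  fallback <- vapply(seq_along(domains), function(i) {
    nm <- domains[[i]]$name
    if (is.null(nm) || !nzchar(nm)) paste0("domain_", i) else nm
  }, "")
  names(strs) <- ifelse(nzchar(nms), nms, fallback)
  write_fasta(strs, path)
}
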