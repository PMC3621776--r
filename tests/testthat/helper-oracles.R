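# Independent oracles and fixture builders shared by the tests.

cdr_bounds <- function(region) {
  reg <- scheme_constants()$regions
  reg[reg$region == paste0(sub("-IMGT$", "", region), "-IMGT"), ]
}

# Brute-force gap oracle: remove positions middle-out. Odd capacities
# start at the single middle position and alternate outward upward-first
# (111, 112, 110, ...); even capacities start at the upper middle and
# alternate downward-first (33, 32, 34, ...).
middle_out_gaps <- function(region, observed_length) {
  row <- cdr_bounds(region)
  positions <- seq.int(row$start, row$end)
  cap <- length(positions)
  m <- if (cap %% 2L == 1L) (cap + 1L) %/% 2L else cap %/% 2L + 1L
  offsets <- 0L
  for (d in seq_len(cap)) {
    offsets <- if (cap %% 2L == 1L) c(offsets, d, -d) else c(offsets, -d, d)
  }
  order <- m + offsets
  order <- order[order >= 1L & order <= cap]
  sort(positions[order[seq_len(cap - observed_length)]])
}

# Brute-force hydrogen-bond oracle over a domain_structure: all directed
# (donor N, acceptor O) pairs by direct distance computation.
brute_hbonds <- function(d, cutoff = 3.5, min_separation = 2L) {
  n <- nrow(d$residues)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < min_separation) next
    if (!d$residues$has_n[i] || !d$residues$has_o[j]) next
    dist <- sqrt(sum((d$n_xyz[i, ] - d$o_xyz[j, ])^2))
    if (dist <= cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d$residues$position[i], acceptor = d$residues$position[j],
        distance = dist, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(donor = character(), acceptor = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Apply a rigid-body transform (rotation matrix + translation) to every
# ATOM coordinate of a PDB file written by synthesize_sheet_structure.
transform_pdb <- function(path, out, rotation, translation) {
  lines <- readLines(path)
  atom <- grepl("^ATOM", lines)
  xyz <- t(vapply(lines[atom], function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))),
    numeric(3L)))
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3L,
                                      byrow = TRUE)
  lines[atom] <- paste0(substr(lines[atom], 1, 30),
                        sprintf("%8.3f%8.3f%8.3f", xyz[, 1], xyz[, 2],
                                xyz[, 3]),
                        substr(lines[atom], 55, 80))
  writeLines(lines, out)
  out
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

# A full-capacity gapped string (no gaps anywhere) that can be edited
# per-position: slot index == IMGT position for positions 1..128.
full_capacity_string <- function(seed = 100) {
  as_gapped_string(gap_sequence(synthesize_domain(c(12, 10, 13),
                                                  seed = seed)))
}

substitute_at <- function(gapped_string, position, residue) {
  substr(gapped_string, position, position) <- residue
  gapped_string
}

trastuzumab_vh <- function() {
  read_fasta(system.file("extdata", "trastuzumab_vh.fasta",
                         package = "collier"))[[1L]]
}

write_synth_fasta <- function(path, triples, seed = 1) {
  seqs <- vapply(seq_along(triples), function(i)
    synthesize_domain(triples[[i]], seed = seed + i), "")
  names(seqs) <- sprintf("synth_%d", seq_along(triples))
  write_fasta(seqs, path)
  seqs
}
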