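test_that("anchor detection recovers the generator's construction", {
  s <- synthesize_domain(c(8, 8, 13), seed = 1)
  hits <- detect_anchors(s)
  expect_equal(hits$first_cys, 23L)
  expect_equal(hits$conserved_trp, 37L)    # 26 + 8 + 3
  expect_equal(hits$second_cys, 98L)       # 26 + 8 + 17 + 8 + 39
  expect_equal(hits$j_anchor, 112L)
  expect_equal(unname(hits$cdr_lengths), c(8L, 8L, 13L))
  expect_equal(hits$fr1_length, 26L)
  expect_equal(hits$fr3_length, 39L)
})

test_that("sequences without the conserved motifs are rejected by anchor", {
  no_cys <- paste(rep("A", 120), collapse = "")
  err <- tryCatch(detect_anchors(no_cys), error = identity)
  expect_s3_class(err, "collier_not_numberable")
  expect_match(conditionMessage(err), "1st-CYS")
  expect_error(detect_anchors("ACDEF"), class = "collier_not_numberable")
  # a CDR1 stretched past capacity leaves no consistent assignment
  s <- synthesize_domain(c(12, 10, 13), seed = 7)
  stretched <- paste0(substr(s, 1, 30), "PPP", substr(s, 31, nchar(s)))
  expect_error(gap_sequence(stretched), class = "collier_not_numberable")
})

test_that("gapping places gaps per the numbering rules", {
  s <- synthesize_domain(c(8, 8, 13), seed = 1)
  g <- gap_sequence(s)
  expect_equal(nrow(g$slots), 128L)
  expect_equal(unname(g$cdr_lengths), c(8L, 8L, 13L))
  gaps <- g$slots$number[is.na(g$slots$residue)]
  expect_equal(sort(gaps), c(31L, 32L, 33L, 34L, 60L, 61L))
  expect_length(g$warnings, 0L)
  # full capacities leave no gap at all
  g_full <- gap_sequence(synthesize_domain(c(12, 10, 13), seed = 2))
  expect_equal(sum(is.na(g_full$slots$residue)), 0L)
})

test_that("the trastuzumab VH numbers to CDR-IMGT lengths [8.8.13]", {
  g <- gap_sequence(trastuzumab_vh())
  expect_equal(unname(g$cdr_lengths), c(8L, 8L, 13L))
  expect_equal(g$fr_gaps, c(10L, 73L))   # the two common germline indels
  expect_length(g$warnings, 0L)
  # conserved residues land on their positions
  res_at <- function(p) g$slots$residue[g$slots$position == p]
  expect_equal(res_at("23"), "C")
  expect_equal(res_at("41"), "W")
  expect_equal(res_at("104"), "C")
  expect_equal(res_at("118"), "W")
})

test_that("ungap inverts gapping across seeds and CDR-length triples", {
  set.seed(11)
  for (k in 1:40) {
    triple <- c(sample(0:12, 1L), sample(0:10, 1L), sample(0:13, 1L))
    s <- synthesize_domain(triple, seed = k)
    g <- gap_sequence(s)
    expect_identical(ungap(g), s)
    expect_equal(unname(g$cdr_lengths), triple)
    # slot conservation: occupied + gaps = 128
    expect_equal(nrow(g$slots), 128L)
  }
})

test_that("long CDR3 domains take insertion slots and round-trip", {
  s <- synthesize_domain(c(8, 8, 17), seed = 3)
  g <- gap_sequence(s)
  expect_equal(nrow(g$slots), 132L)
  expect_equal(unname(g$cdr_lengths["CDR3"]), 17L)
  expect_true(all(c("111.1", "111.2", "112.2", "112.1") %in%
                    g$slots$position))
  expect_identical(ungap(g), s)
})

test_that("conserved-position mismatches warn but do not fail", {
  s <- synthesize_domain(c(8, 8, 13), seed = 5)
  # put an acidic residue at position 89 (hydrophobic expected)
  idx <- 67L + 8L + 8L
  bad <- paste0(substr(s, 1, idx - 1L), "D", substr(s, idx + 1L, nchar(s)))
  g <- gap_sequence(bad)
  expect_match(g$warnings, "position 89", all = FALSE)
  expect_error(gap_sequence(bad, strict = TRUE), "conserved-position")
})

test_that("pre-gapped input parses, normalizes '-' and round-trips", {
  g <- gap_sequence(trastuzumab_vh())
  str <- as_gapped_string(g)
  expect_equal(nchar(str), 128L)
  reparsed <- parse_gapped(str)
  expect_identical(reparsed$slots$residue, g$slots$residue)
  dashes <- gsub(".", "-", str, fixed = TRUE)
  expect_identical(parse_gapped(dashes)$slots$residue, g$slots$residue)
  expect_false(grepl("[.-]", ungap(reparsed)))
  expect_error(parse_gapped("ACDEF"), "at least 128")
})

test_that("domain comparison separates substitutions from length diffs", {
  base <- full_capacity_string()
  q <- parse_gapped(base)
  expect_equal(nrow(compare_to_reference(q, q)$substitutions), 0L)
  expect_equal(nrow(compare_to_reference(q, q)$length_differences), 0L)
  # single substitution at position 50
  old <- substr(base, 50, 50)
  new <- setdiff(c("A", "G"), old)[1L]
  r <- parse_gapped(substitute_at(base, 50, new))
  cmp <- compare_to_reference(q, r)
  expect_equal(nrow(cmp$substitutions), 1L)
  expect_equal(cmp$substitutions$position, "50")
  expect_equal(cmp$substitutions$region, "FR2-IMGT")
  # CDR3 length 12 vs 13: position 111 is a length difference
  q12 <- gap_sequence(synthesize_domain(c(12, 10, 12), seed = 100))
  r13 <- parse_gapped(base)
  cmp2 <- compare_to_reference(q12, r13)
  expect_true("111" %in% cmp2$length_differences$position)
  expect_false("111" %in% cmp2$substitutions$position)
  # symmetry of counts under argument swap
  cmp3 <- compare_to_reference(r13, q12)
  expect_equal(nrow(cmp2$substitutions), nrow(cmp3$substitutions))
  expect_equal(nrow(cmp2$length_differences),
               nrow(cmp3$length_differences))
})

test_that("closest-reference pick maximizes identity with stable ties", {
  base <- full_capacity_string()
  q <- parse_gapped(base)
  one_off <- parse_gapped(substitute_at(base, 30, "A"))
  three_off <- parse_gapped(substitute_at(substitute_at(
    substitute_at(base, 30, "A"), 70, "G"), 90, "S"))
  dir <- list(worse = three_off, better = one_off, self = q)
  best <- pick_closest_reference(q, dir)
  expect_equal(best$name, "self")
  expect_equal(best$identity, 1.0)
  # tie: two copies of the same reference -> first in directory order
  tie <- pick_closest_reference(q, list(first = one_off, second = one_off))
  expect_equal(tie$name, "first")
  expect_error(pick_closest_reference(q, list()), "empty")
})

test_that("the fixture generator is deterministic and validates lengths", {
  expect_identical(synthesize_domain(c(8, 8, 13), seed = 1),
                   synthesize_domain(c(8, 8, 13), seed = 1))
  expect_false(identical(synthesize_domain(c(8, 8, 13), seed = 1),
                         synthesize_domain(c(8, 8, 13), seed = 2)))
  expect_equal(nchar(synthesize_domain(c(8, 8, 13), seed = 1)), 122L)
  expect_error(synthesize_domain(c(13, 8, 13)), "capacit")
  expect_error(synthesize_domain(c(8, 11, 13)), "capacit")
  expect_error(synthesize_domain(c(8, 8, -1)), "capacit")
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(synthesize_domain(c(8, 8, 13), seed = 1))
  expect_identical(runif(1), before)
})

test_that("FASTA and gapped-FASTA writers round-trip", {
  f <- tempfile(fileext = ".fasta")
  seqs <- write_synth_fasta(f, list(c(8, 8, 13), c(5, 3, 9)))
  expect_identical(read_fasta(f), seqs)
  domains <- lapply(seqs, gap_sequence)
  gf <- tempfile(fileext = ".fasta")
  write_gapped_fasta(domains, gf)
  back <- read_gapped_fasta(gf)
  expect_identical(names(back), names(domains))
  expect_identical(lapply(back, ungap), lapply(domains, ungap))
  expect_identical(lapply(back, function(d) d$cdr_lengths),
                   lapply(domains, function(d) d$cdr_lengths))
})

test_that("difference tables write the documented TSV columns", {
  base <- full_capacity_string()
  q <- parse_gapped(substitute_at(base, 50, "A"))
  r <- parse_gapped(substitute_at(base, 50, "R"))
  f <- tempfile(fileext = ".tsv")
  write_differences_tsv(compare_to_reference(q, r), f)
  tab <- utils::read.delim(f, colClasses = c(position = "character"))
  expect_equal(names(tab),
               c("position", "region", "query", "reference",
                 "same_hydropathy", "same_volume", "same_physicochemical",
                 "label"))
  expect_equal(tab$position, "50")
})
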