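test_that("one-layer layout covers every slot with distinct coordinates", {
  g <- parse_gapped(full_capacity_string())
  lay <- layout_one_layer(g)
  expect_equal(nrow(lay$beads), 128L)
  expect_identical(lay$beads$position, g$slots$position)
  expect_false(anyDuplicated(paste(lay$beads$x, lay$beads$y)) > 0L)
  expect_true(all(lay$beads$layer == "single"))
})

test_that("layouts have 9 strand blocks and 3 loop blocks", {
  for (g in list(parse_gapped(full_capacity_string()),
                 gap_sequence(synthesize_domain(c(8, 8, 13), seed = 2)),
                 gap_sequence(trastuzumab_vh()))) {
    for (lay in list(layout_one_layer(g), layout_two_layers(g))) {
      expect_equal(sum(lay$blocks$kind == "strand"), 9L)
      expect_equal(sum(lay$blocks$kind == "loop"), 3L)
    }
  }
})

test_that("consecutive beads stay within one step of each other", {
  geom <- cdp_geometry()
  for (triple in list(c(12, 10, 13), c(8, 8, 13), c(0, 0, 0))) {
    g <- gap_sequence(synthesize_domain(triple, seed = 3))
    b <- layout_one_layer(g, geom)$beads
    steps <- sqrt(diff(b$x)^2 + diff(b$y)^2)
    expect_lte(max(steps), geom$max_step)
  }
  # two layers: the constraint holds between consecutive beads that share
  # a layer (the backbone projection between sheets is exempt)
  g <- gap_sequence(trastuzumab_vh())
  b <- layout_two_layers(g, geom)$beads
  same <- b$layer[-1L] == b$layer[-nrow(b)]
  steps <- sqrt(diff(b$x)^2 + diff(b$y)^2)[same]
  expect_lte(max(steps), geom$max_step)
})

test_that("the two-layer view splits the 9 strands over both sheets", {
  g <- parse_gapped(full_capacity_string())
  one <- layout_one_layer(g)
  two <- layout_two_layers(g)
  strands <- two$blocks[two$blocks$kind == "strand", ]
  expect_setequal(strands$layer, c("front", "back"))
  expect_equal(nrow(strands), 9L)
  expect_false(anyDuplicated(strands$block) > 0L)
  expect_setequal(strands$block[strands$layer == "back"],
                  c("A", "B", "E", "D"))
  expect_setequal(strands$block[strands$layer == "front"],
                  c("G", "F", "C", "C'", "C''"))
  # union of both layers' positions is all slots
  expect_setequal(two$beads$position, g$slots$position)
  # strand membership labels agree between the views
  expect_identical(one$beads$block, two$beads$block)
  expect_false(anyDuplicated(paste(two$beads$x, two$beads$y)) > 0L)
})

test_that("layout is a pure function of domain shape and geometry", {
  g <- gap_sequence(synthesize_domain(c(5, 7, 11), seed = 8))
  expect_identical(layout_one_layer(g), layout_one_layer(g))
  expect_identical(layout_two_layers(g), layout_two_layers(g))
  # a domain with the same gap structure gets identical coordinates
  g2 <- gap_sequence(synthesize_domain(c(5, 7, 11), seed = 88))
  expect_identical(layout_one_layer(g)$beads[, c("x", "y")],
                   layout_one_layer(g2)$beads[, c("x", "y")])
})

test_that("CDR3 insertion slots are laid out on the loop arc", {
  g <- gap_sequence(synthesize_domain(c(8, 8, 16), seed = 10))
  lay <- layout_one_layer(g)
  expect_equal(nrow(lay$beads), 131L)
  ins <- lay$beads[lay$beads$position %in% c("111.1", "112.1"), ]
  expect_equal(ins$block, c("CDR3", "CDR3"))
  steps <- sqrt(diff(lay$beads$x)^2 + diff(lay$beads$y)^2)
  expect_lte(max(steps), cdp_geometry()$max_step)
})

test_that("geometry files override defaults and reject unknown keys", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "spacing=2.0", "max_step=3.2"), f)
  geom <- cdp_geometry(f)
  expect_equal(geom$spacing, 2.0)
  expect_equal(geom$max_step, 3.2)
  expect_equal(geom$bead_radius, 0.35)   # untouched default
  writeLines("wobble=1", f)
  expect_error(cdp_geometry(f), "unknown geometry key")
  writeLines("spacing=wide", f)
  expect_error(cdp_geometry(f), "non-numeric")
  # packaged file equals built-in defaults
  pkg <- cdp_geometry(system.file("extdata", "geometry.cfg",
                                  package = "collier"))
  expect_identical(pkg, cdp_geometry())
})

test_that("strand tables are validated against the region tiling", {
  tab <- v_strand_table()
  expect_equal(nrow(tab), 9L)
  f <- tempfile(fileext = ".tsv")
  bad <- tab
  bad$end[bad$strand == "A"] <- 14L   # position 15 uncovered
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(v_strand_table(f), "tile the FR-IMGT")
  utils::write.table(tab[-1L, ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(v_strand_table(f), "9 strands")
})

test_that("layouts export as TSV", {
  g <- gap_sequence(synthesize_domain(c(8, 8, 13), seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_layout_tsv(layout_two_layers(g), f)
  back <- utils::read.delim(f, colClasses = c(position = "character"))
  expect_equal(nrow(back), 128L)
  expect_equal(names(back), c("position", "x", "y", "layer", "block"))
})
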