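write_lines_tmp <- function(lines, ext) {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

test_that("Pharokka GFF3 rows map to coordinates, strand and product", {
  tf <- write_lines_tmp(c(
    "##gff-version 3",
    "p1\tPharokka\tCDS\t100\t300\t.\t+\t0\tID=c1;product=terminase",
    "p1\tPharokka\ttRNA\t400\t475\t.\t-\t0\tID=t1;product=tRNA-Leu"
  ), ".gff")
  set <- parse_pharokka_gff(tf)
  expect_equal(set$source, rep("pharokka", 2))
  expect_equal(set$start, c(100L, 400L))
  expect_equal(set$end, c(300L, 475L))
  expect_equal(set$strand, c("+", "-"))
  expect_equal(set$product, c("terminase", "tRNA-Leu"))
  expect_equal(set$feature_type, c("CDS", "tRNA"))
})

test_that("GFF with end < start or bad coordinates errors with the line number", {
  tf <- write_lines_tmp(c(
    "##gff-version 3",
    "p1\tPharokka\tCDS\t500\t300\t.\t+\t0\tID=c1;product=x"
  ), ".gff")
  expect_error(parse_pharokka_gff(tf), "line 2", class = "phagetools_parse_error")
  tf2 <- write_lines_tmp(c("p1\tPharokka\tCDS\tabc\t300\t.\t+\t0\tID=c1"), ".gff")
  expect_error(parse_pharokka_gff(tf2), "non-numeric", class = "phagetools_parse_error")
})

test_that("PHASTER coordinate tokens parse with strand and product phrase", {
  tf <- write_lines_tmp(c(
    "# PHASTER region details",
    "CDS_POSITION   BLAST_HIT",
    "313..1470   phage terminase",
    "complement(2000..2600)   integrase"
  ), ".txt")
  set <- suppressWarnings(parse_phaster_txt(tf))
  expect_equal(nrow(set), 2L)
  expect_equal(set$start, c(313L, 2000L))
  expect_equal(set$end, c(1470L, 2600L))
  expect_equal(set$strand, c("+", "-"))
  expect_equal(set$product, c("phage terminase", "integrase"))
  # count of records = count of coordinate-bearing rows
  expect_warning(parse_phaster_txt(tf), "skipped 2")
})

test_that("a PHASTER file with zero parsable rows is a parse error", {
  tf <- write_lines_tmp(c("header only", "no coordinates here"), ".txt")
  expect_error(suppressWarnings(parse_phaster_txt(tf)),
               class = "phagetools_parse_error")
})

test_that("RAST tables re-orient start/stop and keep functions verbatim", {
  tf <- write_lines_tmp(c(
    paste("contig_id", "type", "start", "stop", "strand", "function", sep = "\t"),
    "c1\tCDS\t500\t200\t-\thypothetical protein"
  ), ".tsv")
  set <- parse_rast_table(tf)
  expect_equal(set$start, 200L)
  expect_equal(set$end, 500L)
  expect_equal(set$strand, "-")
  expect_equal(set$product, "hypothetical protein")
})

test_that("a RAST file in the wrong dialect is a schema error naming columns", {
  tf <- write_lines_tmp(c("contig_id;start;stop;strand;function",
                          "c1;1;30;+;x"), ".tsv")
  expect_error(parse_rast_table(tf), "missing required column",
               class = "phagetools_validation_error")
})

make_sets <- function(trip) {
  list(parse_pharokka_gff(trip$paths["pharokka"]),
       suppressWarnings(parse_phaster_txt(trip$paths["phaster"])),
       parse_rast_table(trip$paths["rast"]))
}

test_that("exact matching groups coordinate-identical records across tools", {
  trip <- make_annotation_triplet(tempfile(), design = list(common = 3), seed = 1)
  m <- match_annotations(make_sets(trip))
  expect_equal(max(m$group), 3L)
  expect_true(all(m$n_sources == 3L))
})

test_that("tolerance merges near-miss boundaries, zero keeps them apart", {
  gff <- write_lines_tmp(c("##gff-version 3",
                           "c\tPharokka\tCDS\t100\t300\t.\t+\t0\tID=a;product=x"), ".gff")
  rast <- write_lines_tmp(c(
    paste("contig_id", "type", "start", "stop", "strand", "function", sep = "\t"),
    "c\tCDS\t102\t300\t+\ty"
  ), ".tsv")
  sets <- list(parse_pharokka_gff(gff), parse_rast_table(rast))
  m0 <- match_annotations(sets, tolerance_bp = 0)
  expect_equal(max(m0$group), 2L)
  m5 <- match_annotations(sets, tolerance_bp = 5)
  expect_equal(max(m5$group), 1L)
})

test_that("comparison counts reproduce a constructed fixture design", {
  trip <- make_annotation_triplet(
    tempfile(),
    design = list(common = 6, pharokka_only = 2, pharokka_rast = 2),
    seed = 42
  )
  sets <- make_sets(trip)
  res <- compare_annotations(sets, mode = "common_annotation")
  expect_equal(unname(res$counts["common"]), 6L)
  expect_equal(unname(res$counts["pharokka_only"]), 2L)
  expect_equal(unname(res$counts["partial"]), 2L)
  expect_equal(nrow(res$rows), 6L)
  only <- compare_annotations(sets, mode = "pharokka_only")
  expect_equal(nrow(only$rows), 2L)
})

test_that("three identical sets are all common with empty *_only tables", {
  trip <- make_annotation_triplet(tempfile(), design = list(common = 5), seed = 3)
  sets <- make_sets(trip)
  res <- compare_annotations(sets, mode = "all")
  expect_equal(unname(res$counts["common"]), 5L)
  expect_equal(unname(res$counts[c("pharokka_only", "phaster_only", "rast_only")]),
               c(0L, 0L, 0L))
  expect_equal(nrow(compare_annotations(sets, mode = "rast_only")$rows), 0L)
})

test_that("per-tool partition conservation holds on 50 random designs", {
  set.seed(606)
  for (i in 1:50) {
    design <- list(
      common = sample(0:6, 1), pharokka_only = sample(0:4, 1),
      phaster_only = sample(0:4, 1), rast_only = sample(0:4, 1),
      pharokka_phaster = sample(0:3, 1), pharokka_rast = sample(0:3, 1),
      phaster_rast = sample(0:3, 1)
    )
    if (sum(unlist(design)) == 0) design$common <- 1
    trip <- make_annotation_triplet(tempfile(), design = design, seed = i)
    # every tool must have at least one record for its parser to succeed
    participates <- c(
      pharokka = design$common + design$pharokka_only +
        design$pharokka_phaster + design$pharokka_rast,
      phaster = design$common + design$phaster_only +
        design$pharokka_phaster + design$phaster_rast,
      rast = design$common + design$rast_only +
        design$pharokka_rast + design$phaster_rast
    )
    if (any(participates == 0)) next
    sets <- make_sets(trip)
    res <- compare_annotations(sets, mode = "all")
    # counts equal the generator truth
    expect_equal(unname(res$counts["common"]), unname(trip$truth["common"]))
    for (tool in c("pharokka", "phaster", "rast")) {
      expect_equal(unname(res$counts[paste0(tool, "_only")]),
                   unname(trip$truth[paste0(tool, "_only")]))
    }
    # partition: every record in exactly one group; per-tool totals conserved
    m <- res$matched
    expect_equal(nrow(m), sum(participates))
    per_tool <- table(m$source)
    for (tool in names(participates)) {
      in_common <- sum(m$source == tool & m$n_sources == 3L)
      grp_sizes <- table(m$group)
      only <- sum(m$source == tool &
                    m$group %in% names(grp_sizes)[grp_sizes == 1])
      partial <- per_tool[[tool]] - in_common - only
      expect_equal(in_common + only + partial, unname(participates[tool]))
      expect_gte(partial, 0)
    }
  }
})

test_that("set order does not change counts and tolerance only merges groups", {
  trip <- make_annotation_triplet(
    tempfile(), design = list(common = 4, pharokka_only = 2, phaster_rast = 1),
    seed = 9
  )
  sets <- make_sets(trip)
  r1 <- compare_annotations(sets, mode = "all")
  r2 <- compare_annotations(sets[c(3, 1, 2)], mode = "all")
  nm <- sort(names(r1$counts))
  expect_equal(r1$counts[nm], r2$counts[nm])
  # monotonicity: groups never increase with tolerance
  g0 <- max(match_annotations(sets, tolerance_bp = 0)$group)
  for (tol in c(2, 10, 100)) {
    expect_lte(max(match_annotations(sets, tolerance_bp = tol)$group), g0)
  }
})

test_that("sorting orders rows by location, length or product", {
  trip <- make_annotation_triplet(tempfile(), design = list(common = 5), seed = 13)
  sets <- make_sets(trip)
  by_loc <- compare_annotations(sets, mode = "common_annotation", sort_by = "location")
  expect_false(is.unsorted(by_loc$rows$start))
  by_len <- compare_annotations(sets, mode = "common_annotation", sort_by = "length")
  expect_false(is.unsorted(rev(by_len$rows$length)))
})

test_that("export writes csv/tsv with per-tool columns and rejects pdf", {
  trip <- make_annotation_triplet(tempfile(),
                                  design = list(common = 6, pharokka_only = 1),
                                  seed = 21)
  sets <- make_sets(trip)
  res <- compare_annotations(sets, mode = "common_annotation")
  tf <- tempfile(fileext = ".csv")
  export_comparison(res, tf)
  out <- readr::read_csv(tf, show_col_types = FALSE)
  expect_equal(nrow(out), 6L)
  expect_true(all(c("product_pharokka", "product_phaster", "product_rast",
                    "coords_pharokka") %in% names(out)))
  # empty result: header-only file
  empty <- compare_annotations(sets, mode = "rast_only")
  export_comparison(empty, tf)
  expect_equal(nrow(readr::read_csv(tf, show_col_types = FALSE)), 0L)
  expect_error(export_comparison(res, tf, format = "pdf"),
               class = "phagetools_parameter_error")
})

test_that("tool_only mode for an absent tool is a parameter error", {
  trip <- make_annotation_triplet(tempfile(), design = list(common = 3), seed = 2)
  sets <- make_sets(trip)[1:2]  # pharokka + phaster only
  expect_error(compare_annotations(sets, mode = "rast_only"),
               class = "phagetools_parameter_error")
  # pairwise comparison works
  res <- compare_annotations(sets, mode = "common_annotation")
  expect_equal(unname(res$counts["common"]), 3L)
})
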