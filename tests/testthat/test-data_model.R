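test_that("FASTA reading parses entries, preserves gaps/N, rejects bad input", {
  f <- write_tmp_fasta(c(">s1", "ACGT"))
  r <- read_fasta(f)
  expect_length(r, 1)
  expect_equal(r[[1]]$seq, "ACGT")

  f2 <- write_tmp_fasta(c(">a", "AC-T", ">b", "ACNT"))
  r2 <- read_fasta(f2)
  expect_equal(vapply(r2, `[[`, character(1), "seq"), c("AC-T", "ACNT"))

  f3 <- write_tmp_fasta(c(">a", "ACGT", ">a", "ACGT"))
  expect_error(read_fasta(f3), "duplicate")

  f4 <- write_tmp_fasta(c("ACGT", ">a", "ACGT"))
  expect_error(read_fasta(f4), "line 1")

  # lowercase is uppercased; ambiguity codes go to N with a warning
  f5 <- write_tmp_fasta(c(">a", "acgr"))
  expect_warning(r5 <- read_fasta(f5), "mapped to N")
  expect_equal(r5[[1]]$seq, "ACGN")
})

test_that("FASTA round-trip reproduces sequences and anchors", {
  recs <- list(seq_record("x1", "ACGTN-", 15914L),
               seq_record("x2", "AC??TT", 16023L))
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, unclass), lapply(recs, unclass))
})

test_that("window extraction matches the study's fragment arithmetic", {
  seq434 <- paste(rep("ACGT", 109), collapse = "")  # 436; trim to 434
  seq434 <- substr(seq434, 1, 434)
  rec <- seq_record("anc1", seq434, 15914L)

  w399 <- extract_window(list(rec), 15914, 16312)
  expect_equal(nchar(w399$seqs[[1]]), 399)

  w240 <- extract_window(list(rec), 16023, 16262)
  expect_equal(nchar(w240$seqs[[1]]), 240)
  # the 240 bp window is an interior slice of the 399 bp window
  expect_equal(w240$seqs[[1]], substr(w399$seqs[[1]], 16023 - 15914 + 1,
                                      16262 - 15914 + 1))

  # identity window leaves the sequence unchanged
  wid <- extract_window(list(rec), 15914, 15914 + 434 - 1)
  expect_equal(wid$seqs[[1]], seq434)

  # idempotence: re-windowing to the same interval is a no-op
  rec2 <- seq_record("anc1", w240$seqs[[1]], 16023L)
  w2 <- extract_window(list(rec2), 16023, 16262)
  expect_equal(w2$seqs, w240$seqs)

  short <- seq_record("short", "ACGT", 15914L)
  expect_error(extract_window(list(rec, short), 15914, 16312), "short")
})

test_that("BCE-to-generations conversion hits the model's calendar anchors", {
  expect_equal(bce_to_generations(8500), 1750)
  expect_equal(bce_to_generations(6400), 1400)
  expect_equal(bce_to_generations(5000), 7000 / 6)
  # linear and strictly increasing
  ages <- seq(-2000, 9000, by = 250)
  g <- bce_to_generations(ages)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(g), rep(250 / 6, length(ages) - 1))
  expect_error(bce_to_generations(1000, generation_time = 0), "> 0")
})

test_that("metadata validation derives ABC groups and catches bad rows", {
  md <- rbind(make_md(id = "a1"),
              make_md(id = "e1", region = "SEE 6,200-5,500 BCE",
                      lo = 6200, hi = 5500),
              make_md(id = "m1", region = "Europe (modern)", epoch = "modern",
                      lo = 0, hi = 0))
  v <- validate_metadata(md)
  expect_equal(v$abc_group, c("ancient_NE", "ancient_EU", "modern_EU"))

  expect_error(validate_metadata(md[, -3]), "missing column")
  bad <- make_md(); bad$lat <- NA
  expect_error(validate_metadata(bad), "lat")
  rev_age <- make_md(lo = 5000, hi = 7000)
  expect_error(validate_metadata(rev_age), "older bound")
  unk <- make_md(region = "Atlantis 1,000 BCE")
  expect_error(validate_metadata(unk), "unknown region_group")
})

test_that("metadata TSV round-trips through read_metadata", {
  md <- rbind(make_md(id = "a1"), make_md(id = "a2", lo = 6500, hi = 6000))
  f <- tempfile(fileext = ".tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_metadata(f)
  expect_equal(back[names(md)], md, ignore_attr = TRUE)
})

test_that("point ages use the midpoint rule; modern samples map to t = 0", {
  md <- validate_metadata(rbind(
    make_md(id = "a1", lo = 7000, hi = 5000),
    make_md(id = "m1", region = "Near East (modern)", epoch = "modern",
            lo = 0, hi = 0)))
  ages <- sample_ages_bce(md)
  expect_equal(ages[1], 6000)
  expect_equal(bce_to_generations(ages[2]), 0)
  # group-midpoint rule pools the group's range
  md2 <- validate_metadata(rbind(
    make_md(id = "a1", lo = 7000, hi = 6600),
    make_md(id = "a2", lo = 6000, hi = 5000)))
  expect_equal(sample_ages_bce(md2, "group_midpoint"), c(6000, 6000))
})
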