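test_that("a toy long table parses into one record with four intensities", {
  p <- write_toy_table(tempfile(fileext = ".tsv"), toy_rows())
  ds <- read_peptide_table(p)
  expect_s3_class(ds, "peptide_dataset")
  expect_equal(nrow(ds$records), 1L)
  expect_equal(nrow(ds$intensities), 4L)
  expect_equal(sort(unique(ds$intensities$temperature)), c(37, 76))
})

test_that("duplicate keys and missing columns are rejected; bad intensities become missing", {
  rows <- toy_rows()
  dup <- rbind(rows, rows[1, ])
  p <- write_toy_table(tempfile(fileext = ".tsv"), dup)
  expect_error(read_peptide_table(p), "duplicate")

  p2 <- write_toy_table(tempfile(fileext = ".tsv"), rows[, names(rows) != "intensity"])
  expect_error(read_peptide_table(p2), "schema")

  rows$intensity <- c("100", "n.d.", "0", "42")  # non-numeric and zero -> NA
  p3 <- write_toy_table(tempfile(fileext = ".tsv"), rows)
  ds <- read_peptide_table(p3)
  expect_equal(sum(is.na(ds$intensities$intensity)), 2L)

  # schema mapping from foreign column names
  rows2 <- toy_rows()
  names(rows2)[names(rows2) == "peptide"] <- "EG.PrecursorId"
  p4 <- write_toy_table(tempfile(fileext = ".tsv"), rows2)
  expect_s3_class(read_peptide_table(p4, schema = c(peptide = "EG.PrecursorId")),
                  "peptide_dataset")
})

test_that("write then read round-trips the generator's key -> value map", {
  ds <- small_lip(seed = 9, n_prot = 3)
  p <- tempfile(fileext = ".tsv")
  write_peptide_table(ds, p)
  ds2 <- read_peptide_table(p, grid = ds$grid)
  key <- function(d) with(d$intensities,
    paste(peptide_id, condition, replicate, temperature, sep = "|"))
  m <- match(key(ds), key(ds2))
  expect_false(anyNA(m))
  expect_equal(ds$intensities$intensity, ds2$intensities$intensity[m],
               tolerance = 1e-12)
  expect_equal(nrow(ds$records), nrow(ds2$records))
})

test_that("HT/FT matching follows the containment rule, borders inclusive", {
  rec <- data.frame(
    protein_id = c("A", "A", "A", "A", "B"),
    peptide_id = c("ht1", "ht2", "ht3", "ft1", "ft2"),
    start = c(10, 10, 10, 8, 8), end = c(20, 30, 20, 25, 25),
    tryptic_type = c("HT", "HT", "HT", "FT", "FT"),
    stringsAsFactors = FALSE)
  ints <- data.frame(peptide_id = rec$peptide_id, condition = "c",
                     replicate = 1L, temperature = 37, intensity = 1)
  ds <- peptide_dataset(rec, ints)
  pairs <- match_ht_to_ft(ds)
  expect_true(any(pairs$ht == "ht1" & pairs$ft == "ft1"))   # inside
  expect_false(any(pairs$ht == "ht2"))                       # end outside
  expect_false(any(pairs$ft == "ft2"))                       # other protein
  # coinciding borders pair
  rec2 <- rec
  rec2$start[rec2$peptide_id == "ht3"] <- 8
  rec2$end[rec2$peptide_id == "ht3"] <- 25
  ds2 <- peptide_dataset(rec2, ints)
  expect_true(any(with(match_ht_to_ft(ds2), ht == "ht3" & ft == "ft1")))
})

test_that("containment matching agrees with a brute-force double loop", {
  set.seed(7)
  n <- 40
  rec <- data.frame(
    protein_id = sample(c("A", "B", "C"), n, replace = TRUE),
    peptide_id = sprintf("p%02d", seq_len(n)),
    start = sample(1:80, n, replace = TRUE),
    tryptic_type = sample(c("FT", "HT"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  rec$end <- rec$start + sample(5:30, n, replace = TRUE)
  ints <- data.frame(peptide_id = rec$peptide_id, condition = "c",
                     replicate = 1L, temperature = 37, intensity = 1)
  ds <- peptide_dataset(rec, ints)
  got <- match_ht_to_ft(ds)
  # oracle: exhaustive double loop
  want <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (rec$tryptic_type[i] == "HT" && rec$tryptic_type[j] == "FT" &&
        rec$protein_id[i] == rec$protein_id[j] &&
        rec$start[j] <= rec$start[i] && rec$end[i] <= rec$end[j]) {
      want[[length(want) + 1]] <- paste(rec$peptide_id[i], rec$peptide_id[j])
    }
  }
  expect_setequal(paste(got$ht, got$ft), unlist(want))
})

test_that("HT/FT correlation handles affine, anti-correlated and mirrored profiles", {
  grid <- lip_grid()
  prof <- sigmoid_profile(grid, 55)
  mk <- function(id, vals) data.frame(peptide_id = id, condition = "c",
                                      replicate = 1L, temperature = grid,
                                      intensity = vals)
  rec <- data.frame(protein_id = "A", peptide_id = c("ft", "ht2x", "htneg", "htmir"),
                    start = c(1, 2, 2, 2), end = c(40, 20, 20, 20),
                    tryptic_type = c("FT", "HT", "HT", "HT"),
                    stringsAsFactors = FALSE)
  ints <- rbind(mk("ft", 100 * prof + 5), mk("ht2x", 2 * (100 * prof + 5)),
                mk("htneg", 120 - (100 * prof + 5)), mk("htmir", 100 * (1 - prof) + 5))
  ds <- peptide_dataset(rec, ints)
  pairs <- match_ht_to_ft(ds)
  out <- ht_ft_correlation(pairs, ds)
  r <- setNames(out$r, out$ht)
  expect_equal(unname(r["ht2x"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["htneg"]), -1, tolerance = 1e-12)
  expect_lt(unname(r["htmir"]), 0)
  # oracle: recompute the mirrored pair with the covariance formula
  a <- ints$intensity[ints$peptide_id == "htmir"]
  b <- ints$intensity[ints$peptide_id == "ft"]
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r["htmir"]), r_manual, tolerance = 1e-12)
})

test_that("pairs with too few shared observations are skipped with a warning", {
  rec <- data.frame(protein_id = "A", peptide_id = c("ft", "ht"),
                    start = c(1, 2), end = c(40, 20),
                    tryptic_type = c("FT", "HT"), stringsAsFactors = FALSE)
  ints <- data.frame(peptide_id = c("ft", "ft", "ht", "ht"), condition = "c",
                     replicate = 1L, temperature = c(37, 40.5, 37, 44.4),
                     intensity = c(1, 2, 3, 4))
  ds <- peptide_dataset(rec, ints)
  expect_warning(out <- ht_ft_correlation(match_ht_to_ft(ds), ds), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("domain annotations reject overlapping ranges", {
  ok <- data.frame(protein_id = "A", domain_id = c("d1", "d2"),
                   start = c(1, 50), end = c(40, 90))
  expect_silent(validate_domains <- thermolip::read_domain_annotation(
    write_toy_table(tempfile(fileext = ".tsv"), ok)))
  bad <- data.frame(protein_id = "A", domain_id = c("d1", "d2"),
                    start = c(1, 30), end = c(40, 90))
  expect_error(thermolip::read_domain_annotation(
    write_toy_table(tempfile(fileext = ".tsv"), bad)), "overlap")
})
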