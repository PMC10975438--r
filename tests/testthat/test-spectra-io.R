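test_that("write/read round trip reproduces arrays exactly", {
  s <- simulate_spectrum(c(Coumarin = 2), toy_params(noise_sd = 0.01,
                                                     seed = 5),
                         sample_id = "Cin_cass_99", replicate = 2L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_identical(r$ppm, s$ppm)
  expect_identical(r$intensity, s$intensity)
  m <- attr(r, "meta")
  expect_equal(m$sample_id, "Cin_cass_99")
  expect_equal(m$replicate, 2L)
  expect_equal(m$field_mhz, 400)
})

test_that("descending-ppm files are reversed to ascending on read", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%g %g", seq(12, -0.5, by = -0.5),
                     seq_along(seq(12, -0.5, by = -0.5))), path)
  r <- read_spectrum(path)
  expect_true(all(diff(r$ppm) > 0))
  expect_equal(r$intensity[which.max(r$ppm)], 1)
})

test_that("degenerate or malformed spectrum files give located parse errors", {
  p1 <- withr::local_tempfile(fileext = ".txt")
  writeLines("1.0 5.0", p1)
  expect_error(read_spectrum(p1), "fewer than 2", class = "cinnamr_parse")

  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0 5.0", "2.0 6.0 7.0", "3.0 1.0"), p2)
  err <- expect_error(read_spectrum(p2), class = "cinnamr_parse")
  expect_match(conditionMessage(err), ":2:")

  p3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0 5.0", "2.0 abc"), p3)
  err <- expect_error(read_spectrum(p3), class = "cinnamr_parse")
  expect_match(conditionMessage(err), "non-numeric")
})

test_that("a minimal JCAMP-DX XYDATA block is accepted", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=toy", "##JCAMP-DX=4.24", "##XUNITS=PPM",
    "##FIRSTX=0", "##LASTX=4", "##NPOINTS=5",
    "##XFACTOR=1", "##YFACTOR=0.5",
    "##XYDATA=(X++(Y..Y))",
    "0 2 4 6", "3 8 10",
    "##END="
  ), path)
  r <- read_spectrum(path)
  expect_equal(r$ppm, 0:4)
  expect_equal(r$intensity, c(1, 2, 3, 4, 5))
})

test_that("the bundled concentration table matches its printed source", {
  tbl <- load_concentration_table()
  expect_equal(dplyr::n_distinct(tbl$sample_id), 48L)
  expect_equal(dplyr::n_distinct(tbl$metabolite), 16L)
  expect_equal(nrow(tbl), 48L * 16L)

  v1 <- dplyr::filter(tbl, sample_id == "Cin_veru_01",
                      metabolite == "Coumarin")
  expect_equal(v1$mean, 0.8)
  expect_equal(v1$sd, 0.04)
  expect_false(v1$nd)

  c7 <- dplyr::filter(tbl, sample_id == "Cin_cass_07",
                      metabolite == "Cinnamaldehyde")
  expect_true(c7$nd)
  expect_true(is.na(c7$mean))
})

test_that("species parsed from ids match an independent scan of the CSV", {
  path <- system.file("extdata", "table2_concentrations.csv",
                      package = "cinnamr")
  lines <- readLines(path)[-1]
  oracle <- table(substr(lines, 1, 8))
  tbl <- load_concentration_table()
  counts <- tbl |>
    dplyr::distinct(.data$sample_id, .data$species) |>
    dplyr::count(.data$species)
  expect_equal(counts$n[counts$species == "C. verum"],
               unname(oracle[["Cin_veru"]]))
  expect_equal(counts$n[counts$species == "C. cassia"],
               unname(oracle[["Cin_cass"]]))
  expect_equal(counts$n[counts$species == "C. burmannii"],
               unname(oracle[["Cin_burm"]]))
})

test_that("inconsistent ND pairs and unknown species prefixes are rejected", {
  path <- system.file("extdata", "table2_concentrations.csv",
                      package = "cinnamr")
  lines <- readLines(path)

  bad1 <- withr::local_tempfile(fileext = ".csv")
  fields <- strsplit(lines[2], ",")[[1]]
  fields[2] <- "ND" # mean ND while sd stays numeric
  writeLines(c(lines[1], paste(fields, collapse = ",")), bad1)
  expect_error(load_concentration_table(bad1), "inconsistent ND pair",
               class = "cinnamr_parse")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], sub("^Cin_veru", "Cin_fake", lines[2])), bad2)
  expect_error(load_concentration_table(bad2), "unknown species prefix",
               class = "cinnamr_bad_species")
})

test_that("writing and reloading a concentration table preserves content", {
  tbl <- load_concentration_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(tbl, path)
  back <- load_concentration_table(path)
  expect_equal(back$nd, tbl$nd)
  expect_equal(back$mean, tbl$mean, tolerance = 1e-12)
})
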