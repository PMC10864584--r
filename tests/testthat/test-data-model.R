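# Readers, validity filters, gestation length and lactation assembly.

write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_milkings parses well-formed files and flags bad cells", {
  f <- write_tmp_csv(c("herd_id,animal_id,dim,milk_kg",
                       "H1,A1,1,25.5", "H1,A1,2,26.0", "H2,A2,10,30.1"))
  rec <- read_milkings(f)
  expect_equal(nrow(rec), 3)
  expect_type(rec$dim, "integer")
  expect_equal(rec$milk_kg, c(25.5, 26.0, 30.1))

  f2 <- write_tmp_csv("herd_id,animal_id,dim,milk_kg")
  expect_equal(nrow(read_milkings(f2)), 0)

  f3 <- write_tmp_csv(c("herd_id,animal_id,dim,milk_kg",
                        "H1,A1,1,abc", "H1,A1,2,26.0"))
  expect_error(read_milkings(f3), "milk_kg.*line 2")

  f4 <- write_tmp_csv(c("herd_id,animal_id,dim", "H1,A1,1"))
  expect_error(read_milkings(f4), "missing column.*milk_kg")
  expect_error(read_milkings("no/such/file.csv"), "not found")
})

test_that("read_milkings honours a column remapping schema", {
  f <- write_tmp_csv(c("farm,cow,day,yield", "H9,A7,3,22.5"))
  rec <- read_milkings(f, schema = list(herd_id = "farm", animal_id = "cow",
                                        dim = "day", milk_kg = "yield"))
  expect_equal(rec$herd_id, "H9")
  expect_equal(rec$milk_kg, 22.5)
})

test_that("validity filters keep inclusive bounds and tally per rule", {
  recs <- data.frame(
    herd_id = "H1", animal_id = paste0("A", 1:7),
    dim = c(1L, 305L, 306L, 0L, 100L, 100L, 100L),
    milk_kg = c(1.0, 70.0, 30.0, 30.0, 0.5, 70.5, 35.0))
  out <- filter_milkings(recs)
  expect_equal(nrow(out$retained), 3)  # bounds are inclusive on both sides
  expect_true(all(c("A1", "A2", "A7") %in% out$retained$animal_id))
  expect_equal(unname(out$dropped_counts["dim_gt_305"]), 1)
  expect_equal(unname(out$dropped_counts["dim_lt_1"]), 1)
  expect_equal(unname(out$dropped_counts["my_out_of_range"]), 2)
})

test_that("filtering is idempotent and partitions its input", {
  set.seed(5)
  recs <- data.frame(
    herd_id = "H1", animal_id = sprintf("A%03d", 1:500),
    dim = sample(-5:320, 500, replace = TRUE),
    milk_kg = runif(500, -3, 80))
  out <- filter_milkings(recs)
  expect_equal(nrow(out$retained) + sum(out$dropped_counts), nrow(recs))
  again <- filter_milkings(out$retained)
  expect_identical(again$retained, out$retained)
  expect_equal(sum(again$dropped_counts), 0)
})

test_that("gestation length is date arithmetic with an inclusion window", {
  gl <- compute_gestation_length(as.Date("2017-01-01"), as.Date("2017-10-07"))
  expect_equal(gl$gl_days, 279L)
  expect_true(gl$included)

  gl149 <- compute_gestation_length(as.Date("2017-01-01"), as.Date("2017-05-30"))
  expect_equal(gl149$gl_days, 149L)
  expect_false(gl149$included)  # outside window: excluded, not an error

  gl297 <- compute_gestation_length(as.Date("2017-01-01"), as.Date("2017-10-25"))
  expect_equal(gl297$gl_days, 297L)
  expect_true(gl297$included)  # upper bound inclusive

  expect_error(
    compute_gestation_length(as.Date("2017-10-07"), as.Date("2017-01-01")),
    "calving on or before")
})

make_repro_row <- function(animal_id, gl, herd_id = "H1",
                           calving = as.Date("2017-06-01")) {
  data.frame(herd_id = herd_id, animal_id = animal_id,
             birth_date = calving - 730L,
             last_insemination_date = calving - gl,
             calving_date = calving, service_type = "AI",
             stringsAsFactors = FALSE)
}

make_milk_rows <- function(animal_id, dims, herd_id = "H1") {
  data.frame(herd_id = herd_id, animal_id = animal_id, dim = as.integer(dims),
             milk_kg = 25 + 0.01 * dims, stringsAsFactors = FALSE)
}

test_that("lactation assembly joins, derives covariates and applies rules", {
  repro <- rbind(make_repro_row("A1", 279L), make_repro_row("A2", 279L),
                 make_repro_row("A3", 158L), make_repro_row("A4", 149L))
  milk <- rbind(make_milk_rows("A1", 1:30), make_milk_rows("A2", 1:9),
                make_milk_rows("A3", 1:40), make_milk_rows("A4", 1:40),
                make_milk_rows("A9", 1:20))  # A9 has no repro record

  expect_message(assemble_lactations(milk, repro), "no repro record")
  res <- suppressMessages(assemble_lactations(milk, repro))
  # A1 kept (30 d), A2 dropped (max DIM 9), A3 kept (short GL is in scope),
  # A4 dropped (GL 149 outside window)
  expect_setequal(res$lactations$animal_id, c("A1", "A3"))
  expect_equal(unname(res$dropped_counts["below_min_dim"]), 1)
  expect_equal(unname(res$dropped_counts["gl_out_of_range"]), 1)
  expect_equal(unname(res$dropped_counts["no_repro_record"]), 1)
  expect_equal(res$lactations$gl_days[res$lactations$animal_id == "A3"], 158L)

  a1 <- res$lactations[res$lactations$animal_id == "A1", ]
  expect_equal(a1$afc, 730L)
  expect_equal(a1$afc_months, 730 / 30.4375)
  expect_equal(a1$calving_month, 6L)
  expect_equal(a1$calving_year, 2017L)
  expect_equal(sum(res$milkings$animal_id == "A1"), 30)
})

test_that("assembly rejects duplicate records and supports the n-records rule", {
  repro_dup <- rbind(make_repro_row("A1", 279L), make_repro_row("A1", 280L))
  expect_error(assemble_lactations(make_milk_rows("A1", 1:20), repro_dup),
               "duplicate repro")

  milk_dup <- rbind(make_milk_rows("A1", 1:20), make_milk_rows("A1", 20))
  expect_error(assemble_lactations(milk_dup, make_repro_row("A1", 279L)),
               "duplicate milking")

  # sparse recording: max DIM 30 but only 5 records
  sparse <- make_milk_rows("A1", c(1, 5, 12, 20, 30))
  by_max <- assemble_lactations(sparse, make_repro_row("A1", 279L))
  expect_equal(nrow(by_max$lactations), 1)
  by_n <- assemble_lactations(sparse, make_repro_row("A1", 279L),
                              min_dim_rule = "n_records")
  expect_equal(nrow(by_n$lactations), 0)
})

test_that("write/read round-trip preserves identifiers, dates and yields", {
  f <- withr::local_tempfile(fileext = ".csv")
  orig <- data.frame(herd_id = c("H1", "H2"), animal_id = c("A01", "A02"),
                     dim = c(7L, 305L), milk_kg = c(25.125, 69.999))
  write_records(orig, f)
  back <- read_milkings(f)
  expect_identical(back$herd_id, orig$herd_id)
  expect_identical(back$animal_id, orig$animal_id)
  expect_identical(back$dim, orig$dim)
  expect_identical(back$milk_kg, orig$milk_kg)
})
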