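test_that("read_survey collapses duplicates, drops zero cover and grasses", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot,subplot,nutrient,invasion,species,cover",
    "p1,s1,control,early,Aster laevis,5",
    "p1,s1,control,early,Aster laevis,5",
    "p1,s1,control,early,Aster laevis,2",
    "p1,s1,control,early,Ratibida pinnata,0",
    "p1,s1,control,early,grasses,40",
    "p1,s2,control,early, Aster laevis ,1"
  ), f)
  m <- read_survey(f)
  expect_equal(nrow(m$detections), 2) # one per subplot, trimmed to same name
  expect_equal(species_names(m), "Aster laevis")
  expect_false("Ratibida pinnata" %in% species_names(m))
})

test_that("read_survey validates schema and treatment labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot,subplot,species", "p1,s1,A"), f)
  expect_error(read_survey(f), "required column")
  writeLines(c(
    "plot,subplot,nutrient,invasion,species",
    "p1,s1,control,early,A",
    "p1,s2,fertilised,early,B"
  ), f)
  expect_error(read_survey(f), "row 2")
})

test_that("toy survey: 2 plots x 2 subplots x 3 species all present -> 12 detections", {
  rows <- tidyr::expand_grid(
    plot = c("p1", "p2"), subplot = c("s1", "s2"), species = c("A", "B", "C")
  ) |>
    dplyr::mutate(nutrient = "control", invasion = "late", cover = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rows, f)
  m <- read_survey(f)
  expect_equal(nrow(m$detections), 12)
})

test_that("survey round-trips through write_survey/read_survey", {
  X <- withr::with_seed(5, random_X(6, 8))
  m <- matrix_from_X(X)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(m, f)
  m2 <- read_survey(f)
  key <- function(mm) {
    dplyr::arrange(mm$detections, plot, unit, species)
  }
  expect_equal(key(m2), key(m))
})

test_that("perimeter walk becomes a tenth all-or-nothing unit per plot", {
  X <- withr::with_seed(1, random_X(9, 5))
  colnames(X) <- paste0("sp", 1:ncol(X))
  m <- matrix_from_X(X)
  before <- to_frequencies(m)
  # spX is new to the plot, sp1 is already detected somewhere
  walk <- tibble::tibble(plot = "p1", species = c("spX", colnames(X)[1]))
  expect_warning(m2 <- attach_perimeter_walk(m, walk), "dropped")
  expect_equal(nrow(m2$units), 10)
  expect_equal(sum(m2$units$kind == "perimeter_walk"), 1)
  after <- to_frequencies(m2)
  expect_equal(after$Y[after$species == "spX"], 1L)
  # already-detected species keeps its subplot frequency, walk adds nothing
  expect_equal(
    after$Y[after$species == colnames(X)[1]],
    before$Y[before$species == colnames(X)[1]]
  )
  # empty walk set still appends a unit (T constant across plots)
  m3 <- attach_perimeter_walk(m, tibble::tibble(plot = character(),
                                                species = character()))
  expect_equal(nrow(m3$units), 10)
  expect_equal(nrow(m3$detections), nrow(m$detections))
})

test_that("analysis subset keeps the 2x2 factorial: 320 units, 80 per combination", {
  cfg <- sim_config(seed = 11)
  full <- generate_design(cfg, full_factorial = TRUE)
  expect_equal(nrow(full$units), 960) # 12 combos x 8 plots x 10 units
  sub <- filter_analysis_subset(full)
  expect_equal(dplyr::n_distinct(sub$units$plot), 32)
  expect_equal(nrow(sub$units), 320)
  per_combo <- sub$units |>
    dplyr::count(nutrient, invasion)
  expect_equal(nrow(per_combo), 4)
  expect_true(all(per_combo$n == 80))
  # idempotent
  expect_equal(filter_analysis_subset(sub)$units, sub$units)
  expect_error(filter_analysis_subset(full, assembly = "nonexistent"),
               "available")
})

test_that("to_frequencies matches hand counts and conserves detections", {
  # 1 unit, 3 species
  m1 <- matrix_from_X(matrix(1, 1, 3))
  f1 <- to_frequencies(m1)
  expect_equal(attr(f1, "T"), 1L)
  expect_equal(attr(f1, "U"), 3L)
  expect_equal(attr(f1, "S_obs"), 3L)
  expect_equal(attr(f1, "Q1"), 3L)
  # identical units: T=5, 2 species everywhere
  m2 <- matrix_from_X(matrix(1, 5, 2))
  f2 <- to_frequencies(m2)
  expect_equal(sort(f2$Y), c(5L, 5L))
  expect_equal(attr(f2, "U"), 10L)
  expect_equal(attr(f2, "Q1") + attr(f2, "Q2"), 0L)
  # T=4, Y=(4,2,1) by hand
  X <- matrix(0, 4, 3)
  X[, 1] <- 1; X[1:2, 2] <- 1; X[1, 3] <- 1
  f3 <- to_frequencies(matrix_from_X(X))
  expect_equal(sort(f3$Y, decreasing = TRUE), c(4L, 2L, 1L))
  expect_equal(attr(f3, "U"), 7L)
  expect_equal(attr(f3, "Q1"), 1L)
  expect_equal(attr(f3, "Q2"), 1L)
  # conservation: sum Y = number of detection records
  expect_equal(attr(f3, "U"), nrow(matrix_from_X(X)$detections))
  expect_error(to_frequencies(m2, treatment = "nutrients.late"), "no sampling units")
})

test_that("filtering commutes with frequency extraction", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_experiment(cfg, full_factorial = TRUE)
  sub <- filter_analysis_subset(sim$survey)
  f_direct <- to_frequencies(sub, treatment = "control.early")
  f_full <- to_frequencies(sim$survey,
                           plots = sub$units$plot[
                             sub$units$nutrient == "control" &
                               sub$units$invasion == "early"
                           ])
  expect_equal(f_direct$species, f_full$species)
  expect_equal(f_direct$Y, f_full$Y)
  expect_equal(attr(f_direct, "T"), attr(f_full, "T"))
})

test_that("per-treatment frequency export is tidy and consistent", {
  cfg <- sim_config(seed = 9)
  sim <- simulate_experiment(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  out <- write_frequencies(sim$survey, f)
  expect_named(out, c("treatment", "species", "Y", "T"))
  expect_setequal(unique(out$treatment), treatment_levels()$treatment)
  expect_true(all(out$T == 80))
  expect_true(all(out$Y >= 1 & out$Y <= out$T))
})
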