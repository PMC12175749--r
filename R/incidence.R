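# Incidence data model: sampling units (surveyed subplots + optional
# perimeter-walk pseudo-subplot per plot) and binary species detections.

#' Construct an incidence matrix object
#'
#' An `incidence_matrix` holds the sampling design (one row per sampling
#' unit, with its plot and treatment metadata) and the binary detections
#' (one row per unit x species detection). Units with no detections are
#' legitimate and retained, which is why the two tables are kept side by
#' side rather than as a single long table.
#'
#' @param units Tibble with columns `plot`, `unit`, `kind`
#'   (`"surveyed_subplot"` or `"perimeter_walk"`), `nutrient`, `invasion`
#'   and optionally `assembly` and `area_m2`.
#' @param detections Tibble with columns `plot`, `unit`, `species`; one row
#'   per detection (duplicates are collapsed).
#' @return An object of class `incidence_matrix`.
#' @export
incidence_matrix <- function(units, detections) {
  units <- as_tibble(units)
  detections <- as_tibble(detections)
  required <- c("plot", "unit", "kind")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    abort(paste0("`units` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("nutrient", "invasion") %in% names(units))) {
    abort("`units` must carry treatment columns `nutrient` and `invasion`")
  }
  bad_kind <- setdiff(unique(units$kind), c("surveyed_subplot", "perimeter_walk"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown sampling-unit kind: ", paste(bad_kind, collapse = ", ")))
  }
  if (!"area_m2" %in% names(units)) {
    units$area_m2 <- ifelse(units$kind == "surveyed_subplot", 0.25, NA_real_)
  }
  if (anyDuplicated(units[c("plot", "unit")]) > 0) {
    abort("unit ids must be unique within plot")
  }
  n_walk <- units |>
    filter(.data$kind == "perimeter_walk") |>
    count(.data$plot)
  if (any(n_walk$n > 1)) {
    abort("each plot may carry at most one perimeter-walk unit")
  }
  # one treatment per plot
  tr <- distinct(units, .data$plot, .data$nutrient, .data$invasion)
  if (anyDuplicated(tr$plot) > 0) {
    abort("conflicting treatment labels within a plot")
  }
  miss_nut <- setdiff(unique(as.character(units$nutrient)), .nutrient_levels)
  miss_inv <- setdiff(unique(as.character(units$invasion)), .invasion_levels)
  if (length(miss_nut) > 0 || length(miss_inv) > 0) {
    abort(paste0(
      "unknown treatment label(s): ",
      paste(c(miss_nut, miss_inv), collapse = ", ")
    ))
  }
  detections <- detections |>
    mutate(species = trimws(as.character(.data$species))) |>
    distinct(.data$plot, .data$unit, .data$species)
  unknown <- anti_join(detections, units, by = c("plot", "unit"))
  if (nrow(unknown) > 0) {
    abort(paste0(
      "detections reference unknown unit(s): ",
      paste(utils::head(paste(unknown$plot, unknown$unit, sep = "/"), 5), collapse = ", ")
    ))
  }
  structure(
    list(units = units, detections = detections),
    class = "incidence_matrix"
  )
}

#' @export
print.incidence_matrix <- function(x, ...) {
  n_plot <- dplyr::n_distinct(x$units$plot)
  cat(
    "<incidence_matrix> ", nrow(x$units), " sampling units, ",
    n_plot, " plots, ",
    dplyr::n_distinct(x$detections$species), " species, ",
    nrow(x$detections), " detections\n",
    sep = ""
  )
  invisible(x)
}

#' @method as_tibble incidence_matrix
#' @export
as_tibble.incidence_matrix <- function(x, ...) {
  left_join(x$detections, x$units, by = c("plot", "unit"))
}

#' Species detected in an incidence matrix
#' @param x An `incidence_matrix`.
#' @return Character vector of species names, sorted.
#' @export
species_names <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  sort(unique(x$detections$species))
}

#' Read a long-format survey file
#'
#' Expects a UTF-8 CSV with header and columns
#' `plot,subplot,nutrient,invasion,species` plus optional `assembly` and
#' `cover`. A row records one species observed in one subplot; `cover > 0`
#' (or a bare presence row without a cover column) becomes a detection,
#' `cover = 0` is ignored, and duplicated rows collapse to a single
#' detection. Perimeter walks appear as rows with `subplot = "perimeter"`.
#' Grasses are surveyed as a single lumped group and are not part of the
#' forb species pool; rows whose species matches `drop_species` are dropped
#' at ingestion.
#'
#' @param path CSV file path.
#' @param drop_species Species labels excluded at ingestion (default the
#'   lumped grass group, case-insensitive match on `"grass"`/`"grasses"`).
#' @return An [incidence_matrix()].
#' @export
read_survey <- function(path, drop_species = c("grass", "grasses")) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("plot", "subplot", "nutrient", "invasion", "species")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("survey file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(raw$nutrient %in% .nutrient_levels) |
                 !(raw$invasion %in% .invasion_levels))
  if (length(bad) > 0) {
    abort(paste0("unknown treatment label in row ", bad[1], ": nutrient=",
                 raw$nutrient[bad[1]], ", invasion=", raw$invasion[bad[1]]))
  }
  if ("cover" %in% names(raw)) {
    cover <- suppressWarnings(as.numeric(raw$cover))
    keep <- is.na(cover) | cover > 0
    raw <- raw[keep, , drop = FALSE]
  }
  raw$species <- trimws(raw$species)
  raw <- raw[!(tolower(raw$species) %in% tolower(drop_species)), , drop = FALSE]

  unit_cols <- intersect(c("plot", "subplot", "nutrient", "invasion", "assembly"),
                         names(raw))
  units <- raw |>
    distinct(dplyr::across(dplyr::all_of(unit_cols))) |>
    rename(unit = "subplot") |>
    mutate(kind = ifelse(.data$unit == "perimeter", "perimeter_walk",
                         "surveyed_subplot"))
  detections <- raw |>
    transmute(plot = .data$plot, unit = .data$subplot, species = .data$species) |>
    distinct()
  incidence_matrix(units, detections)
}

#' Write a survey file
#'
#' Inverse of [read_survey()]: writes the long CSV dialect (one row per
#' detection; perimeter walks with `subplot = "perimeter"`). Units with no
#' detections are necessarily absent from the file.
#'
#' @param x An `incidence_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  out <- as_tibble(x) |>
    transmute(
      plot = .data$plot, subplot = .data$unit,
      nutrient = .data$nutrient, invasion = .data$invasion,
      assembly = if ("assembly" %in% names(x$units)) .data$assembly else NULL,
      species = .data$species, cover = 1
    ) |>
    arrange(.data$plot, .data$subplot, .data$species)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Append the perimeter-walk pseudo-subplot to each plot
#'
#' The rare-species walk around each plot is treated as a tenth sampling
#' unit. By design it carries only walk-exclusive species: a species already
#' detected in a surveyed subplot of the same plot is dropped from the walk
#' unit (with a warning) so nothing is double counted. Plots with an empty
#' (or absent) walk record still receive an all-zero perimeter unit so that
#' every plot has the same number of sampling units.
#'
#' @param x An `incidence_matrix` containing only surveyed subplots.
#' @param walk_records Tibble with columns `plot`, `species`; one row per
#'   species seen on that plot's walk. May be empty.
#' @return An `incidence_matrix` with one `perimeter_walk` unit per plot.
#' @export
attach_perimeter_walk <- function(x, walk_records) {
  stopifnot(inherits(x, "incidence_matrix"))
  if (any(x$units$kind == "perimeter_walk")) {
    abort("matrix already contains perimeter-walk units")
  }
  walk_records <- as_tibble(walk_records)
  if (nrow(walk_records) > 0) {
    stopifnot(all(c("plot", "species") %in% names(walk_records)))
    walk_records <- walk_records |>
      mutate(species = trimws(as.character(.data$species))) |>
      distinct(.data$plot, .data$species)
    dup <- semi_join(walk_records,
                     x$detections |> distinct(.data$plot, .data$species),
                     by = c("plot", "species"))
    if (nrow(dup) > 0) {
      warn(paste0(
        nrow(dup), " walk species already detected in surveyed subplots ",
        "of the same plot; dropped from the walk unit"
      ))
      walk_records <- anti_join(walk_records, dup, by = c("plot", "species"))
    }
  }
  plot_meta <- x$units |>
    distinct(dplyr::across(dplyr::all_of(
      intersect(c("plot", "nutrient", "invasion", "assembly"), names(x$units))
    )))
  walk_units <- plot_meta |>
    mutate(unit = "perimeter", kind = "perimeter_walk", area_m2 = NA_real_)
  walk_det <- walk_records |>
    semi_join(plot_meta, by = "plot") |>
    mutate(unit = "perimeter")
  incidence_matrix(
    bind_rows(x$units, walk_units),
    bind_rows(x$detections, walk_det |> select("plot", "unit", "species"))
  )
}

#' Restrict a full factorial design to the analysis subset
#'
#' The full experiment crosses nutrients and invasion timing with a
#' three-level seeding-assembly treatment; the diversity analysis uses only
#' the plots where grasses and forbs were seeded together, leaving the 2x2
#' nutrient x invasion factorial. Idempotent on already-filtered input.
#'
#' @param x An `incidence_matrix`; its `units` must carry an `assembly`
#'   column when more than the target level is present.
#' @param assembly The assembly level to keep (default `"both"`).
#' @return A filtered `incidence_matrix` containing only the 2x2 factorial.
#' @export
filter_analysis_subset <- function(x, assembly = "both") {
  stopifnot(inherits(x, "incidence_matrix"))
  if (!"assembly" %in% names(x$units)) {
    # no assembly factor ingested: treat as already filtered
    return(x)
  }
  available <- unique(x$units$assembly)
  if (!assembly %in% available) {
    abort(paste0(
      "assembly level '", assembly, "' absent; available: ",
      paste(available, collapse = ", ")
    ))
  }
  keep_units <- filter(x$units, .data$assembly == !!assembly)
  keep_det <- semi_join(x$detections, keep_units, by = c("plot", "unit"))
  incidence_matrix(keep_units, keep_det)
}

.select_units <- function(x, treatment = NULL, plots = NULL, units = NULL) {
  u <- x$units
  if (!is.null(treatment)) {
    u <- u |>
      mutate(.tr = .treatment_label(.data$nutrient, .data$invasion)) |>
      filter(.data$.tr %in% !!treatment) |>
      select(-".tr")
  }
  if (!is.null(plots)) u <- filter(u, .data$plot %in% !!plots)
  if (!is.null(units)) {
    u <- semi_join(u, as_tibble(units), by = intersect(c("plot", "unit"), names(as_tibble(units))))
  }
  u
}

#' Incidence frequencies of an assemblage
#'
#' Collapses the selected sampling units to the sufficient statistics of all
#' incidence-based Hill estimators: the number of units T, each species'
#' incidence frequency Y_i (number of selected units in which it was
#' detected), the total U = sum(Y_i), and the unique/duplicate counts Q1 and
#' Q2. Species absent from every selected unit are dropped.
#'
#' @param x An `incidence_matrix`.
#' @param treatment Optional character vector of treatment labels
#'   (`"nutrient.invasion"`, see [treatment_levels()]).
#' @param plots Optional vector of plot ids.
#' @param units Optional tibble of (`plot`, `unit`) rows to keep.
#' @return A tibble of class `incidence_freq` with columns `species`, `Y`,
#'   sorted by decreasing `Y`, and attributes `T`, `U`, `S_obs`, `Q1`, `Q2`.
#' @export
to_frequencies <- function(x, treatment = NULL, plots = NULL, units = NULL) {
  stopifnot(inherits(x, "incidence_matrix"))
  u <- .select_units(x, treatment = treatment, plots = plots, units = units)
  if (nrow(u) == 0) abort("selection matches no sampling units")
  det <- semi_join(x$detections, u, by = c("plot", "unit"))
  freq <- det |>
    count(.data$species, name = "Y") |>
    arrange(desc(.data$Y), .data$species)
  out <- new_incidence_freq(freq$Y, freq$species, T_units = nrow(u))
  # unit-level detections and species co-occurrence counts travel along:
  # the functional estimators need them (group incidence at q = 0, exact
  # second moments at q = 2)
  X <- .incidence_logical(x, treatment = treatment, plots = plots, units = units)
  attr(out, "X") <- X
  attr(out, "cooc") <- crossprod(X)[out$species, out$species, drop = FALSE]
  out
}

#' Build an incidence-frequency object from raw counts
#'
#' Mostly useful for worked examples and tests: supply the incidence
#' frequencies Y_i directly rather than deriving them from survey data.
#'
#' @param Y Integer vector of incidence frequencies (one per species).
#' @param species Optional species names (defaults to `sp1`, `sp2`, ...).
#' @param T_units Number of sampling units T; must be `>= max(Y)`.
#' @return An `incidence_freq` tibble; see [to_frequencies()].
#' @export
incidence_freq <- function(Y, T_units, species = NULL) {
  new_incidence_freq(Y, species, T_units)
}

new_incidence_freq <- function(Y, species, T_units) {
  Y <- as.integer(Y)
  if (is.null(species)) species <- paste0("sp", seq_along(Y))
  keep <- Y > 0
  Y <- Y[keep]
  species <- species[keep]
  if (length(Y) > 0 && (T_units < max(Y) || any(Y < 1))) {
    abort("incidence frequencies must satisfy 1 <= Y_i <= T")
  }
  out <- tibble(species = species, Y = Y)
  attr(out, "T") <- as.integer(T_units)
  attr(out, "U") <- sum(Y)
  attr(out, "S_obs") <- length(Y)
  attr(out, "Q1") <- sum(Y == 1L)
  attr(out, "Q2") <- sum(Y == 2L)
  class(out) <- c("incidence_freq", class(out))
  out
}

#' @export
print.incidence_freq <- function(x, ...) {
  cat("<incidence_freq> T = ", attr(x, "T"),
      ", S_obs = ", attr(x, "S_obs"),
      ", U = ", attr(x, "U"),
      ", Q1 = ", attr(x, "Q1"),
      ", Q2 = ", attr(x, "Q2"), "\n", sep = "")
  NextMethod()
}

#' @describeIn to_frequencies One-row summary (T, U, S_obs, Q1, Q2 and the
#'   Chao2 asymptotic richness estimate) of an `incidence_freq` object.
#' @param x,... passed through.
#' @method glance incidence_freq
#' @export
glance.incidence_freq <- function(x, ...) {
  tibble(
    T = attr(x, "T"), U = attr(x, "U"), S_obs = attr(x, "S_obs"),
    Q1 = attr(x, "Q1"), Q2 = attr(x, "Q2"),
    S_chao2 = attr(x, "S_obs") + chao2_q0hat(x)
  )
}

#' Write per-treatment incidence frequencies
#'
#' Tidy export (`treatment,species,Y,T`) of the incidence frequencies of
#' every treatment combination present in the matrix.
#'
#' @param x An `incidence_matrix`.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_frequencies <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  trts <- x$units |>
    distinct(.data$nutrient, .data$invasion) |>
    mutate(treatment = .treatment_label(.data$nutrient, .data$invasion))
  out <- purrr::map_dfr(trts$treatment, function(tr) {
    f <- to_frequencies(x, treatment = tr)
    tibble(treatment = tr, species = f$species, Y = f$Y, T = attr(f, "T"))
  })
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}

# unit x species logical matrix for fast bootstrap work
.incidence_logical <- function(x, treatment = NULL, plots = NULL, units = NULL) {
  u <- .select_units(x, treatment = treatment, plots = plots, units = units)
  if (nrow(u) == 0) abort("selection matches no sampling units")
  det <- semi_join(x$detections, u, by = c("plot", "unit"))
  sp <- sort(unique(det$species))
  key_u <- paste(u$plot, u$unit, sep = "\r")
  key_d <- paste(det$plot, det$unit, sep = "\r")
  m <- matrix(FALSE, nrow = nrow(u), ncol = length(sp),
              dimnames = list(key_u, sp))
  if (nrow(det) > 0) {
    m[cbind(match(key_d, key_u), match(det$species, sp))] <- TRUE
  }
  m
}
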