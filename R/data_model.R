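# Readers, validity filters and lactation assembly for herd management
# records. Two delimited inputs: daily milkings (herd, animal, DIM, kg) and
# reproduction/life events (birth, last insemination, calving). DIM origin:
# day of calving is DIM 0; the first recorded milking is DIM 1.

default_milking_schema <- list(
  herd_id = "herd_id", animal_id = "animal_id",
  dim = "dim", milk_kg = "milk_kg"
)

default_repro_schema <- list(
  herd_id = "herd_id", animal_id = "animal_id",
  birth_date = "birth_date",
  last_insemination_date = "last_insemination_date",
  calving_date = "calving_date", service_type = "service_type"
)

check_columns <- function(df, schema, path) {
  missing <- setdiff(unlist(schema), names(df))
  if (length(missing))
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop("parse error in '", path, "', column '", col, "': non-numeric value ",
         "'", x[bad[1]], "' at data line ", bad[1] + 1L,
         if (length(bad) > 1) paste0(" (and ", length(bad) - 1L, " more)"),
         call. = FALSE)
  out
}

parse_date_col <- function(x, col, path) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop("parse error in '", path, "', column '", col, "': invalid date ",
         "'", x[bad[1]], "' at data line ", bad[1] + 1L, call. = FALSE)
  out
}

#' Read a daily-milkings table
#'
#' Parses a delimited file of daily milk records. No filtering happens here;
#' see \code{\link{filter_milkings}}.
#'
#' @param path CSV file with a header row.
#' @param schema named list mapping the canonical names \code{herd_id},
#'   \code{animal_id}, \code{dim}, \code{milk_kg} to the file's column
#'   names; defaults to the identity mapping.
#' @param sep field separator.
#' @return A \code{data.frame} with columns \code{herd_id}, \code{animal_id}
#'   (character), \code{dim} (integer) and \code{milk_kg} (numeric).
#' @export
read_milkings <- function(path, schema = default_milking_schema, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  schema <- utils::modifyList(default_milking_schema, as.list(schema))
  check_columns(raw, schema, path)
  if (nrow(raw) == 0)
    return(data.frame(herd_id = character(), animal_id = character(),
                      dim = integer(), milk_kg = numeric()))
  data.frame(
    herd_id = raw[[schema$herd_id]],
    animal_id = raw[[schema$animal_id]],
    dim = as.integer(parse_numeric_col(raw[[schema$dim]], "dim", path)),
    milk_kg = parse_numeric_col(raw[[schema$milk_kg]], "milk_kg", path),
    stringsAsFactors = FALSE
  )
}

#' Read a reproduction-events table
#'
#' Parses a delimited file of per-animal life events (first parity). Dates
#' must be ISO-8601. Validates \code{birth < insemination < calving}.
#'
#' @inheritParams read_milkings
#' @param schema named list mapping canonical names (see
#'   \code{default_repro_schema}) to the file's column names.
#' @return A \code{data.frame} with identifier, date and service-type
#'   columns; dates as \code{Date}.
#' @export
read_repro <- function(path, schema = default_repro_schema, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  schema <- utils::modifyList(default_repro_schema, as.list(schema))
  check_columns(raw, schema, path)
  if (nrow(raw) == 0)
    return(data.frame(herd_id = character(), animal_id = character(),
                      birth_date = as.Date(character()),
                      last_insemination_date = as.Date(character()),
                      calving_date = as.Date(character()),
                      service_type = character()))
  out <- data.frame(
    herd_id = raw[[schema$herd_id]],
    animal_id = raw[[schema$animal_id]],
    birth_date = parse_date_col(raw[[schema$birth_date]], "birth_date", path),
    last_insemination_date = parse_date_col(
      raw[[schema$last_insemination_date]], "last_insemination_date", path),
    calving_date = parse_date_col(raw[[schema$calving_date]], "calving_date", path),
    service_type = raw[[schema$service_type]],
    stringsAsFactors = FALSE
  )
  bad <- which(!(out$birth_date < out$last_insemination_date &
                   out$last_insemination_date < out$calving_date))
  if (length(bad))
    stop("invalid repro record for animal(s) ",
         paste(utils::head(out$animal_id[bad], 5), collapse = ", "),
         ": dates must satisfy birth < insemination < calving", call. = FALSE)
  out
}

#' Apply the observational validity filters to daily milkings
#'
#' Retains records with \code{1 <= dim <= 305} and
#' \code{1.0 <= milk_kg <= 70.0} (all bounds inclusive); everything else is
#' dropped and tallied per rule. A record failing both rules is tallied under
#' the DIM rule (applied first).
#'
#' @param records milkings \code{data.frame} from \code{\link{read_milkings}}.
#' @return A list with \code{retained} (data.frame) and \code{dropped_counts}
#'   (named integer vector: \code{dim_gt_305}, \code{dim_lt_1},
#'   \code{my_out_of_range}).
#' @export
filter_milkings <- function(records) {
  stopifnot(all(c("dim", "milk_kg") %in% names(records)))
  dim_hi <- records$dim > 305
  dim_lo <- records$dim < 1
  my_bad <- !dim_hi & !dim_lo &
    (records$milk_kg < 1.0 | records$milk_kg > 70.0 | is.na(records$milk_kg))
  keep <- !dim_hi & !dim_lo & !my_bad
  list(
    retained = records[keep, , drop = FALSE],
    dropped_counts = c(
      dim_gt_305 = sum(dim_hi),
      dim_lt_1 = sum(dim_lo),
      my_out_of_range = sum(my_bad)
    )
  )
}

#' Gestation length from a reproduction record
#'
#' Days from last insemination to the subsequent calving (or abortion).
#' Values outside the plausible window [150, 297] days are flagged as
#' excluded rather than raising an error; calving before insemination is an
#' invalid record.
#'
#' @param last_insemination_date,calving_date \code{Date} vectors.
#' @param range inclusive plausibility window in days.
#' @return A \code{data.frame} with \code{gl_days} (integer) and
#'   \code{included} (logical).
#' @examples
#' compute_gestation_length(as.Date("2017-01-01"), as.Date("2017-10-07"))
#' @export
compute_gestation_length <- function(last_insemination_date, calving_date,
                                     range = c(150L, 297L)) {
  gl <- as.integer(calving_date - last_insemination_date)
  if (any(gl <= 0, na.rm = TRUE))
    stop("invalid record: calving on or before last insemination", call. = FALSE)
  data.frame(gl_days = gl, included = gl >= range[1] & gl <= range[2])
}

#' Assemble per-animal first lactations
#'
#' Joins filtered milkings to reproduction records, computes gestation
#' length, age at first calving and calving month/year, and applies the
#' minimum days-in-milk rule. By default a lactation is kept when its last
#' retained milking falls at DIM >= 10 (\code{min_dim_rule = "max_dim"});
#' the alternative reading, at least 10 milk records, is available as
#' \code{min_dim_rule = "n_records"}.
#'
#' @param milkings filtered milkings \code{data.frame}.
#' @param repro validated repro \code{data.frame} (one row per animal).
#' @param min_dim minimum days in milk (default 10).
#' @param min_dim_rule \code{"max_dim"} or \code{"n_records"}.
#' @param gl_range inclusive gestation-length window in days.
#' @return A list:
#'   \describe{
#'     \item{lactations}{one row per retained animal: identifiers,
#'       \code{gl_days}, \code{afc} (days), \code{afc_months},
#'       \code{calving_month}, \code{calving_year}, \code{n_milkings},
#'       \code{max_dim}.}
#'     \item{milkings}{the milking rows of retained animals, sorted by
#'       animal and DIM.}
#'     \item{dropped_counts}{animals removed per rule (\code{gl_out_of_range},
#'       \code{below_min_dim}, \code{no_repro_record}, \code{no_milkings}).}
#'   }
#' @export
assemble_lactations <- function(milkings, repro, min_dim = 10L,
                                min_dim_rule = c("max_dim", "n_records"),
                                gl_range = c(150L, 297L)) {
  min_dim_rule <- match.arg(min_dim_rule)
  if (anyDuplicated(repro$animal_id))
    stop("duplicate repro records for animal(s): ",
         paste(unique(repro$animal_id[duplicated(repro$animal_id)]),
               collapse = ", "), call. = FALSE)

  milkings <- milkings[order(milkings$animal_id, milkings$dim), , drop = FALSE]
  dup <- duplicated(milkings[c("animal_id", "dim")])
  if (any(dup))
    stop("duplicate milking per animal/DIM for animal(s): ",
         paste(unique(milkings$animal_id[dup]), collapse = ", "), call. = FALSE)

  orphan <- setdiff(unique(milkings$animal_id), repro$animal_id)
  if (length(orphan))
    message(length(orphan), " animal(s) with milkings but no repro record; skipped")

  gl <- compute_gestation_length(repro$last_insemination_date,
                                 repro$calving_date, range = gl_range)
  repro$gl_days <- gl$gl_days
  gl_ok <- gl$included

  stat <- stats::aggregate(dim ~ animal_id, data = milkings,
                           FUN = function(x) c(n = length(x), mx = max(x)))
  stats_df <- data.frame(animal_id = stat$animal_id,
                         n_milkings = stat$dim[, "n"],
                         max_dim = stat$dim[, "mx"],
                         stringsAsFactors = FALSE)
  m <- match(repro$animal_id, stats_df$animal_id)
  repro$n_milkings <- stats_df$n_milkings[m]
  repro$max_dim <- stats_df$max_dim[m]

  has_milk <- !is.na(repro$n_milkings)
  dim_ok <- has_milk & (if (min_dim_rule == "max_dim")
    repro$max_dim >= min_dim else repro$n_milkings >= min_dim)

  keep <- gl_ok & dim_ok
  dropped <- c(
    gl_out_of_range = sum(!gl_ok),
    below_min_dim = sum(gl_ok & has_milk & !dim_ok),
    no_milkings = sum(gl_ok & !has_milk),
    no_repro_record = length(orphan)
  )

  lact <- repro[keep, , drop = FALSE]
  afc <- as.integer(lact$calving_date - lact$birth_date)
  lact$afc <- afc
  lact$afc_months <- afc / 30.4375
  lact$calving_month <- as.integer(format(lact$calving_date, "%m"))
  lact$calving_year <- as.integer(format(lact$calving_date, "%Y"))
  rownames(lact) <- NULL

  list(
    lactations = lact,
    milkings = milkings[milkings$animal_id %in% lact$animal_id, , drop = FALSE],
    dropped_counts = dropped
  )
}

#' Write a lactation table
#'
#' Plain CSV writer preserving identifiers, dates and milk weights at full
#' printed precision (round-trips through \code{\link{read_milkings}} /
#' \code{read.csv} bit-identically for identifiers and dates).
#'
#' @param x data.frame to write.
#' @param path output file.
#' @export
write_records <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
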