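# CSV input-output. Dialect is fixed: UTF-8, comma separator, period
# decimal, ISO-8601 calendar dates. Readers validate and reject rather
# than coerce; doses are serialised at full double precision, with
# rounding confined to the human-readable summary table.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

.parse_num <- function(x, col, path, min = -Inf) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v < min)
  if (length(bad)) {
    stop(sprintf("%s: column '%s', line %d: value '%s' is %s", path, col,
                 bad[1] + 1L, x[bad[1]],
                 if (is.na(suppressWarnings(as.numeric(x[bad[1]]))))
                   "not a number" else paste("below", min)),
         call. = FALSE)
  }
  v
}

.parse_date <- function(x, col, path) {
  v <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: column '%s', line %d: '%s' is not an ISO-8601 date",
                 path, col, bad[1] + 1L, x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read a deposition table
#'
#' @param path CSV with header \code{location_id, cs137_kBq_m2,
#'   cs134_ratio, i131_ratio}.
#' @return Validated data.frame of deposition records.
#' @export
read_deposition <- function(path) {
  df <- .read_csv_checked(path, c("location_id", "cs137_kBq_m2",
                                  "cs134_ratio", "i131_ratio"))
  if (nrow(df) == 0) {
    warning("deposition file ", path, " has no data rows")
    return(data.frame(location_id = character(), cs137_kBq_m2 = numeric(),
                      cs134_ratio = numeric(), i131_ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(df$location_id)) {
    stop(path, ": duplicate location_id '",
         df$location_id[duplicated(df$location_id)][1], "'", call. = FALSE)
  }
  data.frame(
    location_id = df$location_id,
    cs137_kBq_m2 = .parse_num(df$cs137_kBq_m2, "cs137_kBq_m2", path, min = 0),
    cs134_ratio = .parse_num(df$cs134_ratio, "cs134_ratio", path, min = 0),
    i131_ratio = .parse_num(df$i131_ratio, "i131_ratio", path, min = 0),
    stringsAsFactors = FALSE
  )
}

#' Write a deposition table
#' @param deposition Data frame of deposition records.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_deposition <- function(deposition, path) {
  utils::write.csv(deposition, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort and its residence histories
#'
#' @param cohort_path CSV with header \code{person_id, sex, birth_date,
#'   followup_end, end_reason} (optional \code{age_factor}).
#' @param residence_path CSV with header \code{person_id, location_id,
#'   start_date, end_date}.
#' @return List with validated data.frames \code{cohort} and
#'   \code{residences}.
#' @export
read_cohort <- function(cohort_path, residence_path) {
  cdf <- .read_csv_checked(cohort_path, c("person_id", "sex", "birth_date",
                                          "followup_end", "end_reason"))
  cohort <- data.frame(
    person_id = cdf$person_id,
    sex = cdf$sex,
    birth_date = .parse_date(cdf$birth_date, "birth_date", cohort_path),
    followup_end = .parse_date(cdf$followup_end, "followup_end", cohort_path),
    end_reason = cdf$end_reason,
    stringsAsFactors = FALSE
  )
  if ("age_factor" %in% names(cdf)) {
    cohort$age_factor <- .parse_num(cdf$age_factor, "age_factor",
                                    cohort_path, min = 0)
  }
  rdf <- .read_csv_checked(residence_path, c("person_id", "location_id",
                                             "start_date", "end_date"))
  residences <- data.frame(
    person_id = rdf$person_id,
    location_id = rdf$location_id,
    start_date = .parse_date(rdf$start_date, "start_date", residence_path),
    end_date = .parse_date(rdf$end_date, "end_date", residence_path),
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort, residences)
  list(cohort = cohort, residences = residences)
}

#' Write a cohort and its residence histories
#' @param cohort,residences Data frames as consumed by [cohort_doses()].
#' @param cohort_path,residence_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, residences, cohort_path, residence_path) {
  co <- cohort
  co$birth_date <- format(as.Date(co$birth_date), "%Y-%m-%d")
  co$followup_end <- format(as.Date(co$followup_end), "%Y-%m-%d")
  utils::write.csv(co, cohort_path, row.names = FALSE, quote = FALSE)
  rs <- residences
  rs$start_date <- format(as.Date(rs$start_date), "%Y-%m-%d")
  rs$end_date <- format(as.Date(rs$end_date), "%Y-%m-%d")
  utils::write.csv(rs, residence_path, row.names = FALSE, quote = FALSE)
  invisible(c(cohort_path, residence_path))
}

#' Write a per-person dose table
#'
#' Full double precision; column order \code{person_id, sex, d_milk,
#' d_inh, d_ext, d_cs_ing, d_total} (mGy).
#' @param dose_table Output of [cohort_doses()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_doses <- function(dose_table, path) {
  cols <- c("person_id", "sex", "d_milk", "d_inh", "d_ext", "d_cs_ing", "d_total")
  df <- dose_table[cols]
  for (cc in cols[3:7]) df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-person dose table written by [write_doses()]
#' @param path CSV path.
#' @return Data frame with numeric dose columns.
#' @export
read_doses <- function(path) {
  df <- .read_csv_checked(path, c("person_id", "sex", "d_milk", "d_inh",
                                  "d_ext", "d_cs_ing", "d_total"))
  for (cc in c("d_milk", "d_inh", "d_ext", "d_cs_ing", "d_total")) {
    df[[cc]] <- .parse_num(df[[cc]], cc, path, min = 0)
  }
  df
}

#' Write a run manifest
#'
#' Records the configuration hash, input file checksums, seed and tool
#' version so that a rerun with an identical manifest is byte-identical.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param config_path Path to the parameter/scenario configuration file
#'   (hashed), or \code{NULL}.
#' @param input_paths Character vector of input files (checksummed).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config_path = NULL,
                           input_paths = character()) {
  checksum <- function(p) unname(tools::md5sum(p))
  manifest <- list(
    tool = "thyrodose",
    version = as.character(utils::packageVersion("thyrodose")),
    seed = as.integer(seed),
    config = if (!is.null(config_path)) {
      list(path = config_path, md5 = checksum(config_path))
    },
    inputs = if (length(input_paths)) {
      lapply(input_paths, function(p) list(path = p, md5 = checksum(p)))
    } else list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
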