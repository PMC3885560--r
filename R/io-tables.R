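#' Construct a validated intensity panel
#'
#' The intensity panel is the pipeline's main input: a long-form table of
#' peak heights with one row per (subject, phase, OGTT time, metabolite)
#' observation slot. A missing (undetected) intensity is `NA`, never 0 --
#' 0 is a legal peak height and the presence filter needs true missingness.
#'
#' @param df data.frame with columns `subject_id`, `phase` (`"pre"`/`"post"`),
#'   `time_min`, `metabolite_id`, `intensity` (numeric, `NA` = missing).
#' @param schedule numeric vector of allowed OGTT sampling times in minutes,
#'   strictly increasing and starting at 0.
#' @return The validated data.frame with class `intensity_panel` and the
#'   schedule stored as an attribute.
#' @export
intensity_panel <- function(df, schedule = c(0, 30, 60, 90, 120)) {
  required <- c("subject_id", "phase", "time_min", "metabolite_id", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(schedule) || length(schedule) < 2 || schedule[1] != 0 ||
      any(diff(schedule) <= 0)) {
    stop("'schedule' must be strictly increasing minutes starting at 0",
         call. = FALSE)
  }
  df <- df[required]
  df$subject_id <- as.character(df$subject_id)
  df$phase <- as.character(df$phase)
  df$metabolite_id <- as.character(df$metabolite_id)
  df$time_min <- as.numeric(df$time_min)
  df$intensity <- as.numeric(df$intensity)

  bad_phase <- !df$phase %in% c("pre", "post")
  if (any(bad_phase)) {
    stop("invalid phase value(s) at row(s) ",
         paste(utils::head(which(bad_phase), 5), collapse = ", "),
         " (must be 'pre' or 'post')", call. = FALSE)
  }
  bad_time <- !df$time_min %in% schedule
  if (any(bad_time)) {
    stop("time_min outside declared schedule at row(s) ",
         paste(utils::head(which(bad_time), 5), collapse = ", "), call. = FALSE)
  }
  neg <- !is.na(df$intensity) & df$intensity < 0
  if (any(neg)) {
    stop("negative intensity at row(s) ",
         paste(utils::head(which(neg), 5), collapse = ", "),
         " (peak heights must be >= 0 or missing)", call. = FALSE)
  }
  key <- paste(df$subject_id, df$phase, df$time_min, df$metabolite_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1]
    stop(sprintf(
      "duplicated (subject, phase, time, metabolite) key at row %d: (%s, %s, %g, %s)",
      first, df$subject_id[first], df$phase[first], df$time_min[first],
      df$metabolite_id[first]), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, schedule = as.numeric(schedule),
            class = c("intensity_panel", "data.frame"))
}

#' @export
panel_schedule <- function(panel) attr(panel, "schedule")

#' Read an intensity panel from a delimited file
#'
#' Delimiter is chosen from the file extension (`.csv` = comma, anything else
#' = tab) unless `sep` is given. Empty intensity fields become `NA`.
#'
#' @param path file path.
#' @param schedule allowed OGTT times (minutes).
#' @param sep optional delimiter override.
#' @export
read_panel <- function(path, schedule = c(0, 30, 60, 90, 120), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  df$time_min <- suppressWarnings(as.numeric(df$time_min))
  int_raw <- df$intensity
  df$intensity <- suppressWarnings(as.numeric(int_raw))
  bad_num <- !is.na(int_raw) & is.na(df$intensity)
  if (any(bad_num)) {
    stop("non-numeric intensity at data row(s) ",
         paste(utils::head(which(bad_num), 5), collapse = ", "), call. = FALSE)
  }
  intensity_panel(df, schedule)
}

#' Write an intensity panel as TSV
#'
#' @param panel intensity panel.
#' @param path output path.
#' @param provenance optional character vector written as `#`-prefixed header
#'   comment lines (seed, parameters), ignorable by standard parsers.
#' @export
write_panel <- function(panel, path, provenance = NULL) {
  write_tsv_comment(as.data.frame(panel), path, provenance)
}

write_tsv_comment <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct validated subject OGTT records
#'
#' One row per (subject, phase, time) with plasma glucose (mg/dL) and serum
#' insulin (uU/mL); the fasting draw (time 0) must be present for every
#' subject-phase so the clinical indices are computable.
#'
#' @param df data.frame with columns `subject_id`, `phase`, `time_min`,
#'   `glucose_mgdl`, `insulin_uUml`.
#' @export
subject_records <- function(df) {
  required <- c("subject_id", "phase", "time_min", "glucose_mgdl", "insulin_uUml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("subject records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$subject_id <- as.character(df$subject_id)
  df$phase <- as.character(df$phase)
  for (col in c("time_min", "glucose_mgdl", "insulin_uUml")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$glucose_mgdl <= 0 | df$insulin_uUml <= 0, na.rm = TRUE)) {
    stop("glucose and insulin must be positive", call. = FALSE)
  }
  grp <- unique(df[c("subject_id", "phase")])
  has0 <- mapply(function(s, p) {
    any(df$time_min[df$subject_id == s & df$phase == p] == 0)
  }, grp$subject_id, grp$phase)
  if (!all(has0)) {
    stop("fasting (time 0) row missing for subject-phase: ",
         paste(grp$subject_id[!has0], grp$phase[!has0], sep = "/",
               collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("subject_records", "data.frame"))
}

#' @export
read_subject_records <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  subject_records(df)
}

#' @export
write_subject_records <- function(records, path, provenance = NULL) {
  write_tsv_comment(as.data.frame(records), path, provenance)
}

#' Construct a fingerprint set
#'
#' Binary chemical fingerprints as a 0/1 matrix, one row per metabolite.
#' All fingerprints in one set share the same bit length.
#'
#' @param bits numeric/integer 0-1 matrix with metabolite ids as row names.
#' @export
fingerprint_set <- function(bits) {
  bits <- as.matrix(bits)
  if (is.null(rownames(bits))) {
    if (nrow(bits) > 0) stop("fingerprint matrix needs row names (ids)",
                             call. = FALSE)
    rownames(bits) <- character(0)
  }
  if (!all(bits %in% c(0, 1))) stop("fingerprints must be 0/1", call. = FALSE)
  storage.mode(bits) <- "integer"
  structure(bits, class = c("fingerprint_set", class(matrix())))
}

#' Read fingerprints from a two-column TSV (id, bitstring or hex)
#'
#' Bitstrings are runs of `0`/`1`; anything containing `A`-`F` (or an `0x`
#' prefix) is parsed as hexadecimal and expanded most-significant-bit first,
#' so `"0F"` over 8 bits sets bits 4-7 (0-based). All rows must expand to the
#' same length.
#'
#' @param path file path.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  names(df) <- c("metabolite_id", "bits")
  rows <- lapply(df$bits, expand_bitstring)
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) > 1) {
    off <- df$metabolite_id[lens != stats::median(lens)]
    stop("fingerprints of mixed bit length; offending id(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  bits <- do.call(rbind, rows)
  rownames(bits) <- df$metabolite_id
  fingerprint_set(bits)
}

expand_bitstring <- function(s) {
  s <- sub("^0[xX]", "", s)
  if (grepl("^[01]+$", s) && !grepl("[2-9a-fA-F]", s)) {
    as.integer(strsplit(s, "")[[1]])
  } else if (grepl("^[0-9a-fA-F]+$", s)) {
    nib <- strtoi(strsplit(toupper(s), "")[[1]], base = 16L)
    as.integer(unlist(lapply(nib, function(v) {
      as.integer(intToBits(v))[4:1]  # MSB first within each nibble
    })))
  } else {
    stop("not a bitstring or hex string: ", s, call. = FALSE)
  }
}

#' @export
write_fingerprints <- function(fps, path, provenance = NULL) {
  df <- data.frame(metabolite_id = rownames(fps),
                   bits = apply(fps, 1, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  write_tsv_comment(df, path, provenance)
}

#' Write a chemical-similarity network as GraphML
#'
#' Vertices carry `loading_lv1` (signed LV1 loading), `size`
#' (`abs(loading_lv1)`) and `direction` (`increase`/`decrease`/`unclear`);
#' edges carry `tanimoto`. Reading the file back with
#' [read_network_graphml()] reproduces the network.
#'
#' @param network igraph object as built by [build_network()].
#' @param path output path.
#' @export
write_network_graphml <- function(network, path) {
  if (!igraph::is_igraph(network)) stop("'network' must be an igraph object",
                                        call. = FALSE)
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}

#' Write a model or report summary as JSON
#'
#' Serializes PLS-DA model summaries and permutation reports (or any list of
#' scalars/vectors/data.frames) with unboxed scalars and full numeric
#' precision.
#'
#' @param x list to serialize (functions and environments are dropped).
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  clean <- function(v) {
    if (is.function(v) || is.environment(v)) return(NULL)
    if (is.list(v) && !is.data.frame(v)) {
      v <- lapply(v, clean)
      v[!vapply(v, is.null, logical(1))]
    } else v
  }
  jsonlite::write_json(clean(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
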