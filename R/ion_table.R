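#' Construct a peptide ion table
#'
#' An ion table is the unit of LC-MS feature data in this package: one row per
#' detected peptide ion peak, characterised by mass-to-charge ratio (Thomson),
#' charge state, retention time (minutes) and raw abundance (arbitrary units),
#' for one replicate of one protein source. This mirrors the per-replicate
#' comma-separated exports of feature-detection software.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th, > 0).
#' @param charge integer vector of charge states (>= 1).
#' @param rt numeric vector of retention times in minutes (>= 0).
#' @param abundance numeric vector of raw abundances (>= 0).
#' @param ion_id optional identifier vector, unique within the table;
#'   sequential integers are assigned when absent.
#' @param source_id protein-source label (e.g. `"WPC"`, `"Blank"`).
#' @param replicate_id replicate label.
#' @return An object of class `ion_table`: a data frame with columns
#'   `ion_id`, `mz`, `charge`, `rt`, `abundance` and attributes `source_id`
#'   and `replicate_id`.
#' @examples
#' ion_table(mz = c(350.1, 502.3), charge = c(1L, 2L), rt = c(5.2, 12.8),
#'           abundance = c(2e5, 8e5), source_id = "WPC", replicate_id = "R1")
#' @export
ion_table <- function(mz = numeric(), charge = integer(), rt = numeric(),
                      abundance = numeric(), ion_id = NULL,
                      source_id = "unknown", replicate_id = "R1") {
  n <- length(mz)
  if (is.null(ion_id)) ion_id <- seq_len(n)
  tab <- data.frame(ion_id = ion_id, mz = as.numeric(mz),
                    charge = as.integer(charge), rt = as.numeric(rt),
                    abundance = as.numeric(abundance),
                    stringsAsFactors = FALSE)
  attr(tab, "source_id") <- as.character(source_id)
  attr(tab, "replicate_id") <- as.character(replicate_id)
  class(tab) <- c("ion_table", "data.frame")
  validate_ion_table(tab)
}

#' Validate an ion table
#'
#' Checks the type invariants row by row: finite positive m/z, integer charge
#' >= 1, finite retention time >= 0, finite abundance >= 0, and unique
#' `ion_id`. Offending rows are reported, never silently dropped.
#'
#' @param tab an `ion_table`.
#' @return `tab`, invisibly unchanged, if valid; otherwise an error listing
#'   every offending row index and the violated constraint.
#' @export
validate_ion_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("ion_id", "mz", "charge", "rt", "abundance")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("ion table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(idx, what) {
    if (any(idx)) sprintf("rows %s: %s", paste(which(idx), collapse = ","), what)
  }
  problems <- c(problems,
    bad(!is.finite(tab$mz) | tab$mz <= 0, "mz must be finite and > 0"),
    bad(is.na(tab$charge) | tab$charge < 1, "charge must be an integer >= 1"),
    bad(!is.finite(tab$rt) | tab$rt < 0, "rt must be finite and >= 0"),
    bad(!is.finite(tab$abundance) | tab$abundance < 0,
        "abundance must be finite and >= 0"))
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (anyDuplicated(tab$ion_id)) {
    dups <- unique(tab$ion_id[duplicated(tab$ion_id)])
    problems <- c(problems,
                  sprintf("duplicated ion_id: %s", paste(dups, collapse = ",")))
  }
  if (length(problems) > 0L) {
    stop("invalid ion table [", source_id(tab), "/", replicate_id(tab), "]: ",
         paste(unlist(problems), collapse = "; "))
  }
  invisible(tab)
}

#' @export
print.ion_table <- function(x, ...) {
  cat(sprintf("ion_table: %d ions, source '%s', replicate '%s'\n",
              nrow(x), source_id(x), replicate_id(x)))
  NextMethod()
}

#' Source and replicate labels of an ion table
#' @param tab an `ion_table`.
#' @return character scalar label.
#' @export
source_id <- function(tab) {
  s <- attr(tab, "source_id", exact = TRUE)
  if (is.null(s)) "unknown" else s
}

#' @rdname source_id
#' @export
replicate_id <- function(tab) {
  s <- attr(tab, "replicate_id", exact = TRUE)
  if (is.null(s)) "R1" else s
}

#' Default column mapping for ion-table CSV files
#'
#' Feature-export dialects differ in their header names; the mapping names the
#' file columns holding each required field. `ion_id` may be `NA` (assigned
#' sequentially at read time).
#'
#' @param mz,charge,rt,abundance,ion_id column names in the file.
#' @return named character vector mapping internal names to file columns.
#' @export
ion_column_map <- function(mz = "mz", charge = "charge", rt = "rt_min",
                           abundance = "abundance", ion_id = NA_character_) {
  c(mz = mz, charge = charge, rt = rt, abundance = abundance, ion_id = ion_id)
}

#' Read a peptide ion table from CSV
#'
#' Reads one comma-separated per-replicate export (one header row, UTF-8,
#' `.` decimal separator) and returns a validated [ion_table()].
#'
#' @param path path to the CSV file.
#' @param source_id,replicate_id labels attached to the table.
#' @param columns column mapping, see [ion_column_map()].
#' @param rt_in_seconds if `TRUE`, retention times in the file are seconds
#'   and are converted to minutes on read. Retention time is minutes
#'   everywhere downstream (the matching tolerance is stated in minutes).
#' @return a validated `ion_table`.
#' @export
read_ion_table <- function(path, source_id, replicate_id,
                           columns = ion_column_map(),
                           rt_in_seconds = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (field in c("mz", "charge", "rt", "abundance")) {
    col <- columns[[field]]
    if (!col %in% names(raw)) {
      stop("ion table format error in '", path, "': missing column '", col,
           "' (expected to hold '", field, "')")
    }
  }
  num <- function(field) {
    txt <- raw[[columns[[field]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt) & nzchar(txt))
    if (length(bad) > 0L) {
      stop("ion table parse error in '", path, "': non-numeric '", field,
           "' at row(s) ", paste(bad, collapse = ","))
    }
    val
  }
  id_col <- columns[["ion_id"]]
  ids <- if (!is.na(id_col) && id_col %in% names(raw)) raw[[id_col]] else NULL
  rt <- num("rt")
  if (rt_in_seconds) rt <- rt / 60
  ion_table(mz = num("mz"), charge = as.integer(num("charge")), rt = rt,
            abundance = num("abundance"), ion_id = ids,
            source_id = source_id, replicate_id = replicate_id)
}

#' Write a peptide ion table to CSV
#'
#' Numeric values are written with 17 significant digits so that
#' `read_ion_table(write_ion_table(tab))` reproduces `tab` bit-identically.
#'
#' @param table a validated `ion_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ion_table <- function(table, path) {
  validate_ion_table(table)
  out <- data.frame(
    ion_id = table$ion_id,
    mz = sprintf("%.17g", table$mz),
    charge = table$charge,
    rt_min = sprintf("%.17g", table$rt),
    abundance = sprintf("%.17g", table$abundance),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a biological read-out table from long-format CSV
#'
#' The canonical layout is long: columns `source_id`, `replicate_id`,
#' `variable`, `value`, one row per assay measurement. The seven assay
#' variables of the intestinal-tubule panel (inulin-FITC leakage, ZO-1
#' intersections, cell viability, alkaline phosphatase activity, IL-6,
#' TGF-beta, NO) are the expected variables but any variable set is accepted.
#'
#' @param path path to the CSV file.
#' @return a `bio_readout_table` (long data frame).
#' @export
read_bio_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bio_readout_table(raw)
}

#' Construct/validate a biological read-out table
#'
#' @param df data frame with columns `source_id`, `replicate_id`, `variable`,
#'   `value`.
#' @return the validated long table, class `bio_readout_table`.
#' @export
bio_readout_table <- function(df) {
  need <- c("source_id", "replicate_id", "variable", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("bio table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$value <- as.numeric(df$value)
  key <- paste(df$source_id, df$replicate_id, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (source, replicate, variable) rows in bio table: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  }
  if (any(!is.finite(df$value))) {
    stop("non-finite value(s) in bio table at row(s) ",
         paste(which(!is.finite(df$value)), collapse = ","))
  }
  counts <- stats::aggregate(value ~ source_id + variable, df, length)
  thin <- counts[counts$value < 3L, , drop = FALSE]
  if (nrow(thin) > 0L) {
    warning("fewer than 3 replicates before outlier removal for: ",
            paste(sprintf("%s/%s (n=%d)", thin$source_id, thin$variable,
                          thin$value), collapse = "; "))
  }
  class(df) <- c("bio_readout_table", "data.frame")
  df
}

#' Write a biological read-out table to long-format CSV
#' @param bio a `bio_readout_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bio_table <- function(bio, path) {
  out <- as.data.frame(bio)
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
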