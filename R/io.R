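#' Read a measurement table
#'
#' Reads a CSV (UTF-8, decimal point, header row of canonical variable
#' names; lines starting with `#` are ignored) or, when the `readxl`
#' package is available, an XLSX file with the same layout. One row per
#' individual; empty cells are missing. Optional columns: `id`, `sex`
#' (M/F), `site`, `grave`.
#'
#' Validation is strict: unknown columns, non-numeric or non-positive
#' measurements, and duplicate case ids are rejected with the offending
#' cell named. Comma decimals (frequent in European spreadsheets) are
#' detected and rejected with a conversion hint rather than silently
#' mis-parsed.
#'
#' @param path CSV or XLSX file path.
#' @param registry Variable registry used for column validation.
#' @return Data frame with `id` (always present; synthesized as the row
#'   number when absent), optional `sex`, and numeric measurement columns.
#' @export
read_measurement_table <- function(path, registry = variable_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package; ",
           "export the sheet as CSV instead", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  }
  meta_cols <- c("id", "case_id", "sex", "site", "grave")
  unknown <- setdiff(names(df), c(meta_cols, registry$name))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(df)) {
    df$id <- if ("case_id" %in% names(df)) as.character(df$case_id) else
      as.character(seq_len(nrow(df)))
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    stop("duplicate case id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (v in intersect(names(df), registry$name)) {
    col <- df[[v]]
    if (is.character(col)) {
      col <- trimws(col)
      col[col == ""] <- NA_character_
      comma <- grepl(",", col, fixed = TRUE)
      if (any(comma, na.rm = TRUE)) {
        stop("column '", v, "', row ", which(comma)[1],
             ": comma decimal detected ('", col[which(comma)[1]],
             "'); convert to decimal points before import", call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & is.na(num)
      if (any(bad)) {
        stop("column '", v, "', row ", which(bad)[1],
             ": non-numeric value '", col[which(bad)[1]], "'", call. = FALSE)
      }
      col <- num
    } else {
      col <- as.numeric(col)
    }
    neg <- !is.na(col) & col <= 0
    if (any(neg)) {
      stop("column '", v, "', row ", which(neg)[1],
           ": measurement must be positive, got ", col[which(neg)[1]],
           call. = FALSE)
    }
    df[[v]] <- col
  }
  df
}

#' Write batch prediction results
#'
#' Writes the prediction records as CSV with probabilities at 4 decimals,
#' preceded by `#` comment lines embedding the tool version and the
#' effective configuration, so every output is self-describing and
#' reproducible. Warning kinds and magnitudes are `;`-separated in one
#' cell.
#'
#' @param records Data frame from [predict_sex()] (or [loocv()]).
#' @param path Output CSV path.
#' @param config Optional named list echoed into the header comments.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path, config = list()) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot write to '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  version <- as.character(utils::packageVersion("cremsex"))
  writeLines(paste0("# cremsex ", version), con)
  if (length(config)) {
    writeLines(paste0("# config: ",
                      paste(names(config), unlist(config), sep = "=",
                            collapse = "; ")), con)
  }
  out <- records
  for (col in intersect(c("p_male", "p_female"), names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         sprintf("%.4f", out[[col]]))
  }
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}
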