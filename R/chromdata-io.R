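# Tabular data model: retention tables (compounds x systems) and per-system
# chromatographic metadata. All retention times are in minutes.

#' Construct and validate a retention table
#'
#' A retention table is a data frame with one row per compound and columns
#' `compound_id`, `role` (`"calibrant"` or `"suspect"`), optional `smiles`
#' and `inchikey`, and one `rt_<cs_id>` column per chromatographic system
#' holding retention times in minutes. Missing retention times (compound not
#' detected on that system) are `NA`, never 0 or a negative sentinel.
#'
#' @param df data frame in the layout above.
#' @return The validated data frame with class `retention_table`.
#' @export
as_retention_table <- function(df) {
  if (!is.data.frame(df)) validation_error("retention table must be a data frame")
  required <- c("compound_id", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    validation_error(paste("missing required columns:", paste(missing_cols, collapse = ", ")))
  }
  df$compound_id <- as.character(df$compound_id)
  df$role <- as.character(df$role)
  if (anyDuplicated(df$compound_id)) {
    dup <- unique(df$compound_id[duplicated(df$compound_id)])
    validation_error(paste("duplicate compound_id:", paste(dup, collapse = ", ")))
  }
  bad_role <- setdiff(unique(df$role), c("calibrant", "suspect"))
  if (length(bad_role) > 0) {
    validation_error(paste("unknown role label:", paste(bad_role, collapse = ", ")))
  }
  rt_cols <- rt_columns(df)
  if (length(rt_cols) < 2) validation_error("a retention table needs at least 2 systems (rt_* columns)")
  for (cc in rt_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) validation_error(paste("non-numeric retention times in", cc))
    if (any(!is.na(v) & v <= 0)) validation_error(paste("non-positive retention time in", cc))
    df[[cc]] <- as.numeric(v)
  }
  class(df) <- unique(c("retention_table", class(df)))
  df
}

rt_columns <- function(df) grep("^rt_", names(df), value = TRUE)

#' List the system ids covered by a retention table
#' @param table a `retention_table`.
#' @return Character vector of cs_ids.
#' @export
table_systems <- function(table) sub("^rt_", "", rt_columns(table))

#' Read a retention table from CSV
#'
#' Expects a header row with `compound_id`, `role`, optionally `smiles` and
#' `inchikey`, and one `rt_<cs_id>` column per system. Empty cells become
#' missing values. Validation (unique ids, known roles, positive numeric RTs,
#' >= 2 systems) is enforced on read.
#'
#' @param path path to a CSV file.
#' @return A `retention_table`.
#' @export
read_rt_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  for (cc in rt_columns(df)) {
    v <- trimws(df[[cc]])
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & is.na(num))) {
      validation_error(paste("non-numeric retention time in column", cc))
    }
    df[[cc]] <- num
  }
  as_retention_table(df)
}

#' Construct a chromatographic system description
#'
#' @param cs_id system identifier.
#' @param mechanism one of `"RP"`, `"HILIC"`, `"mixed"`.
#' @param column_chemistry free-text stationary phase (e.g. `"C18"`).
#' @param additive_class mobile-phase additive class: `"formic_acid"`,
#'   `"ammonium_salt"` or `"mixed"`.
#' @param run_time elution program length in minutes.
#' @param gradient_segments data frame with columns `t_start`, `t_end`,
#'   `phi_start`, `phi_end`: contiguous, non-overlapping segments covering
#'   `(0, run_time]`, with organic fractions `phi` in `[0, 1]`.
#' @return A `chrom_system` object.
#' @export
chrom_system <- function(cs_id, mechanism = "RP", column_chemistry = "C18",
                         additive_class = "formic_acid", run_time,
                         gradient_segments) {
  if (!is.numeric(run_time) || length(run_time) != 1 || run_time <= 0) {
    validation_error("run_time must be a single positive number of minutes")
  }
  if (!mechanism %in% c("RP", "HILIC", "mixed")) {
    validation_error(paste("unknown mechanism:", mechanism))
  }
  if (!additive_class %in% c("formic_acid", "ammonium_salt", "mixed")) {
    validation_error(paste("unknown additive_class:", additive_class))
  }
  seg <- as.data.frame(gradient_segments)
  need <- c("t_start", "t_end", "phi_start", "phi_end")
  if (!all(need %in% names(seg))) {
    validation_error("gradient_segments needs columns t_start, t_end, phi_start, phi_end")
  }
  seg <- seg[order(seg$t_start), need, drop = FALSE]
  tol <- 1e-8
  if (abs(seg$t_start[1]) > tol) validation_error("gradient must start at t = 0")
  if (nrow(seg) > 1 && any(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)]) > tol)) {
    validation_error("gradient segments must be contiguous and non-overlapping")
  }
  if (any(seg$t_end <= seg$t_start + tol * 0)) {
    if (any(seg$t_end <= seg$t_start)) validation_error("gradient segment with non-positive duration")
  }
  if (abs(seg$t_end[nrow(seg)] - run_time) > tol) {
    validation_error("gradient segments must cover (0, run_time]")
  }
  phis <- c(seg$phi_start, seg$phi_end)
  if (any(phis < -tol | phis > 1 + tol)) validation_error("organic fractions must lie in [0, 1]")
  structure(
    list(cs_id = as.character(cs_id), mechanism = mechanism,
         column_chemistry = as.character(column_chemistry),
         additive_class = additive_class, run_time = as.numeric(run_time),
         gradient_segments = seg),
    class = "chrom_system"
  )
}

#' @export
print.chrom_system <- function(x, ...) {
  cat(sprintf("<chrom_system %s: %s %s, %s, %.1f min, %d gradient segment(s)>\n",
              x$cs_id, x$mechanism, x$column_chemistry, x$additive_class,
              x$run_time, nrow(x$gradient_segments)))
  invisible(x)
}

#' Read chromatographic-system metadata from CSV
#'
#' One record per system with columns `cs_id`, `mechanism`,
#' `column_chemistry`, `additive_class`, `run_time` and `gradient` (a JSON
#' array of `[t_start, t_end, phi_start, phi_end]` segments). Gradient
#' segments are validated for contiguity and coverage of the run.
#'
#' @param path path to a CSV file.
#' @return A named list of `chrom_system` objects.
#' @export
read_cs_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  systems <- lapply(seq_len(nrow(df)), function(i) {
    seg <- jsonlite::fromJSON(df$gradient[i])
    seg <- as.data.frame(seg)
    names(seg) <- c("t_start", "t_end", "phi_start", "phi_end")
    chrom_system(cs_id = df$cs_id[i], mechanism = df$mechanism[i],
                 column_chemistry = df$column_chemistry[i],
                 additive_class = df$additive_class[i],
                 run_time = df$run_time[i], gradient_segments = seg)
  })
  names(systems) <- vapply(systems, `[[`, character(1), "cs_id")
  if (anyDuplicated(names(systems))) validation_error("duplicate cs_id in system metadata")
  systems
}

#' Write chromatographic-system metadata to CSV
#'
#' Inverse of [read_cs_metadata()]; gradient segments are serialized as a
#' JSON array per row.
#'
#' @param systems list of `chrom_system` objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cs_metadata <- function(systems, path) {
  rows <- do.call(rbind, lapply(systems, function(s) {
    data.frame(cs_id = s$cs_id, mechanism = s$mechanism,
               column_chemistry = s$column_chemistry,
               additive_class = s$additive_class, run_time = s$run_time,
               gradient = as.character(jsonlite::toJSON(unname(as.matrix(s$gradient_segments)),
                                                        digits = NA)),
               stringsAsFactors = FALSE)
  }))
  write_table(rows, path, keys = "cs_id")
}

#' Write a result table as deterministic CSV
#'
#' Rows are sorted by the declared key columns and written as UTF-8 CSV
#' without row names, so writing the same result twice yields byte-identical
#' files. Doubles survive a round trip at 15 significant digits.
#'
#' @param rows non-empty data frame.
#' @param path output path.
#' @param keys character vector of columns to sort by (default: first column).
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, keys = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) validation_error("refusing to write an empty table")
  keys <- keys %||% names(rows)[1]
  ord <- do.call(order, unname(rows[, keys, drop = FALSE]))
  rows <- rows[ord, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a retention table to CSV
#'
#' @param table a `retention_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_rt_table <- function(table, path) {
  write_table(as.data.frame(table), path, keys = "compound_id")
}
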