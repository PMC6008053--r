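# Readers and writers for the tab-delimited table formats: peptide evidence
# (native and MaxQuant-style column names), label-species counts, half-life
# records, complex membership and puncta time courses. All tables are UTF-8,
# tab-delimited, single header row; "NA" or an empty cell denotes an absent
# ratio. Numeric round trips are exact to 6 significant digits.

#' Column-name dialects for peptide evidence tables
#'
#' Deposited MaxQuant tables name columns differently across versions;
#' a dialect maps the package's native field names to the file's column
#' names. `maxquant_dialect()` covers the common peptides.txt layout
#' ("Sequence", "Proteins", "Missed cleavages", "Ratio H/L") with decoy and
#' contaminant flag columns; `native_dialect()` is the identity mapping for
#' tables written by this package.
#'
#' @param ... name = column overrides applied on top of the defaults.
#' @return Named character vector mapping native names to file columns.
#' @export
native_dialect <- function(...) {
  d <- c(sequence = "sequence", protein_group = "protein_group",
         missed_cleavages = "missed_cleavages", ratio_HL = "ratio_HL",
         light_only = "light_only", timepoint = "timepoint",
         replicate = "replicate", injection = "injection",
         condition = "condition", reverse = "reverse",
         contaminant = "contaminant")
  over <- c(...)
  d[names(over)] <- over
  d
}

#' @rdname native_dialect
#' @export
maxquant_dialect <- function(...) {
  native_dialect(sequence = "Sequence", protein_group = "Proteins",
                 missed_cleavages = "Missed cleavages",
                 ratio_HL = "Ratio H/L", reverse = "Reverse",
                 contaminant = "Potential contaminant", ...)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""),
             fileEncoding = "UTF-8")
}

num_col <- function(x, col, path) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop_format("non-numeric value in column '%s' of %s at data line(s) %s",
                col, path, paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Read a peptide evidence table
#'
#' Reads a tab-delimited peptide quantification table, remapping column
#' names through a dialect, dropping decoy/contaminant rows (flag columns
#' containing "+", or protein groups prefixed `REV__`/`CON__`) and
#' validating the type invariants. Rows violating invariants raise a format
#' error with the offending line; filtered row counts are reported.
#'
#' @param path file path.
#' @param dialect a dialect from [native_dialect()] or [maxquant_dialect()].
#' @return data.frame with columns sequence, protein_group,
#'   missed_cleavages, ratio_HL, light_only, timepoint, replicate,
#'   injection, condition.
#' @export
read_peptide_table <- function(path, dialect = native_dialect()) {
  raw <- read_tsv_raw(path)
  mandatory <- c("sequence", "protein_group", "missed_cleavages", "ratio_HL",
                 "timepoint", "replicate", "injection")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw))
      stop_format("format error: missing mandatory column '%s' in %s",
                  dialect[[field]], path)
  }
  out <- data.frame(
    sequence = as.character(raw[[dialect[["sequence"]]]]),
    protein_group = as.character(raw[[dialect[["protein_group"]]]]),
    missed_cleavages = num_col(raw[[dialect[["missed_cleavages"]]]],
                               dialect[["missed_cleavages"]], path),
    ratio_HL = num_col(raw[[dialect[["ratio_HL"]]]],
                       dialect[["ratio_HL"]], path),
    timepoint = num_col(raw[[dialect[["timepoint"]]]],
                        dialect[["timepoint"]], path),
    replicate = as.character(raw[[dialect[["replicate"]]]]),
    injection = as.character(raw[[dialect[["injection"]]]]),
    stringsAsFactors = FALSE
  )
  out$condition <- if (dialect[["condition"]] %in% names(raw))
    as.character(raw[[dialect[["condition"]]]]) else "default"

  flagged <- rep(FALSE, nrow(out))
  for (field in c("reverse", "contaminant")) {
    col <- dialect[[field]]
    if (col %in% names(raw))
      flagged <- flagged | (!is.na(raw[[col]]) & raw[[col]] == "+")
  }
  flagged <- flagged | grepl("^(REV__|CON__)", out$protein_group)
  if (any(flagged))
    msg("dropped %d decoy/contaminant row(s) of %d from %s",
        sum(flagged), nrow(out), path)
  out <- out[!flagged, , drop = FALSE]

  out$light_only <- if (dialect[["light_only"]] %in% names(raw)) {
    as.logical(raw[[dialect[["light_only"]]]])[!flagged]
  } else {
    is.na(out$ratio_HL) & out$timepoint == 0
  }

  bad_mc <- which(is.na(out$missed_cleavages) | out$missed_cleavages < 0 |
                    out$missed_cleavages != floor(out$missed_cleavages))
  if (length(bad_mc))
    stop_format("format error: invalid missed_cleavages at data line(s) %s of %s",
                paste(utils::head(bad_mc, 5), collapse = ", "), path)
  bad_ratio <- which(!is.na(out$ratio_HL) & out$ratio_HL < 0)
  if (length(bad_ratio))
    stop_format("format error: negative ratio_HL at data line(s) %s of %s",
                paste(utils::head(bad_ratio, 5), collapse = ", "), path)
  key <- paste(out$sequence, out$timepoint, out$replicate, out$injection,
               out$condition, sep = "\r")
  if (anyDuplicated(key))
    stop_format("format error: duplicate (sequence, timepoint, replicate, injection, condition) keys in %s",
                path)
  msg("read %d peptide row(s) from %s", nrow(out), path)
  rownames(out) <- NULL
  out
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop_format("I/O error writing %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Write a peptide evidence table
#'
#' @param peptides peptide table (native columns).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  peptides <- as.data.frame(peptides)
  peptides$ratio_HL <- fmt_num(peptides$ratio_HL)
  write_tsv(peptides, path)
}

#' Write and read per-protein half-life tables
#'
#' The writer renders censored records with a half-life field of `"<1"` and
#' empty fit diagnostics; the reader restores them (censored flag `TRUE`,
#' numeric fields `NA`). Numeric fields round-trip to 6 significant digits.
#'
#' @param records non-empty data.frame of half-life records (the
#'   `halflives` element of a [run_pipeline()] result).
#' @param path file path.
#' @return `write_halflife_table()` the path invisibly;
#'   `read_halflife_table()` the records data.frame.
#' @export
write_halflife_table <- function(records, path) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop_format("no half-life records to write")
  cols <- c("protein_group", "n_peptides", "n_points", "k_per_day", "se_k",
            "r_squared", "half_life_days", "censored")
  miss <- setdiff(setdiff(cols, "censored"), names(records))
  if (length(miss))
    stop_format("records lack column(s): %s", paste(miss, collapse = ", "))
  if (!"censored" %in% names(records)) records$censored <- FALSE
  out <- records[, intersect(c(cols, "condition"), names(records))]
  for (col in c("k_per_day", "se_k", "r_squared"))
    out[[col]] <- fmt_num(out[[col]])
  out$half_life_days <- ifelse(records$censored, "<1",
                               fmt_num(records$half_life_days))
  write_tsv(out, path)
}

#' @rdname write_halflife_table
#' @export
read_halflife_table <- function(path) {
  raw <- read_tsv_raw(path)
  need <- c("protein_group", "n_peptides", "n_points", "k_per_day", "se_k",
            "r_squared", "half_life_days", "censored")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format("format error: missing column(s) %s in %s",
                paste(miss, collapse = ", "), path)
  censored <- as.logical(raw$censored) | (!is.na(raw$half_life_days) &
                                            raw$half_life_days == "<1")
  hl <- raw$half_life_days
  hl[censored] <- NA_character_
  out <- data.frame(
    protein_group = as.character(raw$protein_group),
    n_peptides = num_col(raw$n_peptides, "n_peptides", path),
    n_points = num_col(raw$n_points, "n_points", path),
    k_per_day = num_col(raw$k_per_day, "k_per_day", path),
    se_k = num_col(raw$se_k, "se_k", path),
    r_squared = num_col(raw$r_squared, "r_squared", path),
    half_life_days = num_col(hl, "half_life_days", path),
    censored = censored,
    stringsAsFactors = FALSE
  )
  if ("condition" %in% names(raw)) out$condition <- as.character(raw$condition)
  out
}

#' Read and write label-species count tables
#'
#' Per-sample counts of mixed (LH) and all-heavy (HH) nascent
#' missed-cleavage peptide detections.
#'
#' @param counts data.frame with sample identifier columns plus `LH_count`,
#'   `HH_count`.
#' @param path file path.
#' @return the table (reader) or the path invisibly (writer).
#' @export
read_label_counts <- function(path) {
  raw <- read_tsv_raw(path)
  need <- c("LH_count", "HH_count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format("format error: missing column(s) %s in %s",
                paste(miss, collapse = ", "), path)
  for (col in need) raw[[col]] <- num_col(raw[[col]], col, path)
  bad <- which(raw$LH_count < 0 | raw$HH_count < 0 |
                 raw$LH_count != floor(raw$LH_count) |
                 raw$HH_count != floor(raw$HH_count))
  if (length(bad))
    stop_format("format error: counts must be non-negative integers (line(s) %s of %s)",
                paste(utils::head(bad, 5), collapse = ", "), path)
  raw
}

#' @rdname read_label_counts
#' @export
write_label_counts <- function(counts, path) {
  write_tsv(as.data.frame(counts), path)
}

#' Read a complex-membership table
#'
#' Long format: one row per (complex, member) pair, columns `complex_id`
#' and `protein_group`. Memberships may overlap across complexes.
#'
#' @param path file path.
#' @return data.frame with columns complex_id, protein_group.
#' @export
read_complex_table <- function(path) {
  raw <- read_tsv_raw(path)
  need <- c("complex_id", "protein_group")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format("format error: missing column(s) %s in %s",
                paste(miss, collapse = ", "), path)
  out <- data.frame(complex_id = as.character(raw$complex_id),
                    protein_group = as.character(raw$protein_group),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$complex_id) | is.na(out$protein_group))
  if (length(bad))
    stop_format("format error: empty complex/member field at data line(s) %s of %s",
                paste(utils::head(bad, 5), collapse = ", "), path)
  msg("read %d membership row(s), %d complex(es) from %s",
      nrow(out), length(unique(out$complex_id)), path)
  out
}

#' Read a puncta time-course table
#'
#' Columns: `cell_id`, `chase_days`, `puncta_count`, optional `target`.
#' Duplicate (cell_id, chase_days) pairs and negative counts are format
#' errors.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_puncta_table <- function(path) {
  raw <- read_tsv_raw(path)
  need <- c("cell_id", "chase_days", "puncta_count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format("format error: missing column(s) %s in %s",
                paste(miss, collapse = ", "), path)
  out <- data.frame(cell_id = as.character(raw$cell_id),
                    chase_days = num_col(raw$chase_days, "chase_days", path),
                    puncta_count = num_col(raw$puncta_count, "puncta_count", path),
                    stringsAsFactors = FALSE)
  if ("target" %in% names(raw)) out$target <- as.character(raw$target)
  bad <- which(is.na(out$puncta_count) | out$puncta_count < 0 |
                 out$puncta_count != floor(out$puncta_count))
  if (length(bad))
    stop_format("format error: puncta_count must be a non-negative integer (line(s) %s of %s)",
                paste(utils::head(bad, 5), collapse = ", "), path)
  if (any(is.na(out$chase_days) | out$chase_days < 0))
    stop_format("format error: chase_days must be non-negative in %s", path)
  key <- paste(out$cell_id, out$chase_days, sep = "\r")
  if (anyDuplicated(key))
    stop_format("format error: duplicate (cell_id, chase_days) pair in %s", path)
  out
}

#' Write a ground-truth table from the simulator
#'
#' @param ground_truth the `ground_truth` element of a simulated experiment.
#' @param path file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- as.data.frame(ground_truth)
  for (col in c("k_true", "half_life_true_days"))
    if (col %in% names(gt)) gt[[col]] <- fmt_num(gt[[col]])
  write_tsv(gt, path)
}
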