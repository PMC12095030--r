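#' Count tables, sample sheets, taxonomy and blocklists
#'
#' A count table is a tibble whose first column is `sample_id` and whose
#' remaining columns are numeric feature (ASV) abundances, one column per
#' feature. Counts are integers on input but may become fractional after
#' partial decontamination. A sample sheet is a tibble with one row per
#' sample: `sample_id`, `is_control` (logical), `group`, and optionally
#' `batch`, `well` (96-well coordinate, e.g. "A1") and `replicate_id`
#' (shared by technical replicates of the same biological sample).
#'
#' @name lobiclean-data
NULL

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

guess_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (stringr::str_count(line, "\t") >= stringr::str_count(line, ",")) "\t" else ","
}

read_delim_quiet <- function(path, delim = NULL) {
  delim <- delim %||% guess_delim(path)
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Convert a count tibble to a numeric matrix (samples x features)
#'
#' @param counts count tibble (`sample_id` + one numeric column per feature).
#' @return numeric matrix with sample ids as rownames, feature ids as colnames.
#' @export
count_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "sample_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$sample_id
  m
}

#' Convert a samples x features matrix to a count tibble
#'
#' @param m numeric matrix with sample rownames and feature colnames.
#' @return count tibble.
#' @export
as_count_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

#' Validate a count tibble
#'
#' Checks the invariants of the count-table data model: a `sample_id` first
#' column, numeric feature columns, no negative entries, and duplicate-free
#' sample and feature identifiers.
#'
#' @param counts count tibble.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_count_table <- function(counts) {
  if (!is.data.frame(counts) || ncol(counts) < 1 ||
      names(counts)[1] != "sample_id") {
    abort("A count table must be a data frame whose first column is 'sample_id'.")
  }
  feats <- names(counts)[-1]
  if (anyDuplicated(counts$sample_id)) {
    dup <- unique(counts$sample_id[duplicated(counts$sample_id)])
    abort(paste0("Duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    abort(paste0("Duplicate feature id(s): ", paste(dup, collapse = ", ")))
  }
  for (f in feats) {
    v <- counts[[f]]
    if (!is.numeric(v)) {
      abort(paste0("Non-numeric values in feature '", f, "'."))
    }
    if (anyNA(v)) abort(paste0("Missing values in feature '", f, "'."))
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(paste0("Negative count (", v[i], ") at sample '",
                   counts$sample_id[i], "', feature '", f, "'."))
    }
  }
  invisible(counts)
}

#' Read a count table from delimited text
#'
#' Reads a TSV/CSV count table with one header row and one id column. The
#' canonical layout is samples in rows and features in columns; tables
#' shipped feature-major are transposed on read.
#'
#' @param path file path (TSV or CSV; delimiter is guessed from the header).
#' @param orientation `"samples"` if rows are samples (default), `"features"`
#'   if rows are features.
#' @return a validated count tibble.
#' @export
read_count_table <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  raw <- read_delim_quiet(path)
  if (ncol(raw) < 2) abort("Count table needs an id column plus at least one data column.")
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v)) {
        bad <- which(is.na(num))[1]
        abort(paste0("Non-numeric cell at row ", bad, ", column '",
                     names(vals)[j], "': '", v[bad], "'."))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)
  counts <- as_count_tbl(m)
  validate_count_table(counts)
  counts
}

#' Write a count table to delimited text
#'
#' @param counts count tibble.
#' @param path output path; ".csv" extension writes CSV, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(counts, path, delim = delim)
  invisible(path)
}

parse_logical_col <- function(x, column) {
  s <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    s %in% c("true", "t", "1", "yes", "y") ~ TRUE,
    s %in% c("false", "f", "0", "no", "n") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    abort(paste0("Cannot parse '", column, "' values as logical: ",
                 paste(bad, collapse = ", ")))
  }
  out
}

#' Parse 96-well plate coordinates
#'
#' @param well character vector of coordinates like "A1" ... "H12".
#' @return tibble with columns `well`, `well_row` (1-8) and `well_col` (1-12).
#' @export
parse_well <- function(well) {
  w <- toupper(trimws(as.character(well)))
  m <- stringr::str_match(w, "^([A-H])([0-9]{1,2})$")
  row <- match(m[, 2], LETTERS[1:8])
  col <- suppressWarnings(as.integer(m[, 3]))
  ok <- !is.na(row) & !is.na(col) & col >= 1 & col <= 12
  ok[is.na(w)] <- NA
  if (any(!ok, na.rm = TRUE)) {
    abort(paste0("Invalid 96-well coordinate(s): ",
                 paste(unique(w[!ok & !is.na(ok)]), collapse = ", ")))
  }
  tibble::tibble(well = w, well_row = row, well_col = col)
}

#' Read a sample sheet
#'
#' Requires columns `sample_id`, `is_control` and `group`; `batch`, `well`
#' and `replicate_id` are optional and left absent (not defaulted) when the
#' file does not carry them. Boolean values accept TRUE/FALSE, 1/0 and
#' yes/no case-insensitively.
#'
#' @param path file path (TSV or CSV).
#' @return sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  raw <- read_delim_quiet(path)
  names(raw) <- tolower(names(raw))
  required <- c("sample_id", "is_control", "group")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Sample sheet is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sheet <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    is_control = parse_logical_col(raw$is_control, "is_control"),
    group = as.character(raw$group)
  )
  for (opt in c("batch", "well", "replicate_id")) {
    if (opt %in% names(raw)) sheet[[opt]] <- as.character(raw[[opt]])
  }
  validate_sample_sheet(sheet)
  sheet
}

#' Validate a sample sheet
#'
#' @param sheet sample-sheet tibble.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) {
    dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
    abort(paste0("Duplicate sample id(s) in sample sheet: ",
                 paste(dup, collapse = ", ")))
  }
  if (!is.logical(sheet$is_control) || anyNA(sheet$is_control)) {
    abort("'is_control' must be logical with no missing values.")
  }
  if ("well" %in% names(sheet)) {
    has_well <- !is.na(sheet$well)
    if (any(has_well)) {
      parse_well(sheet$well[has_well])  # errors on malformed coordinates
      b <- if ("batch" %in% names(sheet)) sheet$batch else rep("1", nrow(sheet))
      key <- paste(b[has_well], toupper(sheet$well[has_well]))
      if (anyDuplicated(key)) {
        abort("Well coordinates must be unique within a batch.")
      }
    }
  }
  invisible(sheet)
}

#' Read a taxonomy table
#'
#' Accepts either a `feature_id` column plus one lineage-string column
#' (semicolon-separated, greengenes-style rank prefixes such as
#' `k__Bacteria;p__Proteobacteria;...;g__Ralstonia`) or a `feature_id`
#' column plus one column per rank (kingdom ... species).
#'
#' @param path file path (TSV or CSV).
#' @return tibble with `feature_id` and one column per taxonomic rank;
#'   missing names are `NA`.
#' @export
read_taxonomy <- function(path) {
  raw <- read_delim_quiet(path)
  names(raw) <- tolower(names(raw))
  if (!"feature_id" %in% names(raw)) {
    names(raw)[1] <- "feature_id"
  }
  raw$feature_id <- as.character(raw$feature_id)
  if (anyDuplicated(raw$feature_id)) {
    abort("Duplicate feature ids in taxonomy table.")
  }
  rank_cols <- intersect(RANKS, names(raw))
  if (length(rank_cols)) {
    tax <- raw[, c("feature_id", rank_cols)]
    for (r in setdiff(RANKS, rank_cols)) tax[[r]] <- NA_character_
    return(tax[, c("feature_id", RANKS)])
  }
  lineage_col <- setdiff(names(raw), "feature_id")[1]
  if (is.na(lineage_col)) abort("Taxonomy table needs a lineage or rank columns.")
  dplyr::bind_cols(tibble::tibble(feature_id = raw$feature_id),
                   parse_lineage(raw[[lineage_col]]))
}

#' Parse greengenes-style lineage strings
#'
#' @param lineage character vector like `"k__Bacteria;p__Firmicutes;...;g__Roseburia"`.
#' @return tibble with one column per rank; empty rank fields become `NA`.
#' @export
parse_lineage <- function(lineage) {
  out <- tibble::as_tibble(setNames(
    rep(list(rep(NA_character_, length(lineage))), length(RANKS)), RANKS))
  parts <- stringr::str_split(as.character(lineage), ";")
  for (i in seq_along(parts)) {
    for (tok in trimws(parts[[i]])) {
      m <- stringr::str_match(tok, "^([a-z])__(.*)$")
      if (is.na(m[1, 1])) next
      rank <- names(RANK_PREFIXES)[RANK_PREFIXES == m[1, 2]]
      if (length(rank) && nzchar(m[1, 3])) out[[rank]][i] <- m[1, 3]
    }
  }
  out
}

#' Read a contaminant blocklist
#'
#' Plain text, one taxon name per line; `#` starts a comment. A bare name is
#' matched at genus rank; `rank:name` (e.g. `family:Comamonadaceae`) matches
#' at the stated rank.
#'
#' @param path file path.
#' @param default_rank rank assumed for bare names (default `"genus"`).
#' @return tibble with columns `rank` and `name`.
#' @export
read_blocklist <- function(path, default_rank = "genus") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  entries <- purrr::map_dfr(lines, function(ln) {
    if (grepl(":", ln, fixed = TRUE)) {
      bits <- stringr::str_split_fixed(ln, ":", 2)
      tibble::tibble(rank = tolower(trimws(bits[1])), name = trimws(bits[2]))
    } else {
      tibble::tibble(rank = default_rank, name = ln)
    }
  })
  bad <- setdiff(unique(entries$rank), RANKS)
  if (length(bad)) {
    abort(paste0("Unknown taxonomic rank(s) in blocklist: ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::distinct(entries)
}

#' Path to the bundled synthetic genus blocklist
#'
#' A small genus-level list of taxa repeatedly reported as reagent and
#' laboratory contaminants, assembled for this package (synthetic stand-in
#' for published curated blocklists).
#'
#' @return file path inside the installed package.
#' @export
default_blocklist_path <- function() {
  system.file("extdata", "blocklist_genus_synthetic.txt",
              package = "lobiclean", mustWork = TRUE)
}

#' Align a count table with its sample sheet
#'
#' Retains samples present in both inputs, in count-table order; sheet rows
#' without counts are dropped with a warning. Every sample with counts must
#' have metadata. Records the control/sample partition per batch.
#'
#' @param counts count tibble.
#' @param sheet sample-sheet tibble.
#' @return a `lobiclean_dataset` object (list with `counts`, `sheet`,
#'   `dropped_sheet_samples`).
#' @export
align_dataset <- function(counts, sheet) {
  validate_count_table(counts)
  validate_sample_sheet(sheet)
  shared <- intersect(counts$sample_id, sheet$sample_id)
  if (!length(shared)) abort("No overlapping samples between counts and sample sheet.")
  missing_meta <- setdiff(counts$sample_id, sheet$sample_id)
  if (length(missing_meta)) {
    abort(paste0("Sample(s) in count table missing from sample sheet: ",
                 paste(missing_meta, collapse = ", ")))
  }
  extra <- setdiff(sheet$sample_id, counts$sample_id)
  if (length(extra)) {
    warn(paste0("Dropping sample-sheet row(s) without counts: ",
                paste(extra, collapse = ", ")))
  }
  sheet <- sheet[match(counts$sample_id, sheet$sample_id), ]
  if (all(sheet$is_control)) {
    abort("All samples are flagged as controls; no biological samples to process.")
  }
  b <- dataset_batches(sheet)
  ctrl_only <- vapply(split(sheet$is_control, b), all, logical(1))
  if (any(ctrl_only)) {
    abort(paste0("Batch(es) containing controls only: ",
                 paste(names(ctrl_only)[ctrl_only], collapse = ", ")))
  }
  structure(list(counts = counts, sheet = sheet,
                 dropped_sheet_samples = extra),
            class = "lobiclean_dataset")
}

# batch labels with single-batch fallback
dataset_batches <- function(sheet) {
  if ("batch" %in% names(sheet) && !all(is.na(sheet$batch))) {
    b <- sheet$batch
    b[is.na(b)] <- "unassigned"
    b
  } else {
    rep("batch1", nrow(sheet))
  }
}

#' @export
print.lobiclean_dataset <- function(x, ...) {
  b <- dataset_batches(x$sheet)
  cat("<lobiclean_dataset> ", nrow(x$counts), " samples (",
      sum(x$sheet$is_control), " controls), ",
      ncol(x$counts) - 1L, " features, ",
      length(unique(b)), " batch(es)\n", sep = "")
  invisible(x)
}
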