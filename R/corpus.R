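#' @keywords internal
"_PACKAGE"

# Column schema for experiment tables.  `req` marks columns that must be
# present in any CSV; pi_* columns may be entirely empty (the packaged
# fixture ships without Performance Index values, which the source table
# does not print).
.mb_schema <- data.frame(
  column = c("study_id", "figure_panel", "genotype_exp", "genotype_ctrl",
             "n_exp", "n_ctrl",
             "pi_exp_mean", "pi_exp_sem", "pi_ctrl_mean", "pi_ctrl_sem",
             "intervention", "lobe_category", "driver", "odor_pair",
             "benzaldehyde", "temperature_c", "shock_v", "current_type",
             "delay_min", "rh_pct", "shared_control_id"),
  type = c("character", "character", "character", "character",
           "integer", "integer",
           "numeric", "numeric", "numeric", "numeric",
           "character", "character", "character", "character",
           "logical", "numeric", "numeric", "character",
           "numeric", "numeric", "character"),
  stringsAsFactors = FALSE)

.interventions <- c("rut_rescue", "rut_mutant", "shi_inactivation",
                    "heat_control")
.lobe_levels <- c("alphabeta", "alphaprime_betaprime", "gamma",
                  "alphabeta_gamma", "all_lobes", "none")

#' Construct an experiment dataset
#'
#' Validates a data frame of per-experiment summary records against the
#' schema used throughout the package and attaches provenance.  One row is
#' one published T-maze experiment: an experimental arm and its control
#' arm, each summarized by the number of iterations and (optionally) the
#' mean Performance Index (PI) with its SEM, plus the design moderators.
#'
#' @param df data frame with the columns listed in [mb_schema()].
#' @param provenance character scalar recorded on the object (file path or
#'   fixture name).
#' @return A `data.frame` of class `"mb_dataset"`.
#' @export
mb_dataset <- function(df, provenance = "in-memory") {
  sch <- .mb_schema
  missing_cols <- setdiff(sch$column, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, sch$column]
  for (i in seq_len(nrow(sch))) {
    cl <- sch$type[i]
    col <- sch$column[i]
    df[[col]] <- switch(cl,
                        character = as.character(df[[col]]),
                        integer   = as.integer(df[[col]]),
                        numeric   = as.numeric(df[[col]]),
                        logical   = as.logical(df[[col]]))
  }
  errs <- .validate_records(df)
  if (length(errs) > 0) {
    stop("dataset validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("mb_dataset", "data.frame"),
            provenance = provenance)
}

# Every invariant violation is collected so the error lists all failures.
.validate_records <- function(df) {
  errs <- character(0)
  n <- nrow(df)
  if (n == 0) return(errs)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0)
      errs[[length(errs) + 1L]] <<- sprintf(
        "%s (rows %s)", msg, paste(utils::head(idx, 10), collapse = ", "))
  }
  bad(is.na(df$n_exp) | df$n_exp < 1, "n_exp must be >= 1")
  bad(is.na(df$n_ctrl) | df$n_ctrl < 1, "n_ctrl must be >= 1")
  bad(!df$intervention %in% .interventions, "unknown intervention")
  bad(!df$lobe_category %in% .lobe_levels, "unknown lobe_category")
  bad(df$lobe_category == "none" &
        !df$intervention %in% c("rut_mutant", "heat_control"),
      "lobe_category 'none' only allowed for mutants and heat controls")
  bad(df$intervention %in% c("rut_rescue", "shi_inactivation") &
        df$lobe_category == "none",
      "rescue/inactivation records need a lobe category")
  for (col in c("pi_exp_mean", "pi_ctrl_mean")) {
    bad(!is.na(df[[col]]) & abs(df[[col]]) > 1,
        paste(col, "must lie in [-1, 1]"))
  }
  for (col in c("pi_exp_sem", "pi_ctrl_sem")) {
    bad(!is.na(df[[col]]) & df[[col]] < 0, paste(col, "must be >= 0"))
  }
  bad(xor(df$benzaldehyde, grepl("BEN", df$odor_pair)),
      "benzaldehyde flag must match odor_pair naming BEN")
  bad(!is.na(df$delay_min) & df$delay_min < 0, "delay_min must be >= 0")
  bad(!df$current_type %in% c("AC", "DC", "unknown"), "bad current_type")
  # shared-control blocks must stay within one study and control genotype
  sc <- !is.na(df$shared_control_id) & nzchar(df$shared_control_id)
  if (any(sc)) {
    per <- split(seq_len(n)[sc], df$shared_control_id[sc])
    for (id in names(per)) {
      idx <- per[[id]]
      if (length(unique(df$study_id[idx])) > 1 ||
          length(unique(df$genotype_ctrl[idx])) > 1) {
        errs[[length(errs) + 1L]] <- sprintf(
          "shared_control_id %s spans multiple studies or control genotypes",
          id)
      }
    }
  }
  key <- paste(df$study_id, df$figure_panel, df$genotype_exp,
               df$genotype_ctrl, df$lobe_category, sep = "|")
  if (anyDuplicated(key)) {
    errs[[length(errs) + 1L]] <- sprintf(
      "duplicate records: %s",
      paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  errs
}

#' Column schema of experiment tables
#'
#' @return Data frame with `column` and `type` of every field.
#' @export
mb_schema <- function() .mb_schema

#' Read an experiment table from CSV
#'
#' CSV dialect: UTF-8, comma separated, mandatory header, empty string =
#' missing.  Cells holding a range such as `"21-25"` in the numeric
#' temperature/RH columns are collapsed to their midpoint; a delay of
#' `"immediately"` is coded 0.
#'
#' @param path path to a CSV file with the [mb_schema()] columns.
#' @return An [mb_dataset()].
#' @export
read_experiments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(.mb_schema$column, names(raw))
  if (length(missing_cols) > 0) {
    stop("header of ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- .mb_schema$column[.mb_schema$type %in% c("numeric", "integer")]
  for (col in num_cols) raw[[col]] <- .parse_numeric(raw[[col]], col, path)
  if (!is.null(raw$delay_min)) {
    # defensively handle textual "immediately"
    imm <- !is.na(raw$delay_min) & raw$delay_min == "immediately"
    raw$delay_min[imm] <- 0
  }
  raw$benzaldehyde <- .parse_logical(raw$benzaldehyde, "benzaldehyde", path)
  mb_dataset(raw, provenance = path)
}

.parse_numeric <- function(x, col, path) {
  x <- as.character(x)
  x[!is.na(x) & x %in% c("-", "")] <- NA
  rng <- !is.na(x) & grepl("^\\s*-?[0-9.]+\\s*[-–]\\s*-?[0-9.]+\\s*$", x) &
    !grepl("^-?[0-9.]+$", x)
  if (any(rng)) {
    parts <- strsplit(gsub("–", "-", x[rng]), "-")
    x[rng] <- vapply(parts, function(p) {
      p <- as.numeric(p[nzchar(p)])
      mean(p)
    }, numeric(1))
  }
  x[!is.na(x) & x == "immediately"] <- "0"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("malformed value '%s' in column '%s' of %s (row %d)",
                 x[bad[1]], col, path, bad[1]), call. = FALSE)
  }
  out
}

.parse_logical <- function(x, col, path) {
  out <- rep(NA, length(x))
  x0 <- tolower(trimws(as.character(x)))
  out[x0 %in% c("true", "t", "1", "yes")] <- TRUE
  out[x0 %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("malformed logical '%s' in column '%s' of %s (row %d)",
                 x[bad[1]], col, path, bad[1]), call. = FALSE)
  }
  out
}

#' Write an experiment table to CSV
#'
#' Inverse of [read_experiments()]: `read_experiments(write_experiments(ds))`
#' returns an identical dataset.
#'
#' @param ds an [mb_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(ds, path) {
  stopifnot(inherits(ds, "mb_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Packaged table of included experiments
#'
#' Returns the transcription of the published characteristics table of the
#' systematic review: 81 rutabaga-related and 37 shibire-related
#' experiments with iteration counts and moderators.  PI means/SEMs are
#' absent (the printed table does not contain them); the shared-control
#' linkage is made explicit in `shared_control_id`.
#'
#' @return An [mb_dataset()].
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "mbmeta",
                      mustWork = TRUE)
  read_experiments(path)
}

#' Count records and iterations
#'
#' @param ds an [mb_dataset()].
#' @param filter optional predicate taking the dataset data frame and
#'   returning a logical vector (or a plain logical vector).
#' @return list with `rows`, `sum_n_exp`, `sum_n_ctrl`.
#' @export
summarize_counts <- function(ds, filter = NULL) {
  stopifnot(inherits(ds, "mb_dataset"))
  keep <- if (is.null(filter)) rep(TRUE, nrow(ds))
          else if (is.function(filter)) filter(ds)
          else as.logical(filter)
  keep[is.na(keep)] <- FALSE
  list(rows = sum(keep),
       sum_n_exp = sum(ds$n_exp[keep]),
       sum_n_ctrl = sum(ds$n_ctrl[keep]))
}

#' Lobe category assignment with the 201Y variant
#'
#' The 201Y enhancer trap was historically used as a gamma-lobe driver but
#' also captures a minority of alphabeta cells; the variant analysis
#' reassigns its rescue/inactivation records from `gamma` to
#' `alphabeta_gamma`.  All other records are returned unchanged.
#'
#' @param ds an [mb_dataset()] (or plain data frame with the schema
#'   columns).
#' @param reassign_201Y logical; move 201Y records to `alphabeta_gamma`?
#' @return Character vector of lobe categories, one per record.
#' @export
assign_lobe_category <- function(ds, reassign_201Y = FALSE) {
  cat_ <- ds$lobe_category
  known <- !is.na(ds$driver) |
    ds$intervention %in% c("rut_mutant", "heat_control")
  if (any(!known)) {
    stop("records with unknown driver and no mutant/heat-control ",
         "annotation: rows ",
         paste(which(!known), collapse = ", "), call. = FALSE)
  }
  if (reassign_201Y) {
    hit <- !is.na(ds$driver) & ds$driver == "201Y" & cat_ == "gamma"
    cat_[hit] <- "alphabeta_gamma"
  }
  cat_
}

#' Genotype subgroup of a mutant record
#'
#' The mutant meta-analysis pools by genotype class rather than driver:
#' plain hypomorphs, hypomorphs carrying drivers, and hypomorphs carrying
#' the (unactivated) UAS responder.
#'
#' @param ds dataset or data frame of records.
#' @return Character vector: one of `rut2080`, `rut2080_driver`,
#'   `rut2080_UAS-rut`, `rut1_UAS-rut`, `rut1`, or `NA` for non-mutant
#'   records.
#' @export
mutant_subgroup <- function(ds) {
  g <- ds$genotype_exp
  out <- rep(NA_character_, length(g))
  mut <- ds$intervention == "rut_mutant"
  r1 <- grepl("^rut1", g)
  uas <- grepl("UAS-rut", g)
  drv <- !is.na(ds$driver)
  out[mut & !r1 & !uas & !drv] <- "rut2080"
  out[mut & !r1 & !uas & drv]  <- "rut2080_driver"
  out[mut & !r1 & uas]         <- "rut2080_UAS-rut"
  out[mut & r1 & uas]          <- "rut1_UAS-rut"
  out[mut & r1 & !uas]         <- "rut1"
  out
}

#' Genotype class of a heat-control record
#'
#' @param ds dataset or data frame of records.
#' @return `wild_type`, `driver`, or `uas_shi` (NA for other records).
#' @export
heat_control_class <- function(ds) {
  g <- ds$genotype_exp
  out <- rep(NA_character_, length(g))
  hc <- ds$intervention == "heat_control"
  shi <- grepl("shi", g, ignore.case = TRUE)
  wt <- g %in% c("wCS10", "Canton-S", "wild type")
  out[hc & shi] <- "uas_shi"
  out[hc & !shi & wt] <- "wild_type"
  out[hc & !shi & !wt] <- "driver"
  out
}

#' @export
print.mb_dataset <- function(x, ...) {
  cat(sprintf("<mb_dataset> %d experiments (%s)\n", nrow(x),
              attr(x, "provenance")))
  tb <- table(x$intervention)
  cat(paste(sprintf("  %s: %d", names(tb), tb), collapse = "\n"), "\n")
  invisible(x)
}

# keep the mb_dataset class (and provenance) across row subsetting
#' @export
`[.mb_dataset` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    structure(out, class = c("mb_dataset", "data.frame"),
              provenance = attr(x, "provenance"))
  } else out
}
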