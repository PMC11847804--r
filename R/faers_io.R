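# FAERS quarterly ASCII dialect: "$"-delimited, one header line, no quoting.
# Legacy ISR-keyed files (pre-2012Q4) are not supported; all tables are
# expected to carry a PRIMARYID column.

# canonical column layout per table kind, with accepted header aliases
# (headers are matched case-insensitively; aliases absorb era drift such as
# GNDR_COD -> SEX)
.faers_schemas <- list(
  DEMO = list(
    primaryid        = c("primaryid"),
    caseid           = c("caseid"),
    fda_dt           = c("fda_dt"),
    age_value        = c("age", "age_value"),
    age_unit         = c("age_cod", "age_unit"),
    sex              = c("sex", "gndr_cod"),
    reporter_type    = c("occp_cod", "reporter_type"),
    reporter_country = c("reporter_country", "occr_country")
  ),
  DRUG = list(
    primaryid = c("primaryid"),
    drug_seq  = c("drug_seq", "drugseq"),
    role_code = c("role_cod", "role_code"),
    drugname  = c("drugname"),
    prod_ai   = c("prod_ai")
  ),
  REAC = list(
    primaryid = c("primaryid"),
    pt        = c("pt")
  ),
  OUTC = list(
    primaryid    = c("primaryid"),
    outcome_code = c("outc_cod", "outc_code", "outcome_code")
  ),
  INDI = list(
    primaryid     = c("primaryid"),
    drug_seq      = c("indi_drug_seq", "drug_seq"),
    indication_pt = c("indi_pt", "indication_pt")
  ),
  THER = list(
    primaryid = c("primaryid"),
    drug_seq  = c("dsg_drug_seq", "drug_seq"),
    start_dt  = c("start_dt"),
    end_dt    = c("end_dt")
  )
)

.faers_kinds <- names(.faers_schemas)

# FAERS header name used on output for each canonical column
.faers_out_header <- list(
  DEMO = c(primaryid = "primaryid", caseid = "caseid", fda_dt = "fda_dt",
           age_value = "age", age_unit = "age_cod", sex = "sex",
           reporter_type = "occp_cod", reporter_country = "reporter_country"),
  DRUG = c(primaryid = "primaryid", drug_seq = "drug_seq",
           role_code = "role_cod", drugname = "drugname", prod_ai = "prod_ai"),
  REAC = c(primaryid = "primaryid", pt = "pt"),
  OUTC = c(primaryid = "primaryid", outcome_code = "outc_cod"),
  INDI = c(primaryid = "primaryid", drug_seq = "indi_drug_seq",
           indication_pt = "indi_pt"),
  THER = c(primaryid = "primaryid", drug_seq = "dsg_drug_seq",
           start_dt = "start_dt", end_dt = "end_dt")
)

.check_kind <- function(table_kind) {
  kind <- toupper(table_kind[1])
  if (!kind %in% .faers_kinds) {
    stop("unknown FAERS table kind: ", table_kind,
         " (expected one of ", paste(.faers_kinds, collapse = ", "), ")",
         call. = FALSE)
  }
  kind
}

#' Parse one FAERS-dialect quarterly ASCII table
#'
#' Reads a `$`-delimited FAERS table (single header line, no quoting) into a
#' `data.table` with canonical column names. Header names are matched
#' case-insensitively and era aliases are accepted (e.g. `GNDR_COD` for sex);
#' columns absent from the file become all-missing columns, so older-era files
#' differ from current ones only in missingness, never in row count. Empty
#' strings become `NA`.
#'
#' @param path path to the ASCII file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`,
#'   `"THER"` (case-insensitive).
#' @param strict logical; if `FALSE` (default, lenient) rows whose field count
#'   does not match the header are skipped and counted, if `TRUE` they are a
#'   fatal error. Real FAERS quarters contain stray rows; strict mode suits
#'   synthetic fixtures.
#' @return a `data.table` with the canonical columns of the table kind and a
#'   `"parse_report"` attribute (rows read/kept/skipped, missing and unknown
#'   columns); see [parse_report()].
#' @seealso [write_quarter_table()], [load_quarters()]
#' @export
parse_quarter_table <- function(path, table_kind, strict = FALSE) {
  kind <- .check_kind(table_kind)
  if (!file.exists(path)) {
    stop("cannot read FAERS ", kind, " table: no such file: ", path,
         call. = FALSE)
  }
  lines <- tryCatch(
    readLines(path, encoding = "UTF-8", warn = FALSE),
    error = function(e) readLines(path, encoding = "latin1", warn = FALSE)
  )
  if (length(lines) == 0) {
    stop("cannot parse FAERS ", kind, " table: file is empty: ", path,
         call. = FALSE)
  }
  schema <- .faers_schemas[[kind]]
  header <- tolower(strsplit(lines[1], "$", fixed = TRUE)[[1]])
  n_fields <- length(header)

  # map each canonical column to its position in the file header (NA if absent)
  col_pos <- vapply(schema, function(aliases) {
    hit <- which(header %in% aliases)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  known_pos <- col_pos[!is.na(col_pos)]
  unknown_columns <- setdiff(seq_len(n_fields), known_pos)
  missing_columns <- names(col_pos)[is.na(col_pos)]

  body <- lines[-1]
  body <- body[nzchar(body)]
  rows_read <- length(body)
  fields <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field: "a$b$" -> c("a","b"); pad rows that
  # are exactly one short and end in "$"
  nf <- lengths(fields)
  short1 <- nf == n_fields - 1L & endsWith(body, "$")
  if (any(short1)) {
    fields[short1] <- lapply(fields[short1], function(f) c(f, ""))
    nf[short1] <- n_fields
  }
  bad <- nf != n_fields
  if (any(bad) && strict) {
    stop("FAERS ", kind, " table ", path, ": ", sum(bad),
         " row(s) with wrong field count (strict mode); first bad row: ",
         which(bad)[1], call. = FALSE)
  }
  fields <- fields[!bad]
  rows_skipped <- sum(bad)

  out <- data.table::as.data.table(lapply(col_pos, function(p) {
    if (is.na(p)) rep(NA_character_, length(fields))
    else blank_to_na(vapply(fields, `[[`, character(1), p))
  }))

  # type coercions and light normalization
  if (kind == "DEMO") {
    out[, `:=`(
      age_value = suppressWarnings(as.numeric(age_value)),
      age_unit  = toupper(age_unit),
      sex       = toupper(sex)
    )]
    dup <- duplicated(out$primaryid) | is.na(out$primaryid)
    if (any(dup)) {
      if (strict) {
        stop("FAERS DEMO table ", path, ": ", sum(dup),
             " row(s) with missing or duplicate primaryid (strict mode)",
             call. = FALSE)
      }
      out <- out[!dup]
      rows_skipped <- rows_skipped + sum(dup)
    }
  } else if (kind == "DRUG") {
    out[, `:=`(drug_seq = suppressWarnings(as.integer(drug_seq)),
               role_code = toupper(role_code))]
  } else if (kind == "REAC") {
    out[, pt := squish(pt)]
    empty <- is.na(out$pt) | out$pt == ""
    if (any(empty)) {
      out <- out[!empty]
      rows_skipped <- rows_skipped + sum(empty)
    }
  } else if (kind == "OUTC") {
    out[, outcome_code := toupper(outcome_code)]
  } else if (kind %in% c("INDI", "THER")) {
    out[, drug_seq := suppressWarnings(as.integer(drug_seq))]
    if (kind == "INDI") out[, indication_pt := squish(indication_pt)]
  }

  data.table::setattr(out, "parse_report", list(
    table_kind      = kind,
    path            = path,
    rows_read       = rows_read,
    rows_kept       = nrow(out),
    rows_skipped    = rows_skipped,
    missing_columns = missing_columns,
    unknown_columns = length(unknown_columns)
  ))
  out[]
}

#' Retrieve the parse report attached to a parsed table
#'
#' @param x a table returned by [parse_quarter_table()].
#' @return the parse-report list (rows read, kept, skipped, missing columns,
#'   unknown column count), or `NULL` if none is attached.
#' @export
parse_report <- function(x) attr(x, "parse_report", exact = TRUE)

#' Write a record collection as a FAERS-dialect ASCII table
#'
#' Emits `$`-delimited text with a FAERS-style header. Missing values become
#' empty fields, so `parse_quarter_table(write_quarter_table(x))` round-trips
#' every field. There is no quoting in the dialect, so a field containing `$`
#' or a newline cannot be represented and is rejected.
#'
#' @param records a `data.table`/`data.frame` with the canonical columns of
#'   the table kind (extra columns are ignored).
#' @param table_kind table kind, as in [parse_quarter_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quarter_table <- function(records, table_kind, path) {
  kind <- .check_kind(table_kind)
  hdr <- .faers_out_header[[kind]]
  records <- data.table::as.data.table(records)
  missing_cols <- setdiff(names(hdr), names(records))
  for (mc in missing_cols) records[, (mc) := NA_character_]
  cols <- lapply(names(hdr), function(cn) {
    v <- records[[cn]]
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  })
  bad <- Reduce(`|`, lapply(cols, function(v) grepl("[$\n\r]", v)))
  if (any(bad)) {
    ids <- records$primaryid[bad]
    stop("cannot write FAERS ", kind, " table: field contains '$' or newline",
         " in record(s) with primaryid ",
         paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(unname(hdr), collapse = "$"),
               do.call(paste, c(cols, sep = "$"))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Load one or more FAERS quarters into a bundle
#'
#' Looks for files named `<kind><quarter>.txt` (case-insensitive, e.g.
#' `demo2024q1.txt`) under `directory`, parses them, and concatenates the
#' per-quarter tables. DEMO, DRUG and REAC are mandatory per quarter; OUTC,
#' INDI and THER are optional. No deduplication is performed here.
#'
#' @param directory directory containing the quarter files.
#' @param quarters character vector of quarter labels (e.g. `"2024q1"`).
#' @param strict passed to [parse_quarter_table()].
#' @return a `faers_bundle`: list with elements `demo`, `drug`, `reac`,
#'   `outc`, `indi`, `ther` (concatenated `data.table`s), `provenance`
#'   (source file paths) and `unresolved` (per-table counts of primaryids
#'   that do not resolve against DEMO — counted and reported, never dropped).
#' @export
load_quarters <- function(directory, quarters, strict = FALSE) {
  if (length(quarters) == 0) {
    warning("load_quarters(): empty quarter list; returning an empty bundle")
    return(faers_bundle())
  }
  files_in_dir <- list.files(directory)
  tabs <- stats::setNames(vector("list", length(.faers_kinds)),
                          tolower(.faers_kinds))
  provenance <- character(0)
  for (q in quarters) {
    for (kind in .faers_kinds) {
      patt <- paste0("^", tolower(kind), tolower(q), "\\.txt$")
      hit <- files_in_dir[grepl(patt, tolower(files_in_dir))]
      mandatory <- kind %in% c("DEMO", "DRUG", "REAC")
      if (length(hit) == 0) {
        if (mandatory) {
          stop("quarter ", q, ": mandatory ", kind, " file (",
               tolower(kind), q, ".txt) not found in ", directory,
               call. = FALSE)
        }
        next
      }
      path <- file.path(directory, hit[1])
      tabs[[tolower(kind)]] <- data.table::rbindlist(
        list(tabs[[tolower(kind)]], parse_quarter_table(path, kind, strict)),
        use.names = TRUE, fill = TRUE)
      provenance <- c(provenance, path)
    }
  }
  faers_bundle(demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
               outc = tabs$outc, indi = tabs$indi, ther = tabs$ther,
               provenance = provenance)
}

#' Construct a FAERS bundle from in-memory tables
#'
#' @param demo,drug,reac,outc,indi,ther tables with the canonical columns of
#'   [parse_quarter_table()]; `NULL` tables become empty.
#' @param provenance character vector of source descriptions.
#' @return a `faers_bundle` object.
#' @export
faers_bundle <- function(demo = NULL, drug = NULL, reac = NULL, outc = NULL,
                         indi = NULL, ther = NULL, provenance = character(0)) {
  empty <- function(kind) {
    cols <- names(.faers_schemas[[kind]])
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(cols)), cols))
    dt
  }
  b <- list(
    demo = data.table::as.data.table(demo %||% empty("DEMO")),
    drug = data.table::as.data.table(drug %||% empty("DRUG")),
    reac = data.table::as.data.table(reac %||% empty("REAC")),
    outc = data.table::as.data.table(outc %||% empty("OUTC")),
    indi = data.table::as.data.table(indi %||% empty("INDI")),
    ther = data.table::as.data.table(ther %||% empty("THER")),
    provenance = provenance
  )
  ids <- b$demo$primaryid
  b$unresolved <- vapply(c("drug", "reac", "outc", "indi", "ther"),
                         function(k) {
                           tab <- b[[k]]
                           if (nrow(tab) == 0) 0L
                           else sum(!(unique(tab$primaryid) %in% ids))
                         }, integer(1))
  if (any(b$unresolved > 0)) {
    message("faers_bundle: primaryids not resolving against DEMO: ",
            paste(names(b$unresolved)[b$unresolved > 0], "=",
                  b$unresolved[b$unresolved > 0], collapse = ", "))
  }
  structure(b, class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle>\n")
  for (k in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    cat(sprintf("  %-5s %8d rows\n", toupper(k), nrow(x[[k]])))
  }
  cat("  provenance:", length(x$provenance), "file(s)\n")
  invisible(x)
}
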