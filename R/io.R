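#' Read a nucleotide FASTA file into a sequence table
#'
#' Parses a FASTA file of IGHV (or any) nucleotide sequences. Sequences
#' are uppercased; IMGT gap characters (`.` and `-`) are preserved so
#' that pre-gapped germline references survive the round trip. The
#' permitted alphabet is `A C G T N . -`.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first whitespace-delimited
#'   token of the header), `nt_sequence`, `germline_call` (`NA`; FASTA
#'   carries no gene call) and `reading_frame_offset` (0).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ATGaaa", ">g2", "TTT..GGG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA at line %d: expected '>' header", nonblank[1]))
  }
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) < 2L) stop(sprintf("malformed FASTA at line %d: empty header", i))
    } else {
      bad <- gsub("[ACGTNacgtn.\\-]", "", ln)
      if (nzchar(bad)) {
        stop(sprintf("malformed FASTA at line %d: illegal character(s) '%s'", i, bad))
      }
    }
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(
    id = ids,
    nt_sequence = toupper(as.character(seqs)),
    germline_call = NA_character_,
    reading_frame_offset = 0L,
    stringsAsFactors = FALSE
  )
}

#' Read an AIRR-style rearrangement TSV
#'
#' Reads a tab-separated rearrangement table in the AIRR Rearrangement
#' dialect. `sequence_id` and `sequence` are mandatory. When both
#' `sequence_alignment` and `germline_alignment` are present and
#' non-empty for a row, the pair is marked pre-aligned and will bypass
#' the alignment stage downstream.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `sequence_id`, `sequence`,
#'   `sequence_alignment`, `germline_alignment`, `v_call` and logical
#'   `prealigned`.
#' @export
read_airr_rearrangements <- function(path) {
  if (!file.exists(path)) stop("rearrangement file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  need <- c("sequence_id", "sequence")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("configuration error: rearrangement file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (opt in c("sequence_alignment", "germline_alignment", "v_call")) {
    if (!opt %in% names(tab)) tab[[opt]] <- ""
  }
  n <- nrow(tab)
  if (n == 0L) stop("rearrangement file has no rows: ", path)
  blank_seq <- which(!nzchar(trimws(tab$sequence)))
  if (length(blank_seq)) {
    stop("missing sequence in rearrangement row(s): ",
         paste(blank_seq, collapse = ", "))
  }
  if (anyDuplicated(tab$sequence_id)) {
    stop("duplicate sequence_id(s): ",
         paste(unique(tab$sequence_id[duplicated(tab$sequence_id)]), collapse = ", "))
  }
  sa <- toupper(trimws(tab$sequence_alignment))
  ga <- toupper(trimws(tab$germline_alignment))
  prealigned <- nzchar(sa) & nzchar(ga)
  bad_len <- which(prealigned & nchar(sa) != nchar(ga))
  if (length(bad_len)) {
    stop("sequence_alignment and germline_alignment lengths differ in row(s): ",
         paste(bad_len, collapse = ", "))
  }
  data.frame(
    sequence_id = tab$sequence_id,
    sequence = toupper(trimws(tab$sequence)),
    sequence_alignment = sa,
    germline_alignment = ga,
    v_call = trimws(tab$v_call),
    prealigned = prealigned,
    stringsAsFactors = FALSE
  )
}

#' Read a clinical table with time to first treatment
#'
#' Accepts either a precomputed `ttft_years` column or ISO-8601 date
#' columns (`diagnosis_date`, `first_treatment_date`,
#' `last_followup_date`). TTFT is the number of years between diagnosis
#' and initial therapy; untreated patients are censored at last
#' follow-up. Days are converted to years by division by 365.25.
#'
#' @param path Path to a CSV file with a header. Must contain
#'   `patient_id` and `event` (treated = TRUE/1) plus either
#'   `ttft_years` or the three date columns.
#' @return A data.frame with columns `patient_id`, `ttft_years`, `event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"patient_id" %in% names(tab)) stop("clinical table lacks patient_id column")
  if (!"event" %in% names(tab)) stop("clinical table lacks event column")
  if (nrow(tab) == 0L) stop("clinical table has no rows")
  event <- .parse_logical(tab$event, "event")
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id(s) in clinical table: ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]), collapse = ", "))
  }

  if ("ttft_years" %in% names(tab)) {
    ttft <- suppressWarnings(as.numeric(tab$ttft_years))
    if (anyNA(ttft)) stop("unparseable ttft_years in row(s): ",
                          paste(which(is.na(ttft)), collapse = ", "))
  } else {
    need <- c("diagnosis_date", "first_treatment_date", "last_followup_date")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols)) {
      stop("clinical table needs ttft_years or date columns; missing: ",
           paste(missing_cols, collapse = ", "))
    }
    diag <- .parse_iso_date(tab$diagnosis_date, "diagnosis_date", required = TRUE)
    trt <- .parse_iso_date(tab$first_treatment_date, "first_treatment_date",
                           required = FALSE)
    fup <- .parse_iso_date(tab$last_followup_date, "last_followup_date",
                           required = FALSE)
    end <- as.Date(ifelse(event, trt, fup), origin = "1970-01-01")
    if (anyNA(end)) {
      stop("missing end date (treatment or follow-up) in row(s): ",
           paste(which(is.na(end)), collapse = ", "))
    }
    bad <- which(event & !is.na(trt) & trt < diag)
    if (length(bad)) stop("first_treatment_date before diagnosis_date in row(s): ",
                          paste(bad, collapse = ", "))
    ttft <- as.numeric(end - diag) / 365.25
  }
  if (any(ttft < 0)) stop("negative TTFT interval in row(s): ",
                          paste(which(ttft < 0), collapse = ", "))
  data.frame(patient_id = tab$patient_id, ttft_years = ttft, event = event,
             stringsAsFactors = FALSE)
}

.parse_logical <- function(x, what) {
  v <- tolower(trimws(x))
  out <- ifelse(v %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(v %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out)) stop("unparseable ", what, " value(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

.parse_iso_date <- function(x, what, required = TRUE) {
  v <- trimws(x)
  blank <- !nzchar(v)
  d <- as.Date(rep(NA_integer_, length(v)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", v)
  d[ok] <- as.Date(v[ok], format = "%Y-%m-%d")
  bad <- which(!blank & (!ok | is.na(d)))
  if (length(bad)) stop("unparseable ", what, " (ISO 8601 required) in row(s): ",
                        paste(bad, collapse = ", "))
  if (required && any(blank)) stop("missing ", what, " in row(s): ",
                                   paste(which(blank), collapse = ", "))
  d
}

#' Write / read an annotated cohort table
#'
#' CSV round-trip for the per-patient cohort table produced by
#' [run_pipeline()]. Numeric columns are written with 17 significant
#' digits so that `read_cohort(write_cohort(x))` reproduces every field
#' exactly.
#'
#' @param cohort A cohort data.frame.
#' @param path Output CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort`
#'   returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
      out[[nm]][is.na(cohort[[nm]])] <- ""
    }
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  num_cols <- intersect(
    c("ttft_years", "percent_diff", "ratio", "log_ratio"), names(tab))
  int_cols <- intersect(
    c("n_s", "n_rc", "n_rnc", "n_unclassified", "n_total", "compared_length"),
    names(tab))
  for (nm in num_cols) tab[[nm]] <- as.numeric(tab[[nm]])
  for (nm in int_cols) tab[[nm]] <- as.integer(tab[[nm]])
  if ("event" %in% names(tab)) tab$event <- .parse_logical(tab$event, "event")
  tab
}
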