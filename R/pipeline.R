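#' Run the full IGHV mutation-ratio pipeline
#'
#' End-to-end orchestration: read patient rearrangements (AIRR TSV or
#' FASTA), germline references (FASTA) and a clinical table; align each
#' patient to its germline (pre-aligned pairs pass through); call and
#' classify nucleotide mutations; compute percent germline difference
#' and 2% mutation status; compute the pseudocounted (S+Rc)/Rnc ratio,
#' Low/High ratio group and mutation-count bin; and join TTFT. The run
#' is deterministic given its inputs and parameters; when `out_dir` is
#' given, the cohort CSV, a per-site TSV, stratified KM/log-rank report
#' files and a run log (all parameters and the seed) are written.
#'
#' @param sequences Path to patient sequences: AIRR-style TSV (detected
#'   by a `sequence_id` header) or FASTA. Already-loaded data frames
#'   from [read_airr_rearrangements()] are also accepted.
#' @param germline Path to a germline FASTA (or data frame from
#'   [read_fasta()]). Patient `v_call` values are matched against
#'   germline ids; FASTA patient input requires a single germline record.
#' @param clinical Path to the clinical CSV (or a data frame from
#'   [read_clinical()]). Optional: without it the cohort has no TTFT
#'   columns and no survival report is written.
#' @param out_dir Optional output directory.
#' @param params A [ratio_params()] object (pseudocounts, threshold).
#' @param percent_cutoff Mutation-status cutoff in percent (default 2).
#' @param rule Conservativeness rule, `"strict"` or `"majority"`.
#' @param effect Codon-effect convention, `"isolated"` or `"observed"`.
#' @param min_overlap Minimum compared positions per alignment.
#' @param seed Seed recorded in the run log (the pipeline itself draws
#'   no random numbers; matching and simulation derive from it).
#' @return The cohort data.frame (one row per patient), with the
#'   per-site classification table attached as `attr(, "sites")` and
#'   the ratio threshold as `attr(, "ratio_threshold")`.
#' @export
run_pipeline <- function(sequences, germline, clinical = NULL, out_dir = NULL,
                         params = ratio_params(), percent_cutoff = 2.0,
                         rule = c("strict", "majority"),
                         effect = c("isolated", "observed"),
                         min_overlap = 60L, seed = 1L) {
  rule <- match.arg(rule)
  effect <- match.arg(effect)

  germ <- if (is.data.frame(germline)) germline else read_fasta(germline)
  pats <- .load_patients(sequences)
  clin <- if (is.null(clinical) || is.data.frame(clinical)) clinical
          else read_clinical(clinical)

  if (nrow(pats) == 0L) stop("no analyzable sequences")
  tables <- aa_class_tables()

  profiles <- vector("list", nrow(pats))
  site_list <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    row <- pats[i, ]
    stage <- sprintf("mutation_calling[%s]", row$sequence_id)
    pair <- tryCatch({
      if (isTRUE(row$prealigned)) {
        align_pair(row$sequence_alignment, row$germline_alignment,
                   patient_id = row$sequence_id, min_overlap = min_overlap)
      } else {
        g <- .lookup_germline(germ, row$v_call)
        align_pair(row$sequence, g, patient_id = row$sequence_id,
                   min_overlap = min_overlap)
      }
    }, error = function(e) stop(stage, ": ", conditionMessage(e), call. = FALSE))
    sites <- call_mutations(pair)
    pct <- 100 * nrow(sites) / pair$compared_length
    profiles[[i]] <- list(sites = sites, pct = pct,
                          compared = pair$compared_length,
                          v_call = row$v_call)
    site_list[[i]] <- sites
  }

  all_sites <- do.call(rbind, site_list)
  cls <- classify_sites(all_sites, tables = tables, rule = rule, effect = effect)

  rows <- lapply(seq_along(profiles), function(i) {
    pr <- profiles[[i]]
    pid <- pats$sequence_id[i]
    labels <- cls$label[cls$patient_id == pid]
    prof <- profile_sequence(labels, pct = pr$pct,
                             status = mutation_status(pr$pct, percent_cutoff),
                             patient_id = pid)
    prof$v_call <- pr$v_call
    prof$compared_length <- pr$compared
    prof
  })
  cohort <- do.call(rbind, rows)
  cohort <- assign_groups(cohort, params)
  threshold <- attr(cohort, "ratio_threshold")
  cohort$mutation_bin <- bin_by_mutation_count(cohort$n_total)

  if (!is.null(clin)) {
    idx <- match(cohort$patient_id, clin$patient_id)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " sequence(s) without clinical record dropped")
      cohort <- cohort[!is.na(idx), , drop = FALSE]
      idx <- idx[!is.na(idx)]
    }
    cohort$ttft_years <- clin$ttft_years[idx]
    cohort$event <- clin$event[idx]
  }
  if (nrow(cohort) == 0L) stop("no analyzable sequences")
  rownames(cohort) <- NULL
  attr(cohort, "sites") <- cls
  attr(cohort, "ratio_threshold") <- threshold

  if (!is.null(out_dir)) {
    .write_pipeline_outputs(cohort, cls, out_dir, params = params,
                            percent_cutoff = percent_cutoff, rule = rule,
                            effect = effect, min_overlap = min_overlap,
                            seed = seed, threshold = threshold)
  }
  cohort
}

.load_patients <- function(sequences) {
  if (is.data.frame(sequences)) {
    if ("sequence_id" %in% names(sequences)) return(sequences)
    # FASTA-style record table
    return(data.frame(sequence_id = sequences$id,
                      sequence = sequences$nt_sequence,
                      sequence_alignment = "", germline_alignment = "",
                      v_call = sequences$germline_call %||% "",
                      prealigned = FALSE, stringsAsFactors = FALSE))
  }
  first <- readLines(sequences, n = 1L, warn = FALSE)
  if (grepl("\t", first) && grepl("sequence_id", first)) {
    read_airr_rearrangements(sequences)
  } else {
    fa <- read_fasta(sequences)
    data.frame(sequence_id = fa$id, sequence = fa$nt_sequence,
               sequence_alignment = "", germline_alignment = "",
               v_call = "", prealigned = FALSE, stringsAsFactors = FALSE)
  }
}

.lookup_germline <- function(germ, v_call) {
  if (!is.na(v_call) && nzchar(v_call)) {
    hit <- which(germ$id == v_call)
    if (length(hit) != 1L) stop("germline gene not found for v_call: ", v_call)
    return(germ$nt_sequence[hit])
  }
  if (nrow(germ) == 1L) return(germ$nt_sequence[1])
  stop("no v_call given and germline reference is not unique")
}

.write_pipeline_outputs <- function(cohort, sites, out_dir, params,
                                    percent_cutoff, rule, effect, min_overlap,
                                    seed, threshold) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  utils::write.table(
    sites[, c("patient_id", "alignment_pos", "germline_base", "observed_base",
              "codon_index", "pos_in_codon", "label", "to_stop")],
    file.path(out_dir, "mutation_sites.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  if ("ttft_years" %in% names(cohort)) {
    for (by in c("status", "ratio_group", "mutation_bin")) {
      ok <- !all(is.na(cohort[[by]]))
      if (ok && length(unique(stats::na.omit(cohort[[by]]))) >= 1L) {
        rep_ <- tryCatch(suppressWarnings(ttft_report(cohort, by)),
                         error = function(e) NULL)
        if (!is.null(rep_)) write_ttft_report(rep_, out_dir)
      }
    }
  }
  log_lines <- c(
    sprintf("ighvratio %s", as.character(utils::packageVersion("ighvratio"))),
    sprintf("group_pseudocount=%g", params$group_pseudocount),
    sprintf("cox_pseudocount=%g", params$cox_pseudocount),
    sprintf("ratio_threshold_mode=%s", params$threshold_mode),
    sprintf("ratio_threshold_used=%.10g", threshold),
    sprintf("percent_cutoff=%g", percent_cutoff),
    sprintf("conservativeness_rule=%s", rule),
    sprintf("codon_effect=%s", effect),
    sprintf("min_overlap=%d", as.integer(min_overlap)),
    sprintf("seed=%d", as.integer(seed)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(NULL)
}
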