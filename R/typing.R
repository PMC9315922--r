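#' Amino-acid physicochemical class tables
#'
#' Loads the three classification axes used to decide whether a
#' replacement mutation is conservative: hydropathy (hydrophobic /
#' neutral / hydrophilic), volume (very_small / small / medium / large /
#' very_large) and chemistry (aliphatic / aromatic / sulfur / hydroxyl /
#' basic / acidic / amide). The tables are shipped as a versioned TSV
#' (`extdata/aa_classes.tsv`), transcribed from the IMGT amino-acid
#' class definitions, and validated on load: each axis must cover the 20
#' standard amino acids exactly once.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A list of three named character vectors (`hydropathy`,
#'   `volume`, `chemistry`), names = one-letter amino-acid codes.
#' @export
aa_class_tables <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.ighvratio_env$aa_tables)) {
    return(.ighvratio_env$aa_tables)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "aa_classes.tsv", package = "ighvratio")
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("amino_acid", "hydropathy_class", "volume_class", "chemistry_class")
  if (!all(need %in% names(tab))) {
    stop("amino-acid class table lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(tab$amino_acid, aas) || anyDuplicated(tab$amino_acid)) {
    stop("amino-acid class table must cover the 20 standard amino acids exactly once")
  }
  tables <- list(
    hydropathy = setNames(tab$hydropathy_class, tab$amino_acid),
    volume = setNames(tab$volume_class, tab$amino_acid),
    chemistry = setNames(tab$chemistry_class, tab$amino_acid))
  if (default) .ighvratio_env$aa_tables <- tables
  tables
}

#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of 3-mers over `A C G T`.
#' @return One-letter amino-acid codes; `"*"` for stop codons.
#' @examples
#' translate_codon(c("ATG", "TAA", "CTG"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("codon(s) not unambiguous DNA 3-mers: ",
         paste(unique(codon[bad]), collapse = ", "))
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify an amino-acid replacement as conservative or not
#'
#' Compares the two residues on the three physicochemical axes. Under
#' `rule = "strict"` a replacement is conservative only when hydropathy,
#' volume *and* chemistry class all agree; under `rule = "majority"`
#' agreement on at least two axes suffices.
#'
#' @param aa_from,aa_to One-letter amino-acid codes (must differ).
#' @param tables Class tables from [aa_class_tables()].
#' @param rule `"strict"` (default) or `"majority"`.
#' @return A list with `conservative` (logical) and `axis_agreement`
#'   (named logical vector over hydropathy/volume/chemistry).
#' @examples
#' classify_aa_change("L", "I")$conservative   # TRUE: all axes agree
#' classify_aa_change("D", "K")$conservative   # FALSE
#' @export
classify_aa_change <- function(aa_from, aa_to, tables = aa_class_tables(),
                               rule = c("strict", "majority")) {
  rule <- match.arg(rule)
  if (aa_from == aa_to) stop("not a replacement: identical amino acids")
  for (aa in c(aa_from, aa_to)) {
    if (!aa %in% names(tables$hydropathy)) stop("not a standard amino acid: ", aa)
  }
  agree <- c(
    hydropathy = unname(tables$hydropathy[aa_from] == tables$hydropathy[aa_to]),
    volume = unname(tables$volume[aa_from] == tables$volume[aa_to]),
    chemistry = unname(tables$chemistry[aa_from] == tables$chemistry[aa_to]))
  conservative <- if (rule == "strict") all(agree) else sum(agree) >= 2L
  list(conservative = conservative, axis_agreement = agree)
}

#' Classify one nucleotide mutation as S, Rc or Rnc
#'
#' Default is the isolated-effect convention: the single base change is
#' applied to the *germline* codon and the two translations compared,
#' which keeps per-nucleotide counts additive when several mutations hit
#' one codon. `effect = "observed"` instead compares the germline codon
#' with the full observed codon. A change creating a stop codon is Rnc
#' with `to_stop = TRUE`. Sites whose codon context contains a gap or
#' ambiguous base are unclassifiable (`label = NA`) and excluded from
#' S/Rc/Rnc counts (but still counted in percent difference).
#'
#' @param site One mutation site (a row of [call_mutations()] output, or
#'   a list with `germline_codon`, `pos_in_codon`, `observed_base`,
#'   `observed_codon`).
#' @param tables,rule See [classify_aa_change()].
#' @param effect `"isolated"` (default) or `"observed"`.
#' @return A list with `label` (`"S"`, `"Rc"`, `"Rnc"` or `NA`),
#'   `to_stop` and `axis_agreement` (NA unless a replacement between two
#'   standard residues).
#' @export
classify_nt_mutation <- function(site, tables = aa_class_tables(),
                                 rule = c("strict", "majority"),
                                 effect = c("isolated", "observed")) {
  rule <- match.arg(rule)
  effect <- match.arg(effect)
  df <- as.data.frame(site, stringsAsFactors = FALSE)
  res <- classify_sites(df, tables = tables, rule = rule, effect = effect)
  list(label = res$label[1], to_stop = res$to_stop[1],
       axis_agreement = c(hydropathy = res$agree_hydropathy[1],
                          volume = res$agree_volume[1],
                          chemistry = res$agree_chemistry[1]))
}

#' Vectorised S/Rc/Rnc classification of mutation sites
#'
#' Same semantics as [classify_nt_mutation()], applied to a whole site
#' table at once (the fast path used by the pipeline and the simulator).
#'
#' @param sites Data frame with columns `germline_codon`, `pos_in_codon`,
#'   `observed_base` (and `observed_codon` for `effect = "observed"`).
#' @inheritParams classify_nt_mutation
#' @return `sites` with added columns `label`, `to_stop`,
#'   `agree_hydropathy`, `agree_volume`, `agree_chemistry`.
#' @export
classify_sites <- function(sites, tables = aa_class_tables(),
                           rule = c("strict", "majority"),
                           effect = c("isolated", "observed")) {
  rule <- match.arg(rule)
  effect <- match.arg(effect)
  n <- nrow(sites)
  label <- rep(NA_character_, n)
  to_stop <- rep(FALSE, n)
  ah <- av <- ac <- rep(NA, n)
  if (n == 0L) {
    return(cbind(sites, data.frame(label = character(0), to_stop = logical(0),
                                   agree_hydropathy = logical(0),
                                   agree_volume = logical(0),
                                   agree_chemistry = logical(0))))
  }

  gcod <- toupper(as.character(sites$germline_codon))
  ok <- !is.na(gcod) & grepl("^[ACGT]{3}$", gcod)
  if (effect == "isolated") {
    pos <- sites$pos_in_codon
    obs <- toupper(as.character(sites$observed_base))
    ok <- ok & !is.na(pos) & pos %in% 0:2 & obs %in% DNA_BASES_STRICT
    mcod <- gcod
    if (any(ok)) {
      m <- mcod[ok]
      substr(m, pos[ok] + 1L, pos[ok] + 1L) <- obs[ok]
      mcod[ok] <- m
    }
  } else {
    mcod <- toupper(as.character(sites$observed_codon))
    ok <- ok & !is.na(mcod) & grepl("^[ACGT]{3}$", mcod)
  }

  if (any(ok)) {
    aa_from <- unname(Biostrings::GENETIC_CODE[gcod[ok]])
    aa_to <- unname(Biostrings::GENETIC_CODE[mcod[ok]])
    lab <- rep(NA_character_, sum(ok))
    stp <- aa_to == "*"
    from_ok <- aa_from != "*"
    silent <- from_ok & aa_from == aa_to
    lab[from_ok & stp] <- "Rnc"
    lab[silent] <- "S"
    repl <- from_ok & !stp & !silent
    if (any(repl)) {
      hf <- tables$hydropathy[aa_from[repl]]; ht <- tables$hydropathy[aa_to[repl]]
      vf <- tables$volume[aa_from[repl]]; vt <- tables$volume[aa_to[repl]]
      cf <- tables$chemistry[aa_from[repl]]; ct <- tables$chemistry[aa_to[repl]]
      agh <- unname(hf == ht); agv <- unname(vf == vt); agc <- unname(cf == ct)
      cons <- if (rule == "strict") agh & agv & agc else (agh + agv + agc) >= 2L
      lab[repl] <- ifelse(cons, "Rc", "Rnc")
      ahh <- rep(NA, sum(ok)); avv <- rep(NA, sum(ok)); acc <- rep(NA, sum(ok))
      ahh[repl] <- agh; avv[repl] <- agv; acc[repl] <- agc
      ah[ok] <- ahh; av[ok] <- avv; ac[ok] <- acc
    }
    label[ok] <- lab
    to_stop[ok] <- from_ok & stp
  }
  out <- sites
  out$label <- label
  out$to_stop <- to_stop
  out$agree_hydropathy <- ah
  out$agree_volume <- av
  out$agree_chemistry <- ac
  out
}

#' Summarise classified sites into a per-sequence mutation profile
#'
#' Counts S, Rc and Rnc labels; `n_total` is their sum (unclassifiable
#' sites are reported separately in `n_unclassified` and excluded).
#' The Table-1-style category is derived from the counts: `0_mut`,
#' `s_only`, `r_only` or `s_plus_r`.
#'
#' @param labels Character vector of site labels (may contain `NA`).
#' @param pct Percent germline difference for the sequence.
#' @param status Mutation status string from [mutation_status()].
#' @param patient_id Identifier carried through.
#' @return One-row data.frame: `patient_id`, `n_s`, `n_rc`, `n_rnc`,
#'   `n_unclassified`, `n_total`, `percent_diff`, `status`, `category`.
#' @export
profile_sequence <- function(labels, pct = NA_real_, status = NA_character_,
                             patient_id = "") {
  n_s <- sum(labels == "S", na.rm = TRUE)
  n_rc <- sum(labels == "Rc", na.rm = TRUE)
  n_rnc <- sum(labels == "Rnc", na.rm = TRUE)
  n_un <- sum(is.na(labels))
  n_total <- n_s + n_rc + n_rnc
  category <- if (n_total == 0L) "0_mut"
  else if (n_s > 0L && n_rc + n_rnc == 0L) "s_only"
  else if (n_s == 0L) "r_only"
  else "s_plus_r"
  data.frame(patient_id = patient_id, n_s = n_s, n_rc = n_rc, n_rnc = n_rnc,
             n_unclassified = n_un, n_total = n_total, percent_diff = pct,
             status = status, category = category, stringsAsFactors = FALSE)
}
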