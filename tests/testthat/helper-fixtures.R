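# shared helpers: temporary input files and tiny generators

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# random pre-aligned pair over an alphabet including gaps and N
random_pair <- function(len = 120, p_mut = 0.05, p_gap = 0.02, p_n = 0.02) {
  g <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  p <- g
  r <- runif(len)
  mut <- r < p_mut
  for (i in which(mut)) p[i] <- sample(setdiff(c("A", "C", "G", "T"), g[i]), 1)
  gap <- runif(len) < p_gap
  p[gap] <- "-"
  nn <- runif(len) < p_n
  p[nn & !gap] <- "N"
  list(patient = paste(p, collapse = ""), germline = paste(g, collapse = ""))
}

# brute-force mutation-count oracle on a pre-aligned pair
count_mismatches_oracle <- function(patient, germline) {
  p <- strsplit(patient, "")[[1]]
  g <- strsplit(germline, "")[[1]]
  n <- 0L
  for (i in seq_along(p)) {
    if (p[i] %in% c("A", "C", "G", "T") && g[i] %in% c("A", "C", "G", "T") &&
        p[i] != g[i]) {
      n <- n + 1L
    }
  }
  n
}
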