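#' Log2 allele-signal contrast
#'
#' Transforms paired allele fluorescence signals into the one-dimensional
#' contrast (also called "Delta") in which genotype clusters are fit:
#' `contrast = log2(a_signal / b_signal)`.
#'
#' Non-positive or non-finite signals cannot be log-transformed; those cells
#' return `NA` and are treated as missing throughout the package.
#'
#' @param a_signal,b_signal Numeric vectors of A- and B-allele signal
#'   strengths (arbitrary fluorescence units, recycled to common length).
#' @return Numeric vector of contrasts, `NA` where either signal is invalid.
#' @examples
#' compute_contrast(4, 1)   # 2
#' compute_contrast(1, 8)   # -3
#' compute_contrast(0, 5)   # NA: non-positive signal
#' @export
compute_contrast <- function(a_signal, b_signal) {
  a <- as.numeric(a_signal)
  b <- as.numeric(b_signal)
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  out <- rep(NA_real_, max(length(a), length(b)))
  a <- rep_len(a, length(out))
  b <- rep_len(b, length(out))
  out[ok] <- log2(a[ok] / b[ok])
  out
}

#' Read an Axiom normalized-summary allele-signal file
#'
#' Parses the tab-delimited `AxiomGT1.normalized-summary.txt` dialect produced
#' by the array-processing software: `#` comment lines, a header row with one
#' column per sample, and two rows per probeset whose identifiers carry `-A`
#' and `-B` suffixes. The two rows are paired per probeset and the contrast is
#' computed per cell.
#'
#' Probesets with only one of the two rows are skipped with a warning.
#' Non-numeric or non-positive cells become missing contrasts.
#'
#' @param path Path to the file.
#' @return A tibble with columns `marker_id`, `sample_id`, `a_signal`,
#'   `b_signal`, `contrast`, one row per probeset x sample.
#' @seealso [write_normalized_summary()], [read_signals_long()],
#'   [contrast_matrix()]
#' @export
read_normalized_summary <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) stop("normalized-summary file needs an id column plus at least one sample column")
  ids <- raw[[1]]
  suffix <- sub("^.*(-[AB])$", "\\1", ids)
  bad <- !suffix %in% c("-A", "-B")
  if (any(bad)) {
    warning(sum(bad), " row(s) without an -A/-B suffix skipped")
    raw <- raw[!bad, ]
    ids <- ids[!bad]
    suffix <- suffix[!bad]
  }
  marker <- substr(ids, 1L, nchar(ids) - 2L)
  samples <- names(raw)[-1]
  a_rows <- match(unique(marker), marker[suffix == "-A"])
  markers <- unique(marker)
  has_a <- markers %in% marker[suffix == "-A"]
  has_b <- markers %in% marker[suffix == "-B"]
  incomplete <- markers[!(has_a & has_b)]
  if (length(incomplete)) {
    warning("probeset(s) missing an -A or -B row skipped: ",
            paste(incomplete, collapse = ", "))
  }
  keep <- markers[has_a & has_b]
  if (!length(keep)) {
    return(tibble::tibble(marker_id = character(), sample_id = character(),
                          a_signal = double(), b_signal = double(),
                          contrast = double()))
  }
  num <- function(rows) {
    m <- suppressWarnings(apply(as.matrix(raw[rows, -1, drop = FALSE]), 2, as.numeric))
    matrix(as.numeric(m), nrow = length(rows),
           dimnames = list(NULL, samples))
  }
  a_mat <- num(match(paste0(keep, "-A"), ids))
  b_mat <- num(match(paste0(keep, "-B"), ids))
  out <- tibble::tibble(
    marker_id = rep(keep, times = length(samples)),
    sample_id = rep(samples, each = length(keep)),
    a_signal = as.vector(a_mat),
    b_signal = as.vector(b_mat)
  )
  out$contrast <- compute_contrast(out$a_signal, out$b_signal)
  out
}

#' Write allele signals in the Axiom normalized-summary dialect
#'
#' Inverse of [read_normalized_summary()]: writes two tab-delimited rows per
#' probeset (`<marker>-A`, `<marker>-B`), one column per sample, with a `#`
#' provenance comment line. Values are written with enough significant digits
#' that a read-back reproduces contrasts to text precision.
#'
#' @param signals Tibble with `marker_id`, `sample_id`, `a_signal`, `b_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normalized_summary <- function(signals, path) {
  stopifnot(all(c("marker_id", "sample_id", "a_signal", "b_signal") %in% names(signals)))
  markers <- unique(signals$marker_id)
  samples <- unique(signals$sample_id)
  a <- matrix(NA_real_, length(markers), length(samples),
              dimnames = list(markers, samples))
  b <- a
  i <- cbind(match(signals$marker_id, markers), match(signals$sample_id, samples))
  a[i] <- signals$a_signal
  b[i] <- signals$b_signal
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#%normalized-summary written by triocall", con)
  writeLines(paste(c("probeset_id", samples), collapse = "\t"), con)
  for (k in seq_along(markers)) {
    writeLines(paste(c(paste0(markers[k], "-A"), fmt(a[k, ])), collapse = "\t"), con)
    writeLines(paste(c(paste0(markers[k], "-B"), fmt(b[k, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read allele signals from a long CSV
#'
#' Long dialect: one row per marker x sample with columns
#' `marker,sample,a_signal,b_signal` (header required, extra columns ignored).
#'
#' @param path Path to the CSV.
#' @return Tibble as from [read_normalized_summary()].
#' @export
read_signals_long <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  nm <- names(raw)
  marker_col <- intersect(c("marker", "marker_id", "probeset_id"), nm)[1]
  sample_col <- intersect(c("sample", "sample_id"), nm)[1]
  if (is.na(marker_col) || is.na(sample_col) ||
      !all(c("a_signal", "b_signal") %in% nm)) {
    stop("long signal CSV needs marker, sample, a_signal, b_signal columns")
  }
  out <- tibble::tibble(
    marker_id = as.character(raw[[marker_col]]),
    sample_id = as.character(raw[[sample_col]]),
    a_signal = as.numeric(raw$a_signal),
    b_signal = as.numeric(raw$b_signal)
  )
  out$contrast <- compute_contrast(out$a_signal, out$b_signal)
  out
}

#' Read a wide contrast CSV
#'
#' Wide dialect: first column marker id, remaining columns one per sample,
#' cells already on the contrast (log2 ratio) scale. Non-numeric cells become
#' missing.
#'
#' @param path Path to the CSV.
#' @return Tibble with `marker_id`, `sample_id`, `contrast`.
#' @export
read_contrast_wide <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  samples <- names(raw)[-1]
  vals <- suppressWarnings(apply(as.matrix(raw[-1]), 2, as.numeric))
  vals <- matrix(as.numeric(vals), nrow = nrow(raw))
  tibble::tibble(
    marker_id = rep(as.character(raw[[1]]), times = length(samples)),
    sample_id = rep(samples, each = nrow(raw)),
    contrast = as.vector(vals)
  )
}

#' Long signal/contrast tibble to markers x samples matrix
#'
#' @param signals Tibble with `marker_id`, `sample_id` and a value column.
#' @param value Name of the value column (default `"contrast"`).
#' @return Numeric matrix, markers as rows (dimnames kept), `NA` = missing.
#' @export
contrast_matrix <- function(signals, value = "contrast") {
  markers <- unique(signals$marker_id)
  samples <- unique(signals$sample_id)
  m <- matrix(NA_real_, length(markers), length(samples),
              dimnames = list(markers, samples))
  m[cbind(match(signals$marker_id, markers),
          match(signals$sample_id, samples))] <- signals[[value]]
  m
}

#' Read a genotype dosage table
#'
#' Reads a markers x samples table of allele dosages (count of A alleles,
#' `0..ploidy`; `NA` = no-call) written by [write_genotypes()]. Tab- or
#' comma-delimited is detected from the header line.
#'
#' @param path Path to the table.
#' @param ploidy Ploidy of the genotyped individuals (2 or 3); dosages outside
#'   `0..ploidy` are a hard error naming the offending marker and sample.
#' @return Tibble with `marker_id`, `sample_id`, `dosage` (integer or `NA`),
#'   with a `ploidy` attribute.
#' @export
read_genotypes <- function(path, ploidy) {
  stopifnot(ploidy >= 1)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    out <- tibble::tibble(marker_id = character(), sample_id = character(),
                          dosage = integer())
    attr(out, "ploidy") <- as.integer(ploidy)
    return(out)
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  samples <- names(raw)[-1]
  markers <- as.character(raw[[1]])
  vals <- suppressWarnings(apply(as.matrix(raw[-1]), 2, as.numeric))
  vals <- matrix(as.numeric(vals), nrow = nrow(raw))
  bad <- which(!is.na(vals) & (vals < 0 | vals > ploidy | vals != round(vals)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage out of range 0..%d at marker '%s', sample '%s'",
                 ploidy, markers[bad[1, 1]], samples[bad[1, 2]]))
  }
  out <- tibble::tibble(
    marker_id = rep(markers, times = length(samples)),
    sample_id = rep(samples, each = length(markers)),
    dosage = as.integer(as.vector(vals))
  )
  attr(out, "ploidy") <- as.integer(ploidy)
  out
}

#' Write a genotype dosage table
#'
#' Writes a markers x samples TSV of dosage codes with `NA` for no-calls;
#' round-trips exactly through [read_genotypes()].
#'
#' @param genotypes Tibble with `marker_id`, `sample_id`, `dosage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  m <- contrast_matrix(genotypes, value = "dosage")
  df <- data.frame(marker_id = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read or write a marker map
#'
#' A marker map places each marker on a chromosome at a 1-based bp position;
#' it is needed only by the recombination-profile stage.
#'
#' @param path Path to a TSV/CSV with columns `marker_id`, `chromosome`,
#'   `position`.
#' @return Tibble sorted by `(chromosome, position)`.
#' @export
read_marker_map <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  map <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_double()
  ), progress = FALSE)
  dplyr::arrange(map, .data$chromosome, .data$position)
}
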