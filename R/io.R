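# Readers and writers for the pipeline's plain-text interchange formats:
# per-ROI spectrum CSV, genes x AOIs count TSV, GMT gene sets, LCO reference
# CSV, nitrogen-index TSV and truth JSON.

#' Read a per-ROI spectrum CSV
#'
#' Two columns (mz, intensity), header optional.
#'
#' @param path CSV file path.
#' @param mode,resolving_power,roi_id Passed to [spectrum()].
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, mode = "LP", resolving_power = NULL,
                              roi_id = NA_character_) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[0-9.eE+-]+[,;\t]", first)
  df <- utils::read.csv(path, header = has_header)
  spectrum(df[[1]], df[[2]], mode = mode, resolving_power = resolving_power,
           roi_id = roi_id)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec A [spectrum()].
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(mz = spec$mz, intensity = spec$intensity),
                   path, row.names = FALSE)
}

#' Read a genes x AOIs count table (TSV/CSV)
#'
#' First column = gene ids, header row = AOI ids.
#'
#' @param path File path; separator inferred from the extension.
#' @return Numeric matrix with dimnames.
#' @export
read_counts <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Write a genes x AOIs count table as TSV
#'
#' @param counts Matrix with gene rownames and AOI colnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated name, description, genes.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Read LCO reference emission spectra
#'
#' CSV with columns wavelength, q, h.
#'
#' @param path CSV path.
#' @return A `reference_pair`.
#' @export
read_reference_spectra <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("wavelength", "q", "h") %in% names(df)))
  structure(list(wavelengths = df$wavelength, ref_q = df$q, ref_h = df$h),
            class = "reference_pair")
}

#' Write LCO reference emission spectra
#'
#' @param refs A `reference_pair`.
#' @param path CSV output path.
#' @export
write_reference_spectra <- function(refs, path) {
  utils::write.csv(data.frame(wavelength = refs$wavelengths, q = refs$ref_q,
                              h = refs$ref_h), path, row.names = FALSE)
}

#' Write per-ROI nitrogen-index records as TSV
#'
#' @param records data.frame with at least roi_id, mode, value, qc_pass.
#' @param path Output path.
#' @export
write_index_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' Write simulation ground truth as JSON
#'
#' @param truth List or data.frame of truth entries.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
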