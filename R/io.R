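# Tabular and JSON I/O for restraint data and fit results.

#' Write a fitted tensor (with UTR and fit report) as JSON
#'
#' @param tensor a [dchi_tensor()]
#' @param path output file
#' @param report optional fit report (from [fit_tensor()]) and/or
#'   bootstrap SDs to embed
#' @return `path`, invisibly
#' @export
write_tensor_json <- function(tensor, path, report = NULL) {
  utr <- to_utr(tensor)
  doc <- list(components_1e32_m3 = as.list(tensor$components),
              metal_angstrom = tensor$metal,
              utr = list(ax = utr$ax, rh = utr$rh,
                         alpha = utr$alpha, beta = utr$beta,
                         gamma = utr$gamma))
  if (!is.null(report))
    doc$report <- report[intersect(names(report),
                                   c("Q", "rss", "n_obs", "sd"))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a tensor JSON document
#'
#' @param path file written by [write_tensor_json()]
#' @return a [dchi_tensor()]
#' @export
read_tensor_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dchi_tensor(unlist(doc$components_1e32_m3), doc$metal_angstrom)
}

#' Read a PCS observation table
#'
#' TSV with header: `key`, `pcs_ppm` (or `pcs_hz` plus a frequency),
#' optional `sd_hz`.
#'
#' @param path file path
#' @param frequency_mhz spectrometer 1H frequency for Hz -> ppm
#' @return data frame with at least `key` and `pcs_ppm`
#' @export
read_pcs_table <- function(path, frequency_mhz = 500) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (is.null(df$key)) stop("PCS table needs a 'key' column")
  if (is.null(df$pcs_ppm)) {
    if (is.null(df$pcs_hz))
      stop("PCS table needs 'pcs_ppm' or 'pcs_hz'")
    df$pcs_ppm <- df$pcs_hz / frequency_mhz
  }
  df
}

#' Read a Gamma2 observation table
#'
#' TSV with header: `key`, `gamma2`, `sd`.
#'
#' @param path file path
#' @return data frame
#' @export
read_gamma2_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("key", "gamma2", "sd") %in% names(df)))
    stop("Gamma2 table needs columns key, gamma2, sd")
  df
}

#' Write a methyl table as TSV
#'
#' Columns: `resno`, `residue_type`, `methyl_id`, `stereo`, `x`, `y`,
#' `z` (plus `key`).
#'
#' @param methyls a `methyl_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_methyl_table <- function(methyls, path) {
  write.table(methyls[, c("key", "resno", "residue_type", "methyl_id",
                          "stereo", "x", "y", "z")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
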