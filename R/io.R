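# Dataset TSV dialect: header `smiles  sequence  label` plus optional
# `drug_id`, `protein_id`; UTF-8; label in {0, 1}.

#' Write interaction records as TSV
#'
#' @param records Data frame with `smiles`, `sequence`, `label` (optional
#'   `drug_id`, `protein_id`).
#' @param path Output file.
#' @param manifest Optional manifest list; when given, written as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path, manifest = NULL) {
  data.table::fwrite(records, path, sep = "\t")
  if (!is.null(manifest))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read interaction records from TSV
#'
#' @param path TSV with at least `smiles` and `sequence` columns; `label`
#'   (0/1) required unless `require_label = FALSE`.
#' @param require_label Demand a label column (default TRUE).
#' @return data.frame of records.
#' @export
read_interactions <- function(path, require_label = TRUE) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "sequence")))
  if (!all(c("smiles", "sequence") %in% names(df)))
    stop_invalid("TSV must have `smiles` and `sequence` columns")
  if (require_label) {
    if (is.null(df$label)) stop_invalid("TSV is missing the `label` column")
    if (!all(df$label %in% 0:1)) stop_invalid("labels must be 0 or 1")
  }
  df
}
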