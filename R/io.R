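# Plain-text readers/writers for the pipeline's external formats. All files
# are UTF-8; tables are comma-separated with a header row on input and
# tab-separated on output (the convention of the result tables).

#' Read a participant table
#'
#' Expects the columns documented in [study_dataset()]; `ses`,
#' `urban_unit_index` are integers, `attended_primary_school` logical
#' (`TRUE`/`FALSE`, empty = unknown).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_participants_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  p$participant_id <- as.character(p$participant_id)
  if ("attended_primary_school" %in% names(p)) {
    p$attended_primary_school <- as.logical(p$attended_primary_school)
  }
  p
}

#' Read a response table
#'
#' Wide format: a `participant_id` column plus one column per variable,
#' holding response labels (empty = missing).
#'
#' @param path CSV file path.
#' @return Character matrix with participant ids as rownames.
#' @export
read_responses_csv <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       na.strings = c("NA", ""), colClasses = "character")
  as_response_table(r)
}

#' @rdname read_participants_csv
#' @param participants data.frame to write.
#' @export
write_participants_csv <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_responses_csv
#' @param responses Response table (matrix or data.frame).
#' @export
write_responses_csv <- function(responses, path) {
  m <- as_response_table(responses)
  df <- data.frame(participant_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
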