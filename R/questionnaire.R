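#' Define a questionnaire item
#'
#' A question definition declares everything needed to turn raw response
#' labels into an analysis variable on \[0, 1\]: the variable identifier, its
#' kind (binary or ordinal), the ordered response levels, and an orientation
#' flag so that higher encoded values always point in a consistent
#' interpretive direction (e.g. "more exposure").
#'
#' @param variable_id Character scalar, unique identifier of the variable.
#' @param levels Character vector of 2 to 5 unique response labels, ordered
#'   from lowest to highest.
#' @param kind `"binary"` or `"ordinal"`. Defaults to `"binary"` when there
#'   are exactly two levels and `"ordinal"` otherwise.
#' @param orientation `"as_is"` keeps the declared level order; `"reversed"`
#'   flips it before encoding.
#' @return An object of class `question_def`.
#' @examples
#' question_def("cola", c("never", "monthly", "weekly", "daily", "several_daily"))
#' @export
question_def <- function(variable_id, levels,
                         kind = if (length(levels) == 2L) "binary" else "ordinal",
                         orientation = c("as_is", "reversed")) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind, c("binary", "ordinal"))
  if (!is.character(variable_id) || length(variable_id) != 1L || is.na(variable_id) ||
      !nzchar(variable_id)) {
    stop("'variable_id' must be a non-empty character scalar", call. = FALSE)
  }
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop("question '", variable_id, "' is degenerate: fewer than 2 levels",
         call. = FALSE)
  }
  if (length(levels) > 5L) {
    stop("question '", variable_id, "' has more than 5 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("question '", variable_id, "' has duplicated levels", call. = FALSE)
  }
  if ((kind == "binary") != (length(levels) == 2L)) {
    stop("question '", variable_id, "': kind 'binary' iff exactly 2 levels",
         call. = FALSE)
  }
  structure(
    list(variable_id = variable_id, kind = kind, levels = levels,
         orientation = orientation),
    class = "question_def"
  )
}

#' Assemble a questionnaire specification
#'
#' @param questions A list of [question_def()] objects with unique
#'   `variable_id`s; their order is preserved and defines the column order of
#'   encoded matrices.
#' @return An object of class `questionnaire_spec`, a named list of
#'   `question_def`s.
#' @export
questionnaire_spec <- function(questions) {
  if (inherits(questions, "question_def")) questions <- list(questions)
  stopifnot(is.list(questions), length(questions) > 0L)
  ok <- vapply(questions, inherits, logical(1), "question_def")
  if (!all(ok)) stop("all elements must be question_def objects", call. = FALSE)
  ids <- vapply(questions, `[[`, character(1), "variable_id")
  if (anyDuplicated(ids)) {
    stop("duplicated variable_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(questions) <- ids
  structure(questions, class = "questionnaire_spec")
}

#' @export
print.questionnaire_spec <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat("questionnaire_spec:", length(x), "variables (",
      sum(kinds == "binary"), "binary,", sum(kinds == "ordinal"), "ordinal )\n")
  invisible(x)
}

#' @export
variable_ids <- function(spec) UseMethod("variable_ids")

#' @export
variable_ids.questionnaire_spec <- function(spec) names(spec)

#' Read / write a questionnaire specification as YAML
#'
#' The on-disk format is a list of mappings, one per question, with keys
#' `variable_id`, `kind`, `levels`, `orientation`.
#'
#' @param path File path.
#' @return `read_questionnaire_yaml` returns a `questionnaire_spec`;
#'   `write_questionnaire_yaml` returns `path` invisibly.
#' @export
read_questionnaire_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  qs <- lapply(raw, function(q) {
    question_def(q$variable_id, unlist(q$levels), kind = q$kind,
                 orientation = if (is.null(q$orientation)) "as_is" else q$orientation)
  })
  questionnaire_spec(qs)
}

#' @rdname read_questionnaire_yaml
#' @param spec A `questionnaire_spec`.
#' @export
write_questionnaire_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  out <- lapply(unname(spec), function(q) {
    list(variable_id = q$variable_id, kind = q$kind,
         levels = as.list(q$levels), orientation = q$orientation)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Encoded values attainable by a question
#'
#' Binary questions encode to \{0, 1\}; an ordinal question with L levels
#' encodes its k-th level (k = 0..L-1, after applying orientation) to
#' k/(L-1), i.e. equally spaced points on \[0, 1\]. The attainable set is
#' fixed by the question definition, never by the observed data, so
#' encodings are comparable across samples.
#'
#' @param q A `question_def`.
#' @return Named numeric vector mapping each response label to its encoded
#'   value.
#' @export
encoding_map <- function(q) {
  stopifnot(inherits(q, "question_def"))
  L <- length(q$levels)
  k <- seq_len(L) - 1
  if (q$orientation == "reversed") k <- rev(k)
  stats::setNames(k / (L - 1), q$levels)
}

#' Encode raw questionnaire responses to the unit interval
#'
#' Turns a participant-by-question table of response labels into a numeric
#' matrix with all non-missing values in \[0, 1\] (see [encoding_map()]).
#' Missing responses stay missing; no imputation is performed, so downstream
#' tests operate on per-variable complete cases.
#'
#' @param raw_responses A data.frame or character matrix, one row per
#'   participant (rownames or a `participant_id` column give participant
#'   identifiers) and one column per variable in `spec`.
#' @param spec A `questionnaire_spec`. Every column of `raw_responses`
#'   matching a `variable_id` is encoded; spec variables absent from the
#'   table are an error.
#' @return Numeric matrix (participants x variables) with `NA` for missing,
#'   rownames = participant ids, colnames = variable ids in spec order.
#' @export
encode_variables <- function(raw_responses, spec) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  raw <- as_response_table(raw_responses)
  ids <- names(spec)
  missing_cols <- setdiff(ids, colnames(raw))
  if (length(missing_cols)) {
    stop("responses table lacks variables: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(raw), length(ids),
                dimnames = list(rownames(raw), ids))
  for (v in ids) {
    map <- encoding_map(spec[[v]])
    x <- raw[, v]
    bad <- !is.na(x) & !(x %in% names(map))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("unknown response label '", x[i], "' for variable '", v,
           "' (participant '", rownames(raw)[i], "')", call. = FALSE)
    }
    out[, v] <- unname(map[x])
  }
  out
}

#' Per-participant questionnaire missingness
#'
#' Fraction of questions left unanswered by one participant, the quantity
#' the exclusion cascade compares against its missingness ceiling (default
#' 0.5: questionnaires more than half empty are dropped).
#'
#' @param raw_responses Response table as in [encode_variables()].
#' @param participant_id Identifier of the participant (must be present).
#' @return A fraction in \[0, 1\].
#' @export
participant_missingness <- function(raw_responses, participant_id) {
  raw <- as_response_table(raw_responses)
  if (ncol(raw) == 0L) stop("no questions in responses table", call. = FALSE)
  if (!participant_id %in% rownames(raw)) {
    stop("participant '", participant_id, "' not found", call. = FALSE)
  }
  x <- raw[participant_id, ]
  sum(is.na(x)) / length(x)
}

# Normalize the accepted response-table inputs (wide data.frame with a
# participant_id column, or a matrix with rownames) to a character matrix
# with participant ids as rownames. Empty strings count as missing.
as_response_table <- function(raw) {
  if (is.data.frame(raw)) {
    if ("participant_id" %in% names(raw)) {
      rn <- as.character(raw$participant_id)
      raw <- raw[, setdiff(names(raw), "participant_id"), drop = FALSE]
    } else {
      rn <- rownames(raw)
    }
    m <- as.matrix(raw)
    storage.mode(m) <- "character"
    rownames(m) <- rn
  } else if (is.matrix(raw)) {
    m <- raw
    storage.mode(m) <- "character"
  } else {
    stop("responses must be a data.frame or matrix", call. = FALSE)
  }
  if (is.null(rownames(m))) {
    stop("responses table needs participant identifiers (rownames or a ",
         "'participant_id' column)", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicated participant ids", call. = FALSE)
  m[!is.na(m) & m == ""] <- NA_character_
  m
}
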