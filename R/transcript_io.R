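# Reading, cleaning, labeling and structural segmentation of two-speaker
# interview transcripts.

#' Default speaker aliases
#'
#' Maps the speaker strings found in transcript files to the two canonical
#' roles. Matching is case-insensitive. The defaults cover the interviewer
#' agent ("Ellie") and participant naming used by Wizard-of-Oz clinical
#' interview corpora plus the generic names used by the synthetic generator.
#'
#' @return Named character vector: names are lowercase speaker strings, values
#'   are `"therapist"` or `"patient"`.
#' @export
default_speaker_aliases <- function() {
  c(
    ellie       = "therapist",
    therapist   = "therapist",
    interviewer = "therapist",
    participant = "patient",
    patient     = "patient"
  )
}

#' Clean utterance text
#'
#' Lowercases, strips bracketed non-verbal annotations (e.g. `<laughter>`,
#' `[sighs]`) and collapses runs of whitespace. Returns `""` for rows whose
#' content is entirely annotation, which callers drop.
#'
#' @param x Character vector of raw utterance texts.
#' @param annotation_regex Regex for non-verbal annotations to remove.
#' @return Cleaned character vector of the same length.
#' @export
clean_text <- function(x, annotation_regex = "<[^>]*>|\\[[^]]*\\]") {
  x <- tolower(as.character(x))
  x <- gsub(annotation_regex, " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

new_transcript <- function(id, utterances, phq8 = NA_integer_, label = NA_integer_) {
  stopifnot(is.data.frame(utterances))
  structure(
    list(id = as.character(id), utterances = utterances,
         phq8 = phq8, label = label),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabeled" else if (x$label == 1L) "depressed" else "non-depressed"
  cat(sprintf("<transcript '%s': %d utterances, PHQ-8 = %s, %s>\n",
              x$id, nrow(x$utterances),
              ifelse(is.na(x$phq8), "NA", x$phq8), lab))
  invisible(x)
}

#' Read an interview transcript from a delimited file
#'
#' Reads one interview from a CSV/TSV file with one utterance per row.
#' The default column names (`speaker`, `value`, `start_time`, `stop_time`)
#' follow the transcript dialect of Wizard-of-Oz clinical interview corpora.
#' Speaker strings are mapped case-insensitively through `aliases`; rows whose
#' text is empty after cleaning are dropped and remaining utterances are
#' re-indexed from 0.
#'
#' @param path Path to the transcript file.
#' @param id Transcript identifier; defaults to the file name without extension.
#' @param sep Field separator; `NULL` auto-detects tab vs comma from the header.
#' @param speaker_col,text_col Column names for speaker and utterance text.
#' @param start_col,stop_col Optional timing column names (seconds).
#' @param aliases Speaker alias map, see [default_speaker_aliases()].
#' @param annotation_regex Passed to [clean_text()].
#' @param phq8 Optional PHQ-8 score (integer 0-24) to attach.
#' @return A `transcript` object: id, an utterance data frame
#'   (`index` 0-based, `speaker`, `text`, `start_time`, `stop_time`),
#'   optional `phq8` and binary `label` (1 = depressed).
#' @export
read_transcript <- function(path, id = NULL, sep = NULL,
                            speaker_col = "speaker", text_col = "value",
                            start_col = "start_time", stop_col = "stop_time",
                            aliases = default_speaker_aliases(),
                            annotation_regex = "<[^>]*>|\\[[^]]*\\]",
                            phq8 = NA_integer_) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(speaker_col, text_col)) {
    if (!col %in% names(raw)) {
      stop(sprintf("transcript format error: required column '%s' missing in %s",
                   col, path))
    }
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  build_transcript_from_rows(
    id = id,
    speakers = raw[[speaker_col]],
    texts = raw[[text_col]],
    start = if (start_col %in% names(raw)) raw[[start_col]] else NULL,
    stop = if (stop_col %in% names(raw)) raw[[stop_col]] else NULL,
    aliases = aliases, annotation_regex = annotation_regex, phq8 = phq8
  )
}

build_transcript_from_rows <- function(id, speakers, texts, start = NULL,
                                       stop = NULL,
                                       aliases = default_speaker_aliases(),
                                       annotation_regex = "<[^>]*>|\\[[^]]*\\]",
                                       phq8 = NA_integer_) {
  key <- tolower(trimws(as.character(speakers)))
  unknown <- which(!key %in% names(aliases))
  if (length(unknown) > 0L) {
    stop(sprintf(
      "transcript format error: unknown speaker '%s' at row %d (configure `aliases`)",
      speakers[unknown[1L]], unknown[1L]))
  }
  speaker <- unname(aliases[key])
  text <- clean_text(texts, annotation_regex)
  keep <- nzchar(text)
  if (!any(keep)) stop("empty transcript: no utterances survive cleaning in '", id, "'")
  n <- sum(keep)
  utt <- data.frame(
    index = seq_len(n) - 1L,
    speaker = speaker[keep],
    text = text[keep],
    start_time = if (is.null(start)) rep(NA_real_, n) else as.numeric(start[keep]),
    stop_time = if (is.null(stop)) rep(NA_real_, n) else as.numeric(stop[keep]),
    stringsAsFactors = FALSE
  )
  tr <- new_transcript(id, utt, phq8 = phq8)
  if (!is.na(phq8)) tr <- assign_label(tr) else tr
}

#' Write a transcript back to a delimited file
#'
#' Writes the dialect [read_transcript()] reads (tab-separated,
#' columns `speaker`, `value`, `start_time`, `stop_time`), so that a
#' write/read round trip reproduces speakers, texts and order exactly.
#'
#' @param transcript A `transcript`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  u <- transcript$utterances
  out <- data.frame(speaker = u$speaker, value = u$text,
                    start_time = u$start_time, stop_time = u$stop_time)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Assign the binary depression label from the PHQ-8 score
#'
#' Applies the conventional screening threshold: a transcript is labeled
#' depressed (1) iff its PHQ-8 score is at least 10, otherwise
#' non-depressed (0).
#'
#' @param transcript A `transcript` with a `phq8` score (or an existing label).
#' @return The transcript with `label` set.
#' @export
assign_label <- function(transcript) {
  if (is.na(transcript$phq8)) {
    if (is.na(transcript$label)) {
      stop("labeling error: transcript '", transcript$id,
           "' has neither a PHQ-8 score nor a label")
    }
    return(transcript)
  }
  if (transcript$phq8 < 0 || transcript$phq8 > 24) {
    stop("labeling error: PHQ-8 score out of range [0, 24]: ", transcript$phq8)
  }
  transcript$label <- as.integer(transcript$phq8 >= 10)
  transcript
}

#' Segment a transcript into maximal same-speaker turns
#'
#' A turn is a maximal run of consecutive utterances by the same speaker;
#' neighbouring turns always belong to different speakers. Turn texts are the
#' member utterance texts joined with single spaces.
#'
#' @param transcript A non-empty `transcript`.
#' @return A list of turns, each a list with `speaker`, `utterance_indices`
#'   (0-based, contiguous) and `text`.
#' @export
segment_turns <- function(transcript) {
  u <- transcript$utterances
  if (nrow(u) == 0L) stop("cannot segment an empty transcript")
  run <- cumsum(c(1L, as.integer(u$speaker[-1L] != u$speaker[-nrow(u)])))
  lapply(split(seq_len(nrow(u)), run), function(rows) {
    list(speaker = u$speaker[rows[1L]],
         utterance_indices = u$index[rows],
         text = paste(u$text[rows], collapse = " "))
  })
}

#' Pair therapist question turns with the patient answer turns that follow
#'
#' Question-answer correspondence is defined at the turn level: each therapist
#' turn is paired with the patient turn immediately following it. A leading
#' patient turn or a trailing therapist turn has no counterpart and is left
#' unpaired (it still appears as nodes in view graphs, just without cross
#' edges).
#'
#' @param turns Turn list from [segment_turns()].
#' @return A list of pairs, each a list with `question` and `answer` turns and
#'   their positions `q_turn`, `a_turn` in the input turn list.
#' @export
pair_questions_answers <- function(turns) {
  pairs <- list()
  i <- 1L
  while (i < length(turns)) {
    if (turns[[i]]$speaker == "therapist" && turns[[i + 1L]]$speaker == "patient") {
      pairs[[length(pairs) + 1L]] <- list(
        question = turns[[i]], answer = turns[[i + 1L]],
        q_turn = i, a_turn = i + 1L
      )
    }
    i <- i + 1L
  }
  pairs
}

#' Split a transcript into therapist and patient views
#'
#' The two views partition the utterances by speaker, preserving order.
#' An empty view (e.g. an all-therapist transcript) is permitted and
#' propagates downstream as an empty view graph.
#'
#' @param transcript A non-empty `transcript`.
#' @return List with `therapist` and `patient`: 0-based utterance index
#'   vectors.
#' @export
split_views <- function(transcript) {
  u <- transcript$utterances
  if (nrow(u) == 0L) stop("cannot split an empty transcript")
  list(
    therapist = u$index[u$speaker == "therapist"],
    patient = u$index[u$speaker == "patient"]
  )
}

#' Read a label file
#'
#' Two-column CSV mapping transcript id to either a PHQ-8 score (`phq8`
#' column) or a binary label (`label` column).
#'
#' @param path CSV path with header.
#' @return Data frame with `id` and whichever of `phq8`/`label` is present.
#' @export
read_labels <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(lab)) stop("label file must have an 'id' column")
  if (!any(c("phq8", "label") %in% names(lab))) {
    stop("label file must have a 'phq8' or 'label' column")
  }
  lab$id <- as.character(lab$id)
  lab
}
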