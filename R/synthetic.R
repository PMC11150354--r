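# Synthetic two-speaker interview corpus generator. Emulates the statistical
# structure the graph models exploit: a finite shared topic set, therapist
# questions answered with topic words, class imbalance, shorter patient
# answers plus heavier therapist follow-up questioning for depressed cases,
# and marker keywords planted almost exclusively in high-score transcripts.
# Text is template-based token sequences, sufficient for the deterministic
# encoder and the NMF topic models; it is not natural language.

#' Default topic vocabularies
#'
#' Eight disjoint word lists standing in for the life-domain topics a
#' semi-structured clinical interview walks through.
#'
#' @return Named list of character vectors.
#' @export
default_topics <- function() {
  list(
    work = c("job", "office", "boss", "coworkers", "salary", "working",
             "career", "shift", "workplace", "employment"),
    family = c("family", "mother", "father", "brother", "sister", "parents",
               "kids", "children", "household", "relatives"),
    sleep = c("sleep", "insomnia", "tired", "bed", "night", "dreams",
              "rest", "awake", "nap", "exhausted"),
    relationships = c("partner", "friends", "dating", "marriage", "divorce",
                      "lonely", "social", "trust", "connection", "breakup"),
    health = c("doctor", "illness", "pain", "hospital", "exercise",
               "appetite", "weight", "energy", "headaches", "sick"),
    hobbies = c("music", "reading", "movies", "travel", "cooking", "sports",
                "games", "painting", "hiking", "guitar"),
    living = c("apartment", "city", "moving", "neighborhood", "rent",
               "roommate", "commute", "hometown", "weather", "house"),
    mood = c("feeling", "sad", "happy", "anxious", "stress", "worry",
             "anger", "hopeless", "mood", "crying")
  )
}

#' Default conversation-filler vocabulary
#'
#' Short back-channel tokens that form dense, uninformative clusters in
#' therapist-side similarity graphs.
#'
#' @return Character vector.
#' @export
default_fillers <- function() {
  c("mhm", "uh-huh", "okay", "yeah", "right", "sure", "hmm", "alright")
}

#' Generator parameters
#'
#' Defaults mirror the study conditions the models target: about 100
#' interviews with a 70/30 negative/positive class split, topic-driven
#' question-answer structure, shorter patient answers and more therapist
#' follow-up questions in the depressed class, and marker keywords
#' ("therapy", "depression", "p_t_s_d", ...) injected into patient answers
#' with probability 0.95 for positive and 0.05 for negative transcripts.
#'
#' @param n_transcripts Number of interviews.
#' @param positive_rate Probability of the depressed class (default 0.3).
#' @param topics Named list of disjoint topic vocabularies.
#' @param marker_keywords Marker tokens tied to the positive class.
#' @param marker_rate_pos,marker_rate_neg Per-transcript marker-injection
#'   probabilities by class.
#' @param answer_len_pos,answer_len_neg Min/max tokens per patient answer
#'   utterance, by class (positive answers shorter).
#' @param followup_rate_pos,followup_rate_neg Probability of a follow-up
#'   question-answer exchange per topic, by class (higher for positives).
#' @param filler_rate Probability a therapist turn carries a filler
#'   utterance.
#' @param fillers Filler vocabulary.
#' @param noise_rate Probability per answer of a random out-of-topic token.
#' @param n_topics_per_transcript Min/max topics sampled per interview.
#' @param phq8_neg,phq8_pos Class-conditional PHQ-8 ranges (scores below 10
#'   are the non-depressed class).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated `gen_params` list.
#' @export
gen_params <- function(n_transcripts = 100L, positive_rate = 0.3,
                       topics = default_topics(),
                       marker_keywords = c("therapy", "depression", "p_t_s_d",
                                           "medication", "diagnosis"),
                       marker_rate_pos = 0.95, marker_rate_neg = 0.05,
                       answer_len_pos = c(2L, 5L), answer_len_neg = c(7L, 14L),
                       followup_rate_pos = 0.6, followup_rate_neg = 0.15,
                       filler_rate = 0.35, fillers = default_fillers(),
                       noise_rate = 0.05,
                       n_topics_per_transcript = c(5L, 8L),
                       phq8_neg = c(0L, 9L), phq8_pos = c(10L, 24L),
                       seed = 0L) {
  p <- list(n_transcripts = as.integer(n_transcripts),
            positive_rate = positive_rate, topics = topics,
            marker_keywords = marker_keywords,
            marker_rate_pos = marker_rate_pos, marker_rate_neg = marker_rate_neg,
            answer_len_pos = as.integer(answer_len_pos),
            answer_len_neg = as.integer(answer_len_neg),
            followup_rate_pos = followup_rate_pos,
            followup_rate_neg = followup_rate_neg,
            filler_rate = filler_rate, fillers = fillers,
            noise_rate = noise_rate,
            n_topics_per_transcript = as.integer(pmin(n_topics_per_transcript,
                                                      length(topics))),
            phq8_neg = as.integer(phq8_neg), phq8_pos = as.integer(phq8_pos),
            seed = as.integer(seed))
  validate_gen_params(p)
  structure(p, class = "gen_params")
}

validate_gen_params <- function(p) {
  if (p$n_transcripts < 1L) stop("invalid params: n_transcripts must be >= 1")
  if (!(p$positive_rate > 0 && p$positive_rate < 1)) {
    stop("invalid params: positive_rate must lie in (0, 1)")
  }
  rates <- c(p$marker_rate_pos, p$marker_rate_neg, p$followup_rate_pos,
             p$followup_rate_neg, p$filler_rate, p$noise_rate)
  if (any(rates < 0 | rates > 1)) stop("invalid params: rates must lie in [0, 1]")
  all_words <- unlist(p$topics, use.names = FALSE)
  if (anyDuplicated(all_words)) {
    stop("invalid params: topic vocabularies must be disjoint")
  }
  if (any(p$marker_keywords %in% all_words)) {
    stop("invalid params: marker keywords must not appear in topic vocabularies")
  }
  invisible(p)
}

# Glue tokens: mostly stop words so the NMF vocabulary stays topical.
.question_stems <- list(
  c("tell", "me", "about", "your"),
  c("how", "do", "you", "feel", "about", "your"),
  c("what", "can", "you", "say", "about", "your"),
  c("could", "you", "describe", "your")
)
.followup_stems <- list(
  c("can", "you", "say", "more", "about", "your"),
  c("why", "do", "you", "think", "that", "is"),
  c("how", "does", "that", "affect", "your")
)

sample_range <- function(r) if (r[1L] >= r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

generate_one_transcript <- function(p, id, label) {
  topics_here <- sample(names(p$topics), sample_range(p$n_topics_per_transcript))
  ans_len <- if (label == 1L) p$answer_len_pos else p$answer_len_neg
  followup_rate <- if (label == 1L) p$followup_rate_pos else p$followup_rate_neg
  marker_rate <- if (label == 1L) p$marker_rate_pos else p$marker_rate_neg
  inject_markers <- stats::runif(1) < marker_rate
  markers_here <- if (inject_markers) {
    sample(p$marker_keywords, min(3L, length(p$marker_keywords)))
  } else character(0)
  all_topic_words <- unlist(p$topics, use.names = FALSE)

  speakers <- character(0); texts <- character(0)
  say <- function(speaker, tokens) {
    speakers <<- c(speakers, speaker)
    texts <<- c(texts, paste(tokens, collapse = " "))
  }
  answer_tokens <- function(vocab) {
    toks <- sample(vocab, sample_range(ans_len), replace = TRUE)
    if (stats::runif(1) < p$noise_rate) {
      toks <- c(toks, sample(all_topic_words, 1L))
    }
    toks
  }
  # markers are spread over the patient's answers on a few random topics
  marker_topics <- if (length(markers_here) > 0L) {
    sample(topics_here, min(length(markers_here), length(topics_here)))
  } else character(0)

  for (topic in topics_here) {
    vocab <- p$topics[[topic]]
    q <- c(.question_stems[[sample.int(length(.question_stems), 1L)]],
           sample(vocab, 2L))
    if (stats::runif(1) < p$filler_rate) {
      say("therapist", sample(p$fillers, 1L))
    }
    say("therapist", q)
    if (topic %in% marker_topics) {
      # the answer dwells on treatment/diagnosis vocabulary: these
      # marker-dominated responses are what surfaces as marker-keyword
      # clusters in the keyword graphs
      a <- sample(markers_here, sample_range(ans_len), replace = TRUE)
    } else {
      a <- answer_tokens(vocab)
    }
    say("patient", a)
    while (stats::runif(1) < followup_rate) {
      fq <- c(.followup_stems[[sample.int(length(.followup_stems), 1L)]],
              sample(vocab, 1L))
      say("therapist", fq)
      say("patient", answer_tokens(vocab))
      if (stats::runif(1) > followup_rate) break
    }
  }
  phq_range <- if (label == 1L) p$phq8_pos else p$phq8_neg
  phq8 <- sample(phq_range[1L]:phq_range[2L], 1L)
  build_transcript_from_rows(id = id, speakers = speakers, texts = texts,
                             phq8 = phq8)
}

#' Generate a labeled synthetic interview corpus
#'
#' Each transcript walks through a sampled subset of the global topics; per
#' topic the therapist asks a question built from that topic's vocabulary
#' and the patient answers with topic words. Depressed-class transcripts get
#' shorter answers, more follow-up questions, and marker keywords injected
#' into their answers with high probability; PHQ-8 scores are sampled from
#' class-conditional ranges so the >= 10 labeling rule reproduces the class.
#'
#' @param params A [gen_params()] object.
#' @return A `synthetic_corpus`: `transcripts` (list of `transcript`) and the
#'   generating `params`. Splits are added by [make_splits()].
#' @export
generate_corpus <- function(params = gen_params()) {
  validate_gen_params(params)
  withr::with_seed(params$seed, {
    labels <- stats::rbinom(params$n_transcripts, 1L, params$positive_rate)
    transcripts <- lapply(seq_len(params$n_transcripts), function(i) {
      generate_one_transcript(params, sprintf("synth_%03d", i), labels[i])
    })
    structure(list(transcripts = transcripts, params = params, splits = NULL),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  labs <- vapply(x$transcripts, function(t) t$label, integer(1L))
  cat(sprintf("<synthetic_corpus: %d transcripts, %d depressed / %d non-depressed>\n",
              length(x$transcripts), sum(labs), sum(labs == 0L)))
  invisible(x)
}

corpus_ids <- function(corpus) {
  vapply(corpus$transcripts, function(t) t$id, character(1L))
}

corpus_labels <- function(corpus) {
  stats::setNames(vapply(corpus$transcripts, function(t) t$label, integer(1L)),
                  corpus_ids(corpus))
}

# Largest-remainder rounding of n * fractions to integers summing to n.
apportion <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

#' Split a corpus into train/dev/test id lists
#'
#' @param corpus A `synthetic_corpus` (or any list with `transcripts`).
#' @param fractions Numeric of length 3 summing to 1 (train, dev, test).
#' @param stratified Balance the positive rate across splits.
#' @param seed Shuffling seed.
#' @return Named list `train`, `dev`, `test` of transcript ids (disjoint,
#'   exhaustive).
#' @export
make_splits <- function(corpus, fractions = c(train = 0.6, dev = 0.2, test = 0.2),
                        stratified = TRUE, seed = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  ids <- corpus_ids(corpus)
  labels <- corpus_labels(corpus)
  splits_names <- c("train", "dev", "test")
  global_sizes <- apportion(length(ids), fractions)
  assign_sizes <- function(ids_g, sizes) {
    shuffled <- sample(ids_g)
    grp <- rep(splits_names, times = sizes)
    split(shuffled, factor(grp, levels = splits_names))
  }
  withr::with_seed(as.integer(seed), {
    parts <- if (stratified) {
      # per-group floors, with remainders steered toward the splits still
      # below their exact global size
      by_lab <- split(ids, labels)
      floors <- lapply(by_lab, function(g) floor(length(g) * fractions))
      deficit <- global_sizes - Reduce(`+`, floors)
      merged <- stats::setNames(rep(list(character(0)), 3L), splits_names)
      for (k in seq_along(by_lab)) {
        g <- by_lab[[k]]
        sizes <- as.integer(floors[[k]])
        rem <- length(g) - sum(sizes)
        frac_order <- order(length(g) * fractions - sizes, decreasing = TRUE)
        while (rem > 0L) {
          pick <- frac_order[which(deficit[frac_order] > 0)[1L]]
          sizes[pick] <- sizes[pick] + 1L
          deficit[pick] <- deficit[pick] - 1L
          rem <- rem - 1L
        }
        s <- assign_sizes(g, sizes)
        for (nm in splits_names) merged[[nm]] <- c(merged[[nm]], s[[nm]])
      }
      merged
    } else {
      assign_sizes(ids, global_sizes)
    }
    if (any(vapply(parts, length, integer(1L)) < 1L)) {
      stop("split error: every split must receive at least one transcript")
    }
    lapply(parts, function(x) ids[ids %in% x])  # restore corpus order
  })
}

#' Write a corpus to disk / read it back
#'
#' Transcripts are written in the delimited dialect [read_transcript()]
#' reads (one TSV per transcript under `dir/transcripts/`) plus a
#' `labels.csv` with id and PHQ-8 score, and split id lists as
#' `splits.json` when present.
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir` (write) / a corpus-like list (read).
#' @export
write_corpus <- function(corpus, dir) {
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (tr in corpus$transcripts) {
    write_transcript(tr, file.path(tdir, paste0(tr$id, ".tsv")))
  }
  labs <- data.frame(id = corpus_ids(corpus),
                     phq8 = vapply(corpus$transcripts, function(t) t$phq8,
                                   integer(1L)))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(corpus$splits)) {
    jsonlite::write_json(corpus$splits, file.path(dir, "splits.json"))
  }
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  if (!file.exists(file.path(dir, "labels.csv"))) {
    stop("no corpus found at '", dir, "': labels.csv is missing")
  }
  labs <- read_labels(file.path(dir, "labels.csv"))
  transcripts <- lapply(seq_len(nrow(labs)), function(i) {
    read_transcript(file.path(dir, "transcripts", paste0(labs$id[i], ".tsv")),
                    id = labs$id[i], phq8 = labs$phq8[i])
  })
  splits_path <- file.path(dir, "splits.json")
  splits <- if (file.exists(splits_path)) {
    lapply(jsonlite::read_json(splits_path, simplifyVector = TRUE), as.character)
  } else NULL
  structure(list(transcripts = transcripts, params = NULL, splits = splits),
            class = "synthetic_corpus")
}
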