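## Linguistic item features from item-stem text: raw-token statistics,
## word-list memberships, pluggable part-of-speech counts, and
## multicollinearity screening.

#' Preprocess an item stem into tokens and sentences
#'
#' Mathematical symbols and digits are stripped (everything outside
#' letters, apostrophes, whitespace and sentence punctuation `.!?`),
#' tokens are lowercased, and sentences split on runs of `.!?`.
#'
#' @param text a single item stem.
#' @return list with `tokens` (lowercase words) and `sentences`; an empty
#'   token list is flagged via attribute `empty` so callers can exclude the
#'   item from linguistic features.
#' @export
preprocess_stem <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop_invalid("item stem must be a single non-empty string")
  clean <- gsub("[^A-Za-z'.!? ]+", " ", text)
  sentences <- trimws(strsplit(clean, "[.!?]+")[[1]])
  sentences <- sentences[nzchar(gsub("[^A-Za-z]", "", sentences))]
  words <- tolower(unlist(strsplit(gsub("[.!?]", " ", clean), "[[:space:]]+")))
  words <- gsub("^'+|'+$", "", words)
  words <- words[nzchar(gsub("[^a-z]", "", words))]
  out <- list(tokens = words, sentences = sentences)
  attr(out, "empty") <- length(words) == 0
  out
}

#' Raw-token features
#'
#' @param tokens character vector from [preprocess_stem()].
#' @return list with `word_token` (count), `prop_six_letters` (proportion
#'   of tokens with six or more letters; `NA` and flagged for zero tokens)
#'   and `n_sentences` when sentences are supplied via the `sentences`
#'   argument.
#' @param sentences optional sentence vector for the sentence count.
#' @export
token_features <- function(tokens, sentences = NULL) {
  n <- length(tokens)
  prop6 <- if (n == 0) NA_real_ else mean(nchar(gsub("[^a-z]", "", tokens)) >= 6)
  out <- list(word_token = n, prop_six_letters = prop6)
  if (!is.null(sentences)) out$n_sentences <- length(sentences)
  attr(out, "empty") <- n == 0
  out
}

#' Read a word-list resource
#'
#' Plain text, one lowercase token per line. For frequency tables
#' (`frequency = TRUE`) each line is `token<TAB>count`.
#'
#' @param path file path.
#' @param frequency read as a token -> frequency table.
#' @return character vector of tokens, or a named numeric frequency vector.
#' @export
read_wordlist <- function(path, frequency = FALSE) {
  if (!file.exists(path))
    stop_invalid("word-list resource not found: ", path)
  if (!frequency) {
    w <- tolower(trimws(readLines(path, warn = FALSE)))
    return(w[nzchar(w)])
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("token", "freq"),
                           stringsAsFactors = FALSE)
  stats::setNames(tab$freq, tolower(tab$token))
}

#' Word-list based features
#'
#' Counts tokens absent from a familiar-words list (difficult words), the
#' mean per-token frequency under a reference-corpus frequency table
#' ("popularity"; tokens missing from the table count as frequency 0), and
#' tokens present in a function-word list. `popularity_mode = "sum"`
#' switches the popularity score to the summed frequency.
#'
#' @param tokens character vector.
#' @param familiar character vector of familiar words (e.g., a Dale-Chall
#'   style list).
#' @param corpus_freq named numeric token frequency table (e.g., from a
#'   news corpus).
#' @param function_words character vector of function words.
#' @param popularity_mode `"mean"` (default) or `"sum"`.
#' @return list with `n_unfamiliar`, `popularity`, `n_function_words`.
#' @export
wordlist_features <- function(tokens, familiar, corpus_freq, function_words,
                              popularity_mode = c("mean", "sum")) {
  popularity_mode <- match.arg(popularity_mode)
  f <- corpus_freq[tokens]
  f[is.na(f)] <- 0
  pop <- if (length(tokens) == 0) NA_real_
         else if (popularity_mode == "mean") mean(f) else sum(f)
  list(n_unfamiliar = sum(!tokens %in% familiar),
       popularity = unname(pop),
       n_function_words = sum(tokens %in% function_words))
}

#' Deterministic lookup-table part-of-speech tagger
#'
#' Returns a tagger function mapping a token vector to (token, tag) pairs
#' by dictionary lookup; unknown tokens get tag `"UNK"`. Suitable for tests
#' and for small controlled vocabularies; a corpus-trained tagger can be
#' injected in its place.
#'
#' @param map named character vector, token -> tag.
#' @return function(tokens) -> data.frame(token, tag).
#' @export
lookup_tagger <- function(map) {
  names(map) <- tolower(names(map))
  function(tokens) {
    tag <- unname(map[tolower(tokens)])
    tag[is.na(tag)] <- "UNK"
    data.frame(token = tokens, tag = tag, stringsAsFactors = FALSE)
  }
}

# default mapping from Penn-style tags to the counted word classes
.TAG_CLASSES <- list(adjective = c("JJ", "JJR", "JJS", "ADJ"),
                     adverb = c("RB", "RBR", "RBS", "ADV"))

#' Part-of-speech features
#'
#' Tags the tokens with the injected tagger and counts adjectives and
#' adverbs under a documented tag map (Penn-style `JJ*`/`RB*` plus the
#' universal `ADJ`/`ADV`). Tags outside the map count in no class. A
#' tagger error flags the item and returns missing counts.
#'
#' @param tokens character vector.
#' @param tagger function(tokens) -> data.frame with columns token, tag.
#' @param tag_classes named list mapping class -> tag set.
#' @return list with `n_adjectives`, `n_adverbs` (NA and `failed = TRUE`
#'   attribute on tagger failure).
#' @export
pos_features <- function(tokens, tagger, tag_classes = .TAG_CLASSES) {
  tags <- tryCatch(tagger(tokens), error = function(e) NULL)
  if (is.null(tags) || !all(c("token", "tag") %in% names(tags))) {
    out <- list(n_adjectives = NA_real_, n_adverbs = NA_real_)
    attr(out, "failed") <- TRUE
    return(out)
  }
  list(n_adjectives = sum(tags$tag %in% tag_classes$adjective),
       n_adverbs = sum(tags$tag %in% tag_classes$adverb))
}

#' Extract the item feature matrix from stems plus metadata
#'
#' Produces the eight-feature set used throughout the package: word token
#' count, number of adjectives, number of adverbs, story flag, item type,
#' proportion of tokens with six or more letters, number of unfamiliar
#' (non-word-list) words, and corpus popularity. The story flag and item
#' type are metadata columns supplied by the caller, not text-derived.
#'
#' @param stems data frame with columns `item`, `stem`, `item_type` (0/1),
#'   `story` (0/1).
#' @param familiar,corpus_freq,function_words word-list resources as in
#'   [wordlist_features()].
#' @param tagger a tagger as in [pos_features()].
#' @return items x 8 feature matrix (rownames = item ids) with attribute
#'   `excluded` listing items whose stems had no tokens after stripping.
#' @export
extract_item_features <- function(stems, familiar, corpus_freq,
                                  function_words, tagger) {
  need <- c("item", "stem", "item_type", "story")
  if (!all(need %in% names(stems)))
    stop_invalid("stems must have columns: ", paste(need, collapse = ", "))
  feats <- c("word_token", "n_adjectives", "n_adverbs", "story",
             "item_type", "prop_six_letters", "n_unfamiliar", "popularity")
  z <- matrix(NA_real_, nrow(stems), length(feats),
              dimnames = list(stems$item, feats))
  excluded <- character(0)
  for (i in seq_len(nrow(stems))) {
    pp <- preprocess_stem(stems$stem[i])
    if (attr(pp, "empty")) { excluded <- c(excluded, stems$item[i]); next }
    tf <- token_features(pp$tokens)
    wf <- wordlist_features(pp$tokens, familiar, corpus_freq, function_words)
    pf <- pos_features(pp$tokens, tagger)
    z[i, ] <- c(tf$word_token, pf$n_adjectives, pf$n_adverbs,
                stems$story[i], stems$item_type[i], tf$prop_six_letters,
                wf$n_unfamiliar, wf$popularity)
  }
  attr(z, "excluded") <- excluded
  z
}

#' Screen features for multicollinearity
#'
#' Greedy retention in column order (zero-variance columns dropped first):
#' a feature is kept iff its absolute Pearson correlation with every
#' already-kept feature is below `rho_threshold`. Variance inflation
#' factors are then computed on the kept set and features at or above
#' `vif_threshold` are reported (and dropped).
#'
#' @param z items x features matrix.
#' @param rho_threshold pairwise correlation ceiling (default 0.3).
#' @param vif_threshold VIF ceiling (default 5).
#' @return object of class `feature_report`: the retained matrix, the full
#'   correlation matrix, VIFs of retained features, and per-feature
#'   retained/dropped status with reasons.
#' @export
screen_features <- function(z, rho_threshold = 0.3, vif_threshold = 5) {
  validate_features(z)
  nm <- colnames(z) %||% paste0("Z", seq_len(ncol(z)))
  status <- data.frame(feature = nm, retained = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  keep <- integer(0)
  for (m in seq_len(ncol(z))) {
    if (stats::sd(z[, m]) == 0) {
      status$reason[m] <- "zero variance"; next
    }
    rho <- if (length(keep))
      abs(stats::cor(z[, m], z[, keep, drop = FALSE])) else 0
    if (any(rho >= rho_threshold)) {
      status$reason[m] <- paste0("|rho| = ", round(max(rho), 2), " with ",
                                 nm[keep[which.max(rho)]])
    } else {
      keep <- c(keep, m); status$retained[m] <- TRUE
    }
  }
  if (length(keep) + 1 >= nrow(z))
    stop_invalid("too few items to compute VIFs on the retained set")
  v <- if (length(keep) > 1) vif(z[, keep, drop = FALSE]) else
    stats::setNames(1, nm[keep])
  names(v) <- nm[keep]
  high <- names(v)[v >= vif_threshold]
  for (f in high) {
    m <- match(f, nm)
    status$retained[m] <- FALSE
    status$reason[m] <- paste0("VIF = ", round(v[f], 1))
  }
  keep <- match(status$feature[status$retained], nm)
  structure(list(features = z[, keep, drop = FALSE],
                 correlation = stats::cor(z[, apply(z, 2, stats::sd) > 0,
                                            drop = FALSE]),
                 vif = v[names(v) %in% nm[keep]],
                 status = status,
                 rho_threshold = rho_threshold,
                 vif_threshold = vif_threshold),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("Feature screening: retained", sum(x$status$retained), "of",
      nrow(x$status), "features (|rho| <", x$rho_threshold, ", VIF <",
      x$vif_threshold, ")\n")
  dropped <- x$status[!x$status$retained, ]
  if (nrow(dropped))
    cat(paste0("  dropped ", dropped$feature, ": ", dropped$reason,
               collapse = "\n"), "\n")
  invisible(x)
}
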