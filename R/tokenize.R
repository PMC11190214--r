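#' Word-piece tokenizer for clinical narratives
#'
#' A small deterministic sub-word tokenizer: text is lower-cased, split on
#' whitespace, punctuation is split off into its own tokens, and each word
#' is decomposed by greedy longest-prefix matching against a word-piece
#' vocabulary. Continuation pieces carry the conventional `"##"` prefix, so
#' several pieces may compose one word (e.g. `"euthanasia"` ->
#' `"euth" "##anasia"`), which is what makes token-to-feature summation
#' non-trivial. Unknown fragments fall back to single characters, so
#' tokenization never fails.
#'
#' @param vocab Character vector of pieces; continuation pieces start with
#'   `"##"`. Default [default_wordpiece_vocab()].
#' @return A function `(character vector) -> list of token character
#'   vectors`, of class `wordpiece_tokenizer`.
#' @export
#' @examples
#' tok <- wordpiece_tokenizer()
#' tok("Owner elected euthanasia today.")
wordpiece_tokenizer <- function(vocab = default_wordpiece_vocab()) {
  whole <- unique(vocab[!startsWith(vocab, "##")])
  cont <- unique(sub("^##", "", vocab[startsWith(vocab, "##")]))
  whole_set <- stats::setNames(rep(TRUE, length(whole)), whole)
  cont_set <- stats::setNames(rep(TRUE, length(cont)), cont)
  max_len <- max(nchar(c(whole, cont)), 1L)

  split_word <- function(w) {
    n <- nchar(w)
    pieces <- character(0)
    pos <- 1L
    while (pos <= n) {
      found <- NA_character_
      for (len in seq(min(max_len, n - pos + 1L), 1L)) {
        cand <- substr(w, pos, pos + len - 1L)
        ok <- if (pos == 1L) isTRUE(whole_set[cand]) else isTRUE(cont_set[cand])
        if (ok) { found <- cand; break }
      }
      if (is.na(found)) found <- substr(w, pos, pos)  # character fallback
      pieces <- c(pieces, if (pos == 1L) found else paste0("##", found))
      pos <- pos + nchar(found)
    }
    pieces
  }

  f <- function(texts) {
    lapply(texts, function(tx) {
      if (is.na(tx) || !nzchar(trimws(tx))) return(character(0))
      tx <- tolower(tx)
      tx <- gsub("([[:punct:]])", " \\1 ", tx)
      tx <- gsub("# #", "##", tx, fixed = TRUE)
      words <- strsplit(trimws(tx), "[[:space:]]+")[[1]]
      unlist(lapply(words, split_word), use.names = FALSE)
    })
  }
  structure(f, class = c("wordpiece_tokenizer", "function"))
}

#' Default word-piece vocabulary
#'
#' Whole-word entries cover common English, veterinary shorthand (NAD, BAR,
#' CE, DUDE, o for owner) and the synthetic-cohort vocabulary; continuation
#' entries (`"##..."`) provide frequent suffixes and the pieces needed to
#' decompose mortality and clinical terms into multiple word-pieces.
#'
#' @return Character vector of pieces.
#' @export
default_wordpiece_vocab <- function() {
  whole <- c(
    # function words
    "a", "an", "and", "the", "is", "are", "was", "were", "of", "to", "in",
    "on", "at", "for", "with", "no", "not", "all", "very", "but", "or",
    "has", "had", "have", "be", "been", "its", "his", "her", "this", "that",
    "today", "well", "ok", "fine", "good", "normal", "given", "back",
    # clinical shorthand
    "o", "ce", "nad", "bar", "dude", "adv", "re", "abdo", "palp", "exam",
    "qol", "pts", "doa", "kg", "bcs", "hx", "vacc",
    # generator vocabulary (benign / signal / mortality stems)
    "bright", "alert", "responsive", "eating", "drinking", "hydration",
    "coat", "teeth", "ears", "eyes", "skin", "weight", "stable", "booster",
    "vaccination", "vaccine", "wormer", "worming", "flea", "check",
    "unremarkable", "recheck", "improving", "playful", "appetite",
    "reports", "concerned", "aware", "discussed", "advised", "owner",
    "elected", "slowing", "down", "age", "old", "older", "senior",
    "collapse", "collapsed", "tumour", "mass", "lump", "vomiting",
    "lethargy", "lethargic", "anorexia", "weak", "decline", "chronic",
    "renal", "cardiac", "arthritis", "stiff", "blind", "deaf", "kitten",
    "puppy", "young", "quality", "life", "sleep", "put", "home", "visit",
    "injection", "pain", "relief", "comfort", "palliative",
    # mortality stems kept whole so regex terms surface as single pieces
    "euth", "dead", "died", "pento", "crem", "burial", "bury", "ashes",
    "scatter", "casket",
    # breed and region words (routed high-cardinality features)
    "labrador", "cocker", "spaniel", "border", "collie", "french",
    "bulldog", "german", "shepherd", "staffordshire", "bull", "terrier",
    "jack", "russell", "golden", "retriever", "springer", "shih", "tzu",
    "chihuahua", "dachshund", "pug", "boxer", "beagle", "whippet",
    "lurcher", "greyhound", "rottweiler", "husky", "akita", "poodle",
    "cavapoo", "cockapoo", "labradoodle", "domestic", "shorthair",
    "longhair", "british", "ragdoll", "bengal", "siamese", "maine",
    "coon", "persian", "sphynx", "burmese", "north", "south", "east",
    "west", "yorkshire", "midlands", "london", "wales", "scotland",
    "ireland", "northern", "cumbria", "lancashire", "merseyside",
    "cheshire", "greater", "manchester", "tyne", "wear", "durham",
    "northumberland", "norfolk", "suffolk", "essex", "kent", "surrey",
    "sussex", "hampshire", "dorset", "devon", "cornwall", "somerset",
    "england",
    # numerals
    as.character(0:9)
  )
  cont <- c(
    "##s", "##ed", "##ing", "##ly", "##e", "##y", "##er", "##al",
    "##anasia", "##anased", "##anase", "##barb", "##ation", "##ated",
    "##ness", "##ia", "##itis", letters, 0:9
  )
  cont <- ifelse(startsWith(cont, "##"), cont, paste0("##", cont))
  unique(c(whole, cont))
}
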