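# Embedded vocabularies for the synthetic corpus and the key-phrase
# extractor.  Everything is built at load time from fixed embedded lists:
# no external downloads, no session randomness.

# Morphemes composing the background "clinical-ish" filler vocabulary.
# Filler words carry no label signal; their role is to give every note an
# idiosyncratic surface form, as real discharge summaries have.
.filler_prefixes <- c(
  "cardi", "nephr", "hepat", "derm", "neur", "gastr", "pulmon", "oste",
  "arthr", "hemat", "cephal", "entero", "myo", "angio", "broncho", "cysto",
  "encephal", "fibro", "glosso", "hystero", "kerato", "laryngo", "lipo",
  "mening", "nephro", "oculo", "phlebo", "pneumo", "rhino", "spleno",
  "thoraco", "tracheo", "vaso", "veno", "adeno", "chondro", "colo",
  "duodeno", "esophag", "gingivo"
)
.filler_suffixes <- c(
  "opathy", "itis", "osis", "emia", "algia", "ectomy", "ogram", "oscopy",
  "otomy", "ostomy", "oplasty", "olysis", "omegaly", "orrhea", "orrhagia",
  "osclerosis", "ostenosis", "otrophy", "oplegia", "oparesis", "ocele",
  "ogenic", "olith", "omalacia", "onecrosis", "opexy", "ophobia",
  "oporosis", "optosis", "orrhaphy", "ospasm", "otoxic", "ovolemia",
  "odynia", "ogenesis", "okinesis", "olepsy", "omimetic", "opoiesis",
  "otropic"
)

# Common connective words mixed into the filler stream for readability.
.filler_common <- c(
  "patient", "admitted", "noted", "stable", "history", "exam", "course",
  "hospital", "daily", "continued", "improved", "discharged", "follow",
  "plan", "review", "left", "right", "mild", "moderate", "marked",
  "bilateral", "chronic", "acute", "status", "prior", "known", "findings",
  "impression", "recommend", "tolerated", "without", "during", "after",
  "before", "upon", "under", "over", "within", "again", "also", "well",
  "clear", "present", "absent", "normal", "unremarkable", "elevated",
  "decreased", "increased", "persistent", "resolved", "ongoing",
  "intermittent", "occasional", "frequent", "severe", "slight", "gradual",
  "sudden", "progressive", "residual", "initial", "final", "routine",
  "repeat", "serial", "supportive", "symptomatic", "asymptomatic",
  "afebrile", "ambulatory", "alert", "oriented", "cooperative",
  "comfortable", "fatigued", "weak", "dizzy", "nauseated", "febrile",
  "tachycardic", "bradycardic", "hypertensive", "hypotensive", "anemic",
  "icteric", "edematous", "cyanotic", "diaphoretic", "lethargic"
)

# Morphemes for code signature phrases.  Deliberately DISJOINT from the
# filler morphemes so that, with signature injection off, note text carries
# exactly zero information about the label set.
.signature_prefixes <- c(
  "zygor", "quend", "vexil", "brom", "drast", "fulm", "glent", "harn",
  "jusk", "krelb", "lorn", "morv", "nusk", "plov", "quarn", "rusk",
  "sarn", "trelm", "urv", "weld", "xant", "yorv", "zelb", "crusk",
  "drelb", "flarn", "grusk", "helv", "jarn", "klov"
)
.signature_suffixes <- c(
  "ax", "edge", "ion", "ora", "une", "ivex", "oam", "urst", "yle", "ect",
  "ulf", "ingr", "ost", "arn", "ibe", "ude", "olv", "ym", "anth", "orp"
)

# Surnames and place stems for PHI surrogate tokens.
.phi_names <- c(
  "garcia", "nakamura", "okafor", "lindqvist", "petrov", "alvarez",
  "kowalski", "yilmaz", "fontaine", "oduya", "ramirez", "schneider",
  "tanaka", "novak", "haddad", "bergstrom"
)
.phi_places <- c(
  "riverside", "maplewood", "kingsport", "eastvale", "northfield",
  "lakeview", "westbrook", "fairhaven", "stonebridge", "oakmont"
)

# Fixed English stopword list used by the key-phrase extractor.
.stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "could", "did",
  "do", "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "me", "more", "most", "my", "no", "nor", "not", "now",
  "of", "off", "on", "once", "only", "or", "other", "our", "ours", "out",
  "over", "own", "same", "she", "should", "so", "some", "such", "than",
  "that", "the", "their", "theirs", "them", "then", "there", "these",
  "they", "this", "those", "through", "to", "too", "under", "until", "up",
  "very", "was", "we", "were", "what", "when", "where", "which", "while",
  "who", "whom", "why", "will", "with", "would", "you", "your", "yours"
)

#' Background filler vocabulary
#'
#' The fixed embedded word list the corpus generator draws filler tokens
#' from: morpheme-composed clinical-sounding words plus common connective
#' words.  Carries no label information.
#'
#' @return character vector of words.
#' @export
filler_vocabulary <- function() {
  composed <- as.vector(outer(.filler_prefixes, .filler_suffixes, paste0))
  c(composed, .filler_common)
}

#' Signature-phrase vocabulary
#'
#' The reserved word pool that code signature phrases are built from.
#' Disjoint from [filler_vocabulary()] so signature injection is the only
#' channel from labels to text.
#'
#' @return character vector of words.
#' @export
signature_vocabulary <- function() {
  as.vector(outer(.signature_prefixes, .signature_suffixes, paste0))
}

#' Embedded English stopword list
#'
#' Used by the key-phrase extractor: candidates may not begin or end with
#' a stopword.
#'
#' @return character vector of lowercase stopwords.
#' @export
stopword_list <- function() .stopwords
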