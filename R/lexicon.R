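#' Referral classes
#'
#' The five referral classes used throughout the package. `DATE`, `TODAY`,
#' `YESTERDAY` and `NO_PREVIOUS` are span-level classes that may occur several
#' times per report; `MISSING` is a document-level, exclusive class: a report
#' labeled `MISSING` carries no span of any other class.
#'
#' @return Character vector of class names.
#' @export
referral_classes <- function() {
  c("DATE", "TODAY", "YESTERDAY", "NO_PREVIOUS", "MISSING")
}

#' DICOM-style modality codes
#'
#' @return Character vector of the nine supported modality codes.
#' @export
modality_codes <- function() {
  c("CR", "XA", "CT", "MR", "NM", "PT", "US", "MG", "OT")
}

#' Body-region labels
#'
#' The default set of fourteen body-region labels attached to exams.
#'
#' @return Character vector of region labels.
#' @export
body_regions <- function() {
  c("thorax", "abdomen", "head", "breast", "heart", "neck", "spine",
    "pelvis", "trunk", "upper_extremity", "lower_extremity", "whole_body",
    "vessels", "other")
}

#' German modality synonym table
#'
#' Maps each modality code to the German surface forms under which it appears
#' in report text. Used both by the synthetic generator (to mention a modality
#' in a referral sentence) and by the linker (to detect a mentioned modality).
#' Users may extend or override entries.
#'
#' @param extra Optional named list of character vectors merged over the
#'   defaults (names are modality codes).
#' @return Named list: modality code -> character vector of synonyms.
#' @export
modality_lexicon <- function(extra = NULL) {
  lex <- list(
    CT = c("CT", "Computertomographie"),
    MR = c("MRT", "MR", "Magnetresonanztomographie"),
    CR = c("Röntgen", "Rx", "konventionelle Aufnahme"),
    US = c("Sonographie", "Ultraschall"),
    MG = c("Mammographie"),
    XA = c("Angiographie"),
    NM = c("Szintigraphie"),
    PT = c("PET-CT", "PET"),
    OT = c("Durchleuchtung")
  )
  if (!is.null(extra)) {
    for (nm in names(extra)) lex[[nm]] <- unique(c(extra[[nm]], lex[[nm]]))
  }
  lex
}

#' German referral phrase bank
#'
#' Lexicon of literal expressions for the non-numeric referral classes. The
#' `noisy` element holds out-of-lexicon variants (colloquial or misspelled)
#' that the synthetic generator can inject to emulate phrasing the rule-based
#' tagger does not know.
#'
#' @return Named list with elements `TODAY`, `YESTERDAY`, `NO_PREVIOUS`,
#'   and `noisy` (itself a named list for the same classes).
#' @export
referral_phrases <- function() {
  list(
    TODAY = c("heute", "vom heutigen Tag", "gleichentags"),
    YESTERDAY = c("gestern", "vom Vortag"),
    NO_PREVIOUS = c(
      "Keine Voraufnahmen zum Vergleich vorhanden",
      "keine Voruntersuchung verfügbar",
      "Keine Vergleichsaufnahmen vorliegend",
      "keine relevanten Voraufnahmen"
    ),
    noisy = list(
      TODAY = c("am selben Tag", "im Verlauf des heutigen Tages"),
      YESTERDAY = c("tags zuvor"),
      NO_PREVIOUS = c(
        "Keine Vorafnahmen zum Vergleich",
        "Vergleichsbilder liegen nicht vor"
      )
    )
  )
}

.regex_escape <- function(s) {
  gsub("([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1", s, perl = TRUE)
}

# Abbreviations whose trailing period never ends a sentence.
.radgraph_abbrev <- c(
  "z.B.", "bzw.", "ggf.", "ca.", "u.a.", "s.o.", "v.a.", "Dr.", "St.",
  "i.v.", "d.h.", "Z.n.", "a.e."
)
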