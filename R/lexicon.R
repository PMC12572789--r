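#' @keywords internal
"_PACKAGE"

## NULL coalescing helper used across the package
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize free-text ingredient lists
#'
#' Lower-cases, folds accents to ASCII, replaces punctuation and hyphens by
#' spaces, glues a standalone "e"/"E" onto a following number so that
#' "E 620", "e620" and "E620" become the same token, and squeezes whitespace.
#' The result is a canonical space-separated token stream. Normalization is
#' idempotent and the empty string maps to the empty string.
#'
#' @param x character vector of raw ingredient texts.
#' @return character vector of normalized token streams (same length).
#' @examples
#' normalize_text("Sugar, FLAVOURING (E 621)")
#' @export
normalize_text <- function(x) {
  if (length(x) == 0L) return(character(0))
  x[is.na(x)] <- ""
  out <- tolower(x)
  out <- iconv(out, from = "UTF-8", to = "ASCII//TRANSLIT", sub = " ")
  out[is.na(out)] <- ""
  out <- gsub("[^a-z0-9]+", " ", out)
  # "e 620" -> "e620" (E-number split across whitespace)
  out <- gsub("\\be (\\d)", "e\\1", out, perl = TRUE)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

lexicon_env <- new.env(parent = emptyenv())

new_mup_lexicon <- function(categories, markers) {
  lex <- list(
    categories = categories,
    markers = markers,
    category_of = vapply(markers, function(m) m$category, character(1)),
    marker_names = vapply(markers, function(m) m$name, character(1))
  )
  names(lex$category_of) <- lex$marker_names
  # pre-pad normalized terms for whole-token-sequence matching
  lex$padded_terms <- lapply(markers, function(m) {
    paste0(" ", normalize_text(m$search_terms), " ")
  })
  names(lex$padded_terms) <- lex$marker_names
  class(lex) <- "mup_lexicon"
  lex
}

validate_lexicon <- function(lex) {
  if (length(lex$categories) < 1L) stop("lexicon must define at least one category")
  if (anyDuplicated(lex$categories))
    stop("duplicate category names: ",
         paste(unique(lex$categories[duplicated(lex$categories)]), collapse = ", "))
  if (anyDuplicated(lex$marker_names)) {
    dup <- unique(lex$marker_names[duplicated(lex$marker_names)])
    stop("marker assigned more than once (must map to exactly one category): ",
         paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(lex$category_of), lex$categories)
  if (length(bad)) stop("marker with unknown category: ", paste(bad, collapse = ", "))
  nt <- vapply(lex$markers, function(m) length(m$search_terms), integer(1))
  if (any(nt == 0L))
    stop("marker without search terms: ",
         paste(lex$marker_names[nt == 0L], collapse = ", "))
  invisible(lex)
}

#' Load a MUP lexicon from a YAML file
#'
#' The file lists categories, each with markers, each with a non-empty set of
#' search terms (see the shipped \code{inst/extdata/mup_lexicon.yaml}).
#' Validation rejects duplicate category names, markers assigned to more than
#' one category, and markers without search terms.
#'
#' @param path path to the lexicon YAML file; default loads the shipped
#'   9-category / 57-marker lexicon.
#' @return an object of class \code{mup_lexicon}.
#' @export
load_lexicon <- function(path = system.file("extdata", "mup_lexicon.yaml",
                                            package = "mupsurv")) {
  if (!nzchar(path) || !file.exists(path)) stop("lexicon file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed lexicon file '", path, "': ", conditionMessage(e)))
  if (is.null(raw$categories)) stop("malformed lexicon file: no 'categories' key")
  categories <- vapply(raw$categories, function(cc) {
    if (is.null(cc$name)) stop("malformed lexicon entry: category without a name")
    cc$name
  }, character(1))
  markers <- list()
  for (cc in raw$categories) {
    for (m in cc$markers) {
      if (is.null(m$name))
        stop("malformed lexicon entry: marker without a name in category '",
             cc$name, "'")
      markers[[length(markers) + 1L]] <- list(
        name = m$name,
        category = cc$name,
        search_terms = as.character(unlist(m$search_terms)),
        category_marker = isTRUE(m$category_marker),
        verified = isTRUE(m$verified)
      )
    }
  }
  validate_lexicon(new_mup_lexicon(categories, markers))
}

#' Default shipped MUP lexicon (9 categories, 57 markers)
#'
#' Cached per session.
#' @return a \code{mup_lexicon}.
#' @export
default_lexicon <- function() {
  if (is.null(lexicon_env$default)) lexicon_env$default <- load_lexicon()
  lexicon_env$default
}

#' @export
print.mup_lexicon <- function(x, ...) {
  cat("MUP lexicon:", length(x$markers), "markers in",
      length(x$categories), "categories\n")
  tab <- table(factor(x$category_of, levels = x$categories))
  for (cc in x$categories) cat("  ", cc, ": ", tab[[cc]], " markers\n", sep = "")
  invisible(x)
}

#' Scan an ingredient list for MUPs
#'
#' A marker is present iff at least one of its search terms occurs in the
#' normalized text as a whole-word token (multi-word terms must occur as a
#' contiguous token sequence). Matching is case-, accent- and
#' punctuation-insensitive via \code{\link{normalize_text}}.
#'
#' @param text a single raw ingredient string.
#' @param lexicon a \code{mup_lexicon}.
#' @return character vector of marker names present (possibly empty).
#' @examples
#' scan_ingredients("Sugar, monosodium glutamate", default_lexicon())
#' @export
scan_ingredients <- function(text, lexicon = default_lexicon()) {
  hits <- scan_ingredients_matrix(text, lexicon)
  lexicon$marker_names[hits[1L, ]]
}

#' Scan many ingredient lists at once
#'
#' Commas, semicolons, colons and brackets delimit ingredient segments:
#' multi-word terms never match across a segment boundary ("whole milk,
#' protein hydrolysate" does not contain "milk protein").
#'
#' @param texts character vector of raw ingredient strings.
#' @param lexicon a \code{mup_lexicon}.
#' @return logical matrix (length(texts) x n markers) of marker presence,
#'   with marker names as column names.
#' @export
scan_ingredients_matrix <- function(texts, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "mup_lexicon"))
  segged <- vapply(strsplit(as.character(texts), "[][,;:()]"),
                   function(segs) paste(normalize_text(segs), collapse = "  "),
                   character(1))
  padded <- paste0(" ", segged, " ")
  nm <- lexicon$marker_names
  out <- matrix(FALSE, nrow = length(texts), ncol = length(nm),
                dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    hit <- rep(FALSE, length(texts))
    for (term in lexicon$padded_terms[[j]]) {
      if (all(hit)) break
      hit <- hit | grepl(term, padded, fixed = TRUE)
    }
    out[, j] <- hit
  }
  out
}

#' Is a food item ultra-processed?
#'
#' An item counts as ultra-processed food (UPF, NOVA group 4) if it contains
#' at least one marker of ultra-processing.
#'
#' @param markers_present character vector (or logical vector) of detected
#'   markers for one product.
#' @return TRUE iff at least one marker is present.
#' @export
is_upf <- function(markers_present) {
  if (is.logical(markers_present)) return(any(markers_present))
  length(markers_present) > 0L
}

#' Markers belonging to a category
#' @param lexicon a \code{mup_lexicon}.
#' @param category category name.
#' @return character vector of member marker names.
#' @export
category_markers <- function(lexicon, category) {
  if (!category %in% lexicon$categories) stop("unknown category: ", category)
  lexicon$marker_names[lexicon$category_of == category]
}
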