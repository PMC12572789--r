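test_that("shipped lexicon has the full marker taxonomy", {
  lex <- default_lexicon()
  expect_s3_class(lex, "mup_lexicon")
  expect_length(lex$categories, 9L)
  expect_length(lex$markers, 57L)
  expect_setequal(
    lex$categories,
    c("flavour", "flavour enhancer", "colouring agent", "sweetener",
      "processing aid", "varieties of sugar", "modified oil",
      "protein source", "fibre"))
  # every marker maps to exactly one category
  expect_true(all(lex$category_of %in% lex$categories))
  expect_false(anyDuplicated(lex$marker_names) > 0)
  # the four markers that coincide with their categories are flagged
  flagged <- lex$marker_names[vapply(lex$markers, `[[`, logical(1),
                                     "category_marker")]
  expect_setequal(flagged, c("flavour", "colour", "hydrogenated oil", "fibre"))
  # glutamate's printed term set: E620-E625, glutamate, glutamic acids, MSG
  glu <- lex$markers[[which(lex$marker_names == "glutamate")]]
  expect_true(all(c(paste0("e", 620:625), "glutamate", "glutamic acids",
                    "msg") %in% glu$search_terms))
  expect_true(glu$verified)
})

test_that("lexicon loading validates structure", {
  one <- tempfile(fileext = ".yaml")
  writeLines(c("categories:",
               "  - name: sweetener",
               "    markers:",
               "      - name: aspartame",
               "        search_terms: [aspartame, e951]"), one)
  lex <- load_lexicon(one)
  expect_length(lex$markers, 1L)
  expect_identical(lex$category_of[["aspartame"]], "sweetener")

  dup <- tempfile(fileext = ".yaml")
  writeLines(c("categories:",
               "  - name: a",
               "    markers:",
               "      - name: m1",
               "        search_terms: [x]",
               "  - name: b",
               "    markers:",
               "      - name: m1",
               "        search_terms: [y]"), dup)
  expect_error(load_lexicon(dup), "more than once")

  noterms <- tempfile(fileext = ".yaml")
  writeLines(c("categories:",
               "  - name: a",
               "    markers:",
               "      - name: m1",
               "        search_terms: []"), noterms)
  expect_error(load_lexicon(noterms), "without search terms")

  expect_error(load_lexicon(tempfile()), "not found")
})

test_that("normalization is case/punctuation/E-number invariant and idempotent", {
  n <- normalize_text("Sugar, FLAVOURING (E 621)")
  expect_true(grepl("\\bflavouring\\b", n))
  expect_true(grepl("\\be621\\b", n))
  expect_identical(normalize_text(""), "")
  expect_identical(normalize_text("E 620"), normalize_text("e620"))
  expect_identical(normalize_text("E620"), "e620")

  set.seed(99)
  pieces <- c("Sugar", "E 621", "creme fraîche", "MSG", "semi-skimmed",
              "(spices)", "100% cocoa", ",,", "Flävour")
  for (r in 1:50) {
    s <- paste(sample(pieces, sample(1:6, 1), replace = TRUE), collapse = " ")
    expect_identical(normalize_text(normalize_text(s)), normalize_text(s))
  }
})

test_that("ingredient scanning matches whole terms only", {
  lex <- default_lexicon()
  expect_identical(scan_ingredients("water, monosodium glutamate", lex),
                   "glutamate")
  expect_identical(scan_ingredients("water, salt, oats", lex), character(0))
  expect_identical(scan_ingredients("", lex), character(0))
  # whole-word anchoring: no hits inside longer words
  expect_identical(scan_ingredients("discoloured sulphured apricots", lex),
                   character(0))
  # multi-word terms do not match across comma boundaries
  expect_identical(scan_ingredients("whole milk, protein hydrolysate", lex),
                   "hydrolysed protein")
  expect_true("milk protein" %in%
                scan_ingredients("contains milk protein isolate", lex))
})

test_that("scanning agrees with a brute-force per-term oracle on random texts", {
  lex <- default_lexicon()
  set.seed(7)
  all_terms <- unlist(lapply(lex$markers, `[[`, "search_terms"))
  fillers <- c("water", "salt", "oats", "rye flour", "tomato", "basil",
               "butter", "rice", "almonds", "honey")
  # independent oracle: normalize one segment the hard way and look for each
  # term as a delimited token run
  oracle_scan <- function(raw) {
    segs <- strsplit(raw, ",", fixed = TRUE)[[1]]
    norm <- function(s) {
      s <- tolower(s)
      s <- gsub("[^a-z0-9]+", " ", s)
      s <- gsub("\\be (\\d)", "e\\1", s, perl = TRUE)
      paste0(" ", trimws(gsub(" +", " ", s)), " ")
    }
    nsegs <- vapply(segs, norm, character(1))
    vapply(lex$markers, function(m) {
      any(vapply(m$search_terms, function(tm) {
        any(grepl(paste0(" ", tm, " "), nsegs, fixed = TRUE))
      }, logical(1)))
    }, logical(1))
  }
  for (r in 1:200) {
    ing <- sample(c(sample(all_terms, sample(0:4, 1)),
                    sample(fillers, sample(1:5, 1))))
    raw <- paste(ing, collapse = ", ")
    expect_identical(unname(scan_ingredients_matrix(raw, lex)[1, ]),
                     unname(oracle_scan(raw)), label = raw)
  }
})

test_that("scanning is monotone and categories are unions of members", {
  lex <- default_lexicon()
  set.seed(13)
  all_terms <- unlist(lapply(lex$markers, `[[`, "search_terms"))
  for (r in 1:25) {
    a <- paste(sample(all_terms, 3), collapse = ", ")
    b <- paste(a, paste(sample(all_terms, 2), collapse = ", "), sep = ", ")
    expect_true(all(scan_ingredients(a, lex) %in% scan_ingredients(b, lex)))
    pres <- mupsurv:::presence_by_key(b, lex)[1, ]
    for (cc in lex$categories) {
      members <- category_markers(lex, cc)
      expect_identical(unname(pres[paste0("category:", cc)]),
                       any(pres[members]))
    }
    expect_identical(unname(pres["UPF"]), any(pres[lex$marker_names]))
  }
})

test_that("UPF rule is at-least-one-marker", {
  expect_true(is_upf("flavour"))
  expect_true(is_upf(c("lactose")))
  expect_false(is_upf(character(0)))
  expect_true(is_upf(c(FALSE, TRUE, FALSE)))
  expect_false(is_upf(logical(0)))
})
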